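#' Tissue color phenotype map
#'
#' Returns the packaged map assigning a pigment color (red, yellow, black) to
#' every hybridized tissue: each forewing section of the two morphs
#' (\emph{H. e. petiverana} and the hybrid stock) and each whole hindwing race
#' (\emph{emma}, \emph{favorinus}, \emph{amphitrite}). The proximal section is
#' black in petiverana and red in the hybrid; the medial section is red in
#' petiverana and yellow in the hybrid; the distal section is black in both.
#' Hindwings are classified as one color per race: emma (rayed) red,
#' favorinus (yellow-barred) yellow, amphitrite black.
#'
#' The map is stored as a plain TSV under \code{inst/extdata} so it can be
#' edited and versioned.
#'
#' @param file Optional path to an alternative map (TSV with columns
#'   \code{wing}, \code{morph}, \code{section}, \code{color}).
#' @return A data.frame with columns \code{wing}, \code{morph},
#'   \code{section}, \code{color}.
#' @export
phenotype_map <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "phenotype_map.tsv", package = "wingpattern",
                        mustWork = TRUE)
  }
  map <- utils::read.delim(file, stringsAsFactors = FALSE)
  required <- c("wing", "morph", "section", "color")
  if (!all(required %in% names(map))) {
    stop("phenotype map must have columns: ", paste(required, collapse = ", "))
  }
  map
}

#' Look up the color of a tissue
#'
#' Color is a pure function of (wing, morph, section) under the phenotype map.
#'
#' @param wing,morph,section Character vectors (recycled to common length).
#' @param map Phenotype map, as returned by [phenotype_map()].
#' @return Character vector of colors ("red", "yellow" or "black").
#' @export
tissue_color <- function(wing, morph, section, map = phenotype_map()) {
  key <- paste(wing, morph, section, sep = "\r")
  map_key <- paste(map$wing, map$morph, map$section, sep = "\r")
  idx <- match(key, map_key)
  if (anyNA(idx)) {
    bad <- unique(paste(wing, morph, section)[is.na(idx)])
    stop("no phenotype map entry for tissue(s): ", paste(bad, collapse = "; "))
  }
  map$color[idx]
}

#' Stage levels of the pupal wing time course
#'
#' The five ordered sampling stages: days 1, 3 and 5 after pupation, the
#' ommochrome stage (~7 d, when red/orange pigment appears) and the melanin
#' stage (~8 d, when black pigment appears).
#'
#' @return Character vector of the ordered stage labels.
#' @export
stage_levels <- function() c("D1", "D3", "D5", "OMMO", "MELA")

#' Generator configuration
#'
#' Builds and validates the configuration for the synthetic probe-level data
#' generator. Defaults reproduce the study's array content (12,450 transcript
#' contigs represented by 1-6 probes each, mean coverage just over 3 probes
#' per contig, plus random control probes) and its two factorial designs.
#'
#' Planted effect classes and their default mixture:
#' \describe{
#'   \item{null}{no signal at all (0.55)}
#'   \item{stage_only}{a per-contig random walk across the five ordered
#'     stages, shared by all tissues; these contigs carry the developmental
#'     signal that dominates total expression variance (0.25)}
#'   \item{proximal_up / distal_up}{higher expression in the proximal
#'     (respectively distal) forewing section at every stage (0.05 / 0.03)}
#'   \item{color_red_up / color_yellow_up}{higher expression in red
#'     (respectively yellow) tissues during the ommochrome and melanin
#'     stages (0.05 / 0.04)}
#'   \item{morph_global}{higher expression across the whole hybrid forewing
#'     at every stage, a color-inconsistent confound (0.03)}
#' }
#'
#' @param n_contigs Number of transcript contigs.
#' @param probes_per_contig_prob Probabilities for drawing 1..6 probes per
#'   contig (mean ~3.2 by default).
#' @param n_random_probes Number of RANDOM quality-control probes.
#' @param replicates_forewing,replicates_hindwing Biological replicates per
#'   condition cell.
#' @param missing_wings data.frame(morph, stage, replicate) of forewing wings
#'   dropped before hybridization; removing a wing removes all three of its
#'   section samples. Default: one Day-1 petiverana replicate, giving the
#'   87-sample forewing design.
#' @param effect_fractions Named numeric mixture over effect classes; must
#'   sum to 1.
#' @param effect_size Planted log2 fold change for non-null, non-stage-only
#'   classes.
#' @param active_stages_color Stages during which color effects are active.
#' @param sigma_probe Probe-level noise SD (log2 scale).
#' @param sigma_individual Individual (wing) random-effect SD.
#' @param sigma_stage Stage random-walk step SD for stage_only contigs.
#' @param baseline_mean,sigma_baseline Contig baseline log2 mean and SD.
#' @param sigma_probe_offset SD of fixed per-probe offsets (makes probe
#'   summarization non-trivial).
#' @param slide_artifact Either NULL or a list with elements \code{sample}
#'   (sample_id, or integer index into the design), \code{x}, \code{y}
#'   (length-2 inclusive coordinate ranges) and \code{bias} (additive log2
#'   bias) describing a rectangular uneven-intensity region on one subarray.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_contigs = 12450,
                             probes_per_contig_prob = c(0.10, 0.20, 0.28,
                                                        0.24, 0.12, 0.06),
                             n_random_probes = 3248,
                             replicates_forewing = 3,
                             replicates_hindwing = 4,
                             missing_wings = data.frame(
                               morph = "petiverana", stage = "D1",
                               replicate = 3L, stringsAsFactors = FALSE),
                             effect_fractions = c(null = 0.55,
                                                  stage_only = 0.25,
                                                  proximal_up = 0.05,
                                                  distal_up = 0.03,
                                                  color_red_up = 0.05,
                                                  color_yellow_up = 0.04,
                                                  morph_global = 0.03),
                             effect_size = 1.5,
                             active_stages_color = c("OMMO", "MELA"),
                             sigma_probe = 0.3,
                             sigma_individual = 0.2,
                             sigma_stage = 1.0,
                             baseline_mean = 8,
                             sigma_baseline = 1.5,
                             sigma_probe_offset = 0.5,
                             slide_artifact = NULL,
                             seed = 1L) {
  stopifnot(n_contigs >= 0, length(probes_per_contig_prob) == 6L)
  if (any(probes_per_contig_prob < 0) ||
      abs(sum(probes_per_contig_prob) - 1) > 1e-8) {
    stop("probes_per_contig_prob must be a probability vector over 1..6")
  }
  classes <- c("null", "stage_only", "proximal_up", "distal_up",
               "color_red_up", "color_yellow_up", "morph_global")
  if (!all(names(effect_fractions) %in% classes)) {
    stop("unknown effect class in effect_fractions")
  }
  ef <- stats::setNames(numeric(length(classes)), classes)
  ef[names(effect_fractions)] <- effect_fractions
  if (abs(sum(ef) - 1) > 1e-8) stop("effect_fractions must sum to 1")
  if (sigma_probe <= 0 || sigma_individual <= 0 || sigma_stage <= 0 ||
      sigma_baseline <= 0 || sigma_probe_offset <= 0) {
    stop("all noise SDs must be > 0")
  }
  if (!all(active_stages_color %in% stage_levels())) {
    stop("active_stages_color must be a subset of the stage levels")
  }
  cfg <- list(n_contigs = as.integer(n_contigs),
              probes_per_contig_prob = probes_per_contig_prob,
              n_random_probes = as.integer(n_random_probes),
              replicates_forewing = as.integer(replicates_forewing),
              replicates_hindwing = as.integer(replicates_hindwing),
              missing_wings = missing_wings,
              effect_fractions = ef,
              effect_size = effect_size,
              active_stages_color = active_stages_color,
              sigma_probe = sigma_probe,
              sigma_individual = sigma_individual,
              sigma_stage = sigma_stage,
              baseline_mean = baseline_mean,
              sigma_baseline = sigma_baseline,
              sigma_probe_offset = sigma_probe_offset,
              slide_artifact = slide_artifact,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# Subarrays per physical slide on the 12-plex platform.
SUBARRAYS_PER_SLIDE <- 12L

#' Generate the factorial sample design
#'
#' Builds the per-sample design table for both wing studies: forewings with
#' \code{replicates x 2 morphs x 3 wing sections x 5 stages} (each replicate
#' individual contributes its proximal, medial and distal section to the same
#' three rows), and hindwings with \code{replicates x 3 races x 5 stages}
#' sampled whole. Wings listed in \code{missing_wings} are removed together
#' with all three of their section samples; the default configuration
#' therefore yields 87 forewing and 60 hindwing samples. Samples are dealt
#' round-robin across 12-plex slides after ordering by condition, so
#' replicates of the same condition land on different slides.
#'
#' @param config A [generator_config()].
#' @return A data.frame (the design table) with columns \code{sample_id},
#'   \code{wing}, \code{morph}, \code{section}, \code{stage},
#'   \code{individual}, \code{slide}, \code{color}.
#' @export
generate_design <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  stages <- stage_levels()
  fore <- NULL
  if (config$replicates_forewing > 0) {
    grid <- expand.grid(section = c("proximal", "medial", "distal"),
                        replicate = seq_len(config$replicates_forewing),
                        stage = stages,
                        morph = c("petiverana", "hybrid"),
                        stringsAsFactors = FALSE)
    grid$wing <- "forewing"
    grid$individual <- sprintf("FW_%s_%s_r%d", grid$morph, grid$stage,
                               grid$replicate)
    mw <- config$missing_wings
    if (!is.null(mw) && nrow(mw) > 0) {
      gone <- sprintf("FW_%s_%s_r%d", mw$morph, mw$stage, mw$replicate)
      if (!all(gone %in% grid$individual)) {
        stop("missing_wings references nonexistent individual(s): ",
             paste(setdiff(gone, grid$individual), collapse = ", "))
      }
      grid <- grid[!(grid$individual %in% gone), , drop = FALSE]
    }
    fore <- grid
  }
  hind <- NULL
  if (config$replicates_hindwing > 0) {
    grid <- expand.grid(replicate = seq_len(config$replicates_hindwing),
                        stage = stages,
                        morph = c("emma", "favorinus", "amphitrite"),
                        stringsAsFactors = FALSE)
    grid$wing <- "hindwing"
    grid$section <- "whole"
    grid$individual <- sprintf("HW_%s_%s_r%d", grid$morph, grid$stage,
                               grid$replicate)
    hind <- grid
  }
  design <- rbind(fore[, c("wing", "morph", "section", "stage", "replicate",
                           "individual")],
                  hind[, c("wing", "morph", "section", "stage", "replicate",
                           "individual")])
  if (is.null(design) || nrow(design) == 0) {
    return(data.frame(sample_id = character(), wing = character(),
                      morph = character(), section = character(),
                      stage = character(), individual = character(),
                      slide = character(), color = character(),
                      stringsAsFactors = FALSE))
  }
  design$sample_id <- sprintf("%s.%s.%s.%s.r%d",
                              ifelse(design$wing == "forewing", "FW", "HW"),
                              design$morph, design$section, design$stage,
                              design$replicate)
  # Deal round-robin across slides within each wing study (the two studies
  # were hybridized separately): order by condition, then alternate slides so
  # replicates of a condition are spread across slides.
  design$slide <- NA_character_
  for (w in unique(design$wing)) {
    idx <- which(design$wing == w)
    sub <- design[idx, ]
    ord <- order(sub$stage, sub$morph, sub$section, sub$replicate)
    n_slides <- max(1L, ceiling(length(idx) / SUBARRAYS_PER_SLIDE))
    design$slide[idx[ord]] <- sprintf("%s_slide%02d",
                                      toupper(substr(w, 1, 1)),
                                      rep_len(seq_len(n_slides), length(idx)))
  }
  design$color <- tissue_color(design$wing, design$morph, design$section)
  design$replicate <- NULL
  rownames(design) <- NULL
  design[, c("sample_id", "wing", "morph", "section", "stage", "individual",
             "slide", "color")]
}

#' Simulate probe-level intensities with planted effects
#'
#' Simulates a positive probe-by-sample intensity table on the study's grid
#' layout. On the log2 scale each probe value is
#' \code{baseline + probe offset + stage effect + planted effect * indicator
#' + individual effect + slide artifact + noise}, and intensities are
#' \code{2^} of that, hence strictly positive (lognormal noise model). The
#' planted-effect indicator depends on the contig's effect class: proximal/
#' distal contigs respond to the forewing section, color contigs to the
#' tissue color during the active pigment stages, and morph_global contigs to
#' the hybrid forewing as a whole. RANDOM quality-control probes carry
#' baseline-plus-noise only.
#'
#' Output is fully determined by \code{config$seed}.
#'
#' @param design Design table from [generate_design()].
#' @param config A [generator_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{intensity}{data.frame: \code{probe_id}, \code{x}, \code{y},
#'       \code{contig_id} (sentinel "RANDOM" for control probes), then one
#'       positive intensity column per sample.}
#'     \item{probemap}{data.frame(probe_id, contig_id) for transcript probes.}
#'     \item{truth}{data.frame(contig_id, effect_class, effect_size,
#'       active_stages) — the planted truth used for recovery scoring.}
#'   }
#' @export
simulate_intensities <- function(design, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(design) == 0) stop("design is empty")
  set.seed(config$seed)
  n <- config$n_contigs
  classes <- names(config$effect_fractions)
  counts <- round(config$effect_fractions * n)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
  effect_class <- sample(rep(classes, times = counts))
  contig_id <- sprintf("contig%05d", seq_len(n))

  active <- lapply(effect_class, function(cl) {
    if (cl %in% c("color_red_up", "color_yellow_up")) config$active_stages_color
    else if (cl == "null") character(0)
    else stage_levels()
  })
  effect_size <- ifelse(effect_class %in% c("null", "stage_only"),
                        0, config$effect_size)
  truth <- data.frame(contig_id = contig_id,
                      effect_class = effect_class,
                      effect_size = effect_size,
                      active_stages = vapply(active, paste, "", collapse = ","),
                      stringsAsFactors = FALSE)

  n_probes_per_contig <- sample(1:6, n, replace = TRUE,
                                prob = config$probes_per_contig_prob)
  probe_contig <- rep(contig_id, times = n_probes_per_contig)
  n_tp <- length(probe_contig)
  probe_contig <- c(probe_contig, rep("RANDOM", config$n_random_probes))
  n_probes <- length(probe_contig)
  probe_id <- sprintf("probe%06d", seq_len(n_probes))

  # random placement on a square-ish grid (identical layout on every subarray)
  side <- ceiling(sqrt(n_probes))
  pos <- sample(side * side, n_probes)
  x <- (pos - 1L) %% side
  y <- (pos - 1L) %/% side

  n_samp <- nrow(design)
  stage_idx <- match(design$stage, stage_levels())

  # per-contig components
  baseline <- stats::rnorm(n, config$baseline_mean, config$sigma_baseline)
  # stage random walk, carried only by stage_only contigs
  walk <- matrix(0, n, length(stage_levels()))
  is_stage <- effect_class == "stage_only"
  if (any(is_stage)) {
    steps <- matrix(stats::rnorm(sum(is_stage) * (length(stage_levels()) - 1L),
                                 0, config$sigma_stage),
                    nrow = sum(is_stage))
    walk[is_stage, -1L] <- t(apply(steps, 1L, cumsum))
  }

  # planted-effect indicator per sample (0/1), by class
  red <- as.numeric(design$color == "red")
  yellow <- as.numeric(design$color == "yellow")
  prox <- as.numeric(design$wing == "forewing" & design$section == "proximal")
  dist <- as.numeric(design$wing == "forewing" & design$section == "distal")
  hyb <- as.numeric(design$wing == "forewing" & design$morph == "hybrid")
  late <- as.numeric(design$stage %in% config$active_stages_color)
  indicator <- matrix(0, n, n_samp)
  ind_by_class <- list(proximal_up = prox, distal_up = dist,
                       color_red_up = red * late,
                       color_yellow_up = yellow * late,
                       morph_global = hyb)
  for (cl in names(ind_by_class)) {
    rows <- effect_class == cl
    if (any(rows)) {
      indicator[rows, ] <- matrix(ind_by_class[[cl]], sum(rows), n_samp,
                                  byrow = TRUE)
    }
  }

  # individual random effect, shared by the sections of one wing
  individuals <- unique(design$individual)
  ind_eff <- matrix(stats::rnorm(n * length(individuals), 0,
                                 config$sigma_individual),
                    n, length(individuals))
  ind_idx <- match(design$individual, individuals)

  # contig-level log2 mean per sample
  contig_mu <- matrix(baseline, n, n_samp) +
    walk[, stage_idx, drop = FALSE] +
    indicator * effect_size +
    ind_eff[, ind_idx, drop = FALSE]

  probe_offset <- stats::rnorm(n_probes, 0, config$sigma_probe_offset)
  rand_baseline <- stats::rnorm(config$n_random_probes,
                                config$baseline_mean, config$sigma_baseline)

  contig_row <- match(probe_contig, contig_id)  # NA for RANDOM
  m <- matrix(NA_real_, n_probes, n_samp)
  tp <- !is.na(contig_row)
  m[tp, ] <- contig_mu[contig_row[tp], , drop = FALSE]
  m[!tp, ] <- matrix(rand_baseline, config$n_random_probes, n_samp)
  m <- m + probe_offset +
    matrix(stats::rnorm(n_probes * n_samp, 0, config$sigma_probe),
           n_probes, n_samp)

  art <- config$slide_artifact
  if (!is.null(art)) {
    s <- art$sample
    col_idx <- if (is.numeric(s)) as.integer(s) else match(s, design$sample_id)
    if (anyNA(col_idx)) stop("slide_artifact references unknown sample(s)")
    in_block <- x >= art$x[1] & x <= art$x[2] & y >= art$y[1] & y <= art$y[2]
    m[in_block, col_idx] <- m[in_block, col_idx] + art$bias
  }

  intensity <- data.frame(probe_id = probe_id, x = x, y = y,
                          contig_id = probe_contig,
                          stringsAsFactors = FALSE)
  intensity <- cbind(intensity,
                     as.data.frame(2^m, col.names = design$sample_id))
  names(intensity)[-(1:4)] <- design$sample_id

  probemap <- data.frame(probe_id = probe_id[tp],
                         contig_id = probe_contig[tp],
                         stringsAsFactors = FALSE)
  list(intensity = intensity, probemap = probemap, truth = truth)
}
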