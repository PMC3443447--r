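FW_SECTIONS <- c("proximal", "medial", "distal")
HW_RACES <- c("emma", "favorinus", "amphitrite")
COLOR_LEVELS <- c("red", "yellow", "black")

#' Specify a per-contig ANOVA model and its contrast family
#'
#' Presets mirror the study's analyses. Blocking factors stand in for the
#' original mixed-model "random effects" and are fitted as fixed blocks in
#' OLS; with these balanced designs the within-stage cell-mean contrasts are
#' unchanged.
#'
#' \describe{
#'   \item{section_within_stage}{forewing data; Stage, Wing Section and
#'     Stage*Wing Section fixed with Morph as a block; contrasts are the
#'     three section pairs within each stage (pooling morphs).}
#'   \item{color_within_stage}{combined forewing+hindwing data; Color, Stage
#'     and Color*Stage fixed; contrasts are the three color pairs within each
#'     stage.}
#'   \item{pairwise_forewing}{forewing data; Morph, Stage, Wing Section and
#'     Morph*Stage*Wing Section fixed with Slide as a block; contrasts are,
#'     within each stage, section pairs within a morph and the same section
#'     between morphs (9 per stage).}
#'   \item{pairwise_hindwing}{hindwing data; Morph (race), Stage and
#'     Morph*Stage fixed with Slide as a block; contrasts are the three race
#'     pairs within each stage.}
#'   \item{group}{a minimal one-way layout on a \code{group} column of the
#'     design; all group pairs are contrasted (used for calibration and
#'     closed-form checks).}
#' }
#'
#' @param family One of the preset names above.
#' @return An object of class \code{"model_spec"} with the model formula,
#'   the cell (tissue-within-stage) definition, and the contrast registry
#'   builder.
#' @export
model_spec <- function(family = c("section_within_stage", "color_within_stage",
                                  "pairwise_forewing", "pairwise_hindwing",
                                  "group")) {
  family <- match.arg(family)
  spec <- switch(family,
    section_within_stage = list(
      formula = ~ morph + stage * section,
      wing = "forewing",
      cell_fun = function(d) paste(d$stage, d$section, sep = ":"),
      pairs_fun = function(d) .pairs_within_stage(d, FW_SECTIONS,
                                                  function(d) d$section)),
    color_within_stage = list(
      formula = ~ color * stage,
      wing = NULL,
      cell_fun = function(d) paste(d$stage, d$color, sep = ":"),
      pairs_fun = function(d) .pairs_within_stage(d, COLOR_LEVELS,
                                                  function(d) d$color)),
    pairwise_forewing = list(
      formula = ~ slide + morph + stage + section + morph:stage:section,
      wing = "forewing",
      cell_fun = function(d) paste(d$stage,
                                   paste(d$morph, d$section, sep = "."),
                                   sep = ":"),
      pairs_fun = function(d) {
        tissues <- as.vector(outer(c("petiverana", "hybrid"), FW_SECTIONS,
                                   paste, sep = "."))
        tis <- function(d) paste(d$morph, d$section, sep = ".")
        reg <- .pairs_within_stage(d, tissues, tis)
        # retain section pairs within a morph, or same section across morphs
        ma <- sub("\\..*", "", reg$tissue_a); mb <- sub("\\..*", "", reg$tissue_b)
        sa <- sub(".*\\.", "", reg$tissue_a); sb <- sub(".*\\.", "", reg$tissue_b)
        reg[(ma == mb & sa != sb) | (ma != mb & sa == sb), , drop = FALSE]
      }),
    pairwise_hindwing = list(
      formula = ~ slide + morph * stage,
      wing = "hindwing",
      cell_fun = function(d) paste(d$stage, d$morph, sep = ":"),
      pairs_fun = function(d) .pairs_within_stage(d, HW_RACES,
                                                  function(d) d$morph)),
    group = list(
      formula = ~ group,
      wing = NULL,
      cell_fun = function(d) as.character(d$group),
      pairs_fun = function(d) {
        g <- sort(unique(as.character(d$group)))
        if (length(g) < 2) return(NULL)
        pr <- utils::combn(g, 2)
        data.frame(comparison_id = paste0(pr[1, ], "_vs_", pr[2, ]),
                   stage = NA_character_,
                   cell_a = pr[1, ], cell_b = pr[2, ],
                   tissue_a = pr[1, ], tissue_b = pr[2, ],
                   stringsAsFactors = FALSE)
      })
  )
  spec$family <- family
  class(spec) <- "model_spec"
  spec
}

# all ordered tissue pairs within each stage present in the design
.pairs_within_stage <- function(design, levels_order, tissue_fun) {
  stages <- stage_levels()[stage_levels() %in% unique(design$stage)]
  tissues <- levels_order[levels_order %in% unique(tissue_fun(design))]
  if (length(tissues) < 2 || length(stages) < 1) return(NULL)
  pr <- utils::combn(tissues, 2)
  reg <- expand.grid(pair = seq_len(ncol(pr)), stage = stages,
                     stringsAsFactors = FALSE)
  data.frame(
    comparison_id = paste0(reg$stage, ":", pr[1, reg$pair], "_vs_",
                           pr[2, reg$pair]),
    stage = reg$stage,
    cell_a = paste(reg$stage, pr[1, reg$pair], sep = ":"),
    cell_b = paste(reg$stage, pr[2, reg$pair], sep = ":"),
    tissue_a = pr[1, reg$pair], tissue_b = pr[2, reg$pair],
    stringsAsFactors = FALSE)
}

#' Contrast registry for a model family
#'
#' The closed set of within-stage pairwise comparisons a model family tests,
#' as realized on a given design. The registry is fixed before any p-value is
#' computed, and FDR adjustment pools exactly the registry's comparisons.
#'
#' @param spec A [model_spec()].
#' @param design Design table.
#' @return data.frame(comparison_id, stage, cell_a, cell_b, tissue_a,
#'   tissue_b).
#' @export
comparison_registry <- function(spec, design) {
  if (!is.null(spec$wing)) design <- design[design$wing == spec$wing, ]
  spec$pairs_fun(design)
}

#' Per-contig factorial ANOVA with within-stage pairwise contrasts
#'
#' Fits the family's fixed-plus-blocking design to every contig by ordinary
#' least squares and tests each registry comparison as a t-test on cell means
#' using the residual variance and residual degrees of freedom of the full
#' model. Contigs with missing samples are fitted on their complete cases.
#' A comparison whose cells cannot both be estimated is reported missing with
#' a reason; a contig with (numerically) zero residual variance has all its
#' contrasts flagged degenerate with p = 1.
#'
#' @param expr Expression matrix (contigs x samples, log2 scale).
#' @param design Design table covering the columns of \code{expr}.
#' @param spec A [model_spec()].
#' @param adjust Adjust p-values (BH within this run's registry)? The
#'   pipeline disables this when pooling several runs into one family.
#' @return data.frame with one row per contig x comparison: \code{contig_id},
#'   \code{comparison_id}, \code{stage}, \code{estimate} (log2 difference,
#'   tissue_a minus tissue_b), \code{statistic} (t), \code{df} (residual),
#'   \code{p}, \code{q}, \code{note}.
#' @export
fit_anova <- function(expr, design, spec, adjust = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$wing)) design <- design[design$wing == spec$wing, ]
  design <- design[design$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(design) == 0) stop("design has no samples matching expr columns")
  reg <- comparison_registry(spec, design)
  if (is.null(reg) || nrow(reg) == 0) stop("empty comparison registry")
  Y <- t(expr[, design$sample_id, drop = FALSE])  # samples x contigs
  dd <- design
  for (cn in intersect(c("morph", "stage", "section", "slide", "color",
                         "group"), names(dd))) {
    dd[[cn]] <- factor(dd[[cn]])
  }
  X <- stats::model.matrix(spec$formula, dd)
  cells <- spec$cell_fun(design)

  n_contig <- ncol(Y)
  contigs <- colnames(Y)
  complete <- colSums(is.na(Y)) == 0

  s2 <- rep(NA_real_, n_contig)
  dfres <- rep(NA_real_, n_contig)
  cell_names <- sort(unique(cells))
  mean_mat <- matrix(NA_real_, length(cell_names), n_contig,
                     dimnames = list(cell_names, contigs))
  count_mat <- matrix(0, length(cell_names), n_contig,
                      dimnames = list(cell_names, contigs))

  if (any(complete)) {
    fit <- stats::lm.fit(X, Y[, complete, drop = FALSE])
    rk <- fit$rank
    res <- as.matrix(fit$residuals)
    dfres[complete] <- nrow(X) - rk
    s2[complete] <- colSums(res^2) / (nrow(X) - rk)
    mean_mat[, complete] <- rowsum(Y[, complete, drop = FALSE],
                                   cells)[cell_names, , drop = FALSE] /
      as.vector(table(cells)[cell_names])
    count_mat[, complete] <- as.vector(table(cells)[cell_names])
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[, i])
    Xi <- X[ok, , drop = FALSE]
    yi <- Y[ok, i]
    if (sum(ok) >= 2) {
      fi <- stats::lm.fit(Xi, yi)
      dfres[i] <- sum(ok) - fi$rank
      s2[i] <- if (dfres[i] > 0) sum(fi$residuals^2) / dfres[i] else NA_real_
    }
    tb <- tapply(yi, factor(cells[ok], levels = cell_names), mean)
    mean_mat[, i] <- tb
    count_mat[, i] <- table(factor(cells[ok], levels = cell_names))
  }

  ia <- match(reg$cell_a, cell_names)
  ib <- match(reg$cell_b, cell_names)
  n_cmp <- nrow(reg)

  est <- mean_mat[ia, , drop = FALSE] - mean_mat[ib, , drop = FALSE]
  na_ct <- count_mat[ia, , drop = FALSE]
  nb_ct <- count_mat[ib, , drop = FALSE]
  se <- sqrt(outer(rep(1, n_cmp), s2) * (1 / na_ct + 1 / nb_ct))
  tstat <- est / se
  dfm <- outer(rep(1, n_cmp), dfres)
  p <- 2 * stats::pt(-abs(tstat), dfm)

  note <- matrix(NA_character_, n_cmp, n_contig)
  empty <- na_ct == 0 | nb_ct == 0
  note[empty] <- "empty_cell"
  degen <- outer(rep(TRUE, n_cmp), !is.na(s2) & s2 < 1e-12)
  degen <- degen & !empty
  p[degen] <- 1
  tstat[degen] <- 0
  note[degen] <- "degenerate"
  nodf <- outer(rep(TRUE, n_cmp), is.na(dfres) | dfres <= 0) & !empty & !degen
  p[nodf] <- NA_real_
  note[nodf] <- "no_residual_df"

  out <- data.frame(
    contig_id = rep(contigs, each = n_cmp),
    comparison_id = rep(reg$comparison_id, n_contig),
    stage = rep(reg$stage, n_contig),
    estimate = as.vector(est),
    statistic = as.vector(tstat),
    df = as.vector(dfm),
    p = as.vector(p),
    q = NA_real_,
    note = as.vector(note),
    stringsAsFactors = FALSE)
  if (adjust) {
    ok <- !is.na(out$p)
    out$q[ok] <- adjust_fdr(out$p[ok])
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in p rank. Thin validated wrapper
#' around \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvals Numeric vector of raw p-values, all in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
adjust_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Classify proximal-distal differential genes
#'
#' From the section-within-stage contrast family, retains contigs with any
#' within-stage section comparison at \code{q <= fdr} and classifies each by
#' the sign pattern of its section means over the significant stages:
#' proximal above distal gives \code{higher_proximal}, distal above proximal
#' gives \code{higher_distal}; when the proximal and distal means are equal
#' to within 1e-9 the contig is \code{medial_vs_peripheral} if the medial
#' section differs from the ends, and dropped as unclassifiable otherwise.
#'
#' @param results Contrast results from
#'   \code{fit_anova(..., model_spec("section_within_stage"))}.
#' @param fdr FDR threshold (default 0.01).
#' @return data.frame(contig_id, pattern, stages_significant) where
#'   \code{stages_significant} is a comma-joined stage subset.
#' @export
proximal_distal_genes <- function(results, fdr = 0.01) {
  sig <- results[!is.na(results$q) & results$q <= fdr, , drop = FALSE]
  empty <- data.frame(contig_id = character(), pattern = character(),
                      stages_significant = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  out <- lapply(split(sig, sig$contig_id), function(g) {
    stages <- sort(unique(g$stage))
    sub <- results[results$contig_id == g$contig_id[1] &
                     results$stage %in% stages, , drop = FALSE]
    pd <- mean(sub$estimate[grepl("proximal_vs_distal", sub$comparison_id)],
               na.rm = TRUE)
    pm <- mean(sub$estimate[grepl("proximal_vs_medial", sub$comparison_id)],
               na.rm = TRUE)
    if (is.finite(pd) && abs(pd) > 1e-9) {
      pattern <- if (pd > 0) "higher_proximal" else "higher_distal"
    } else if (is.finite(pm) && abs(pm) > 1e-9) {
      pattern <- "medial_vs_peripheral"
    } else {
      return(NULL)  # unclassifiable
    }
    data.frame(contig_id = g$contig_id[1], pattern = pattern,
               stages_significant = paste(
                 stage_levels()[stage_levels() %in% stages], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
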