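#' Condition-mean expression profiles
#'
#' Collapses the expression matrix to per-condition means, a condition being
#' a (wing, morph, section, stage) cell of the design. A contig missing in
#' every sample of a condition is mean-imputed with its own grand mean so
#' profiles carry no missing cells.
#'
#' @param expr Expression matrix (contigs x samples, log2 scale).
#' @param design Design table covering the columns of \code{expr}.
#' @param conditions Optional character vector of condition labels to
#'   require; a requested condition with no samples is an error.
#' @return Numeric matrix contigs x conditions with attribute
#'   \code{"conditions"}: a data.frame(condition, wing, morph, section,
#'   stage, color).
#' @export
build_profiles <- function(expr, design, conditions = NULL) {
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  cond <- paste(design$wing, design$morph, design$section, design$stage,
                sep = ".")
  if (!is.null(conditions)) {
    absent <- setdiff(conditions, cond)
    if (length(absent) > 0) {
      stop("condition(s) with no samples: ", paste(absent, collapse = ", "))
    }
  }
  present <- !is.na(expr)
  e0 <- ifelse(present, expr, 0)
  sums <- t(rowsum(t(e0), cond))
  counts <- t(rowsum(t(present + 0), cond))
  prof <- sums / counts
  if (any(counts == 0)) {
    gm <- rowMeans(expr, na.rm = TRUE)
    prof[counts == 0] <- gm[row(prof)[counts == 0]]
  }
  meta <- unique(data.frame(condition = cond, wing = design$wing,
                            morph = design$morph, section = design$section,
                            stage = design$stage, color = design$color,
                            stringsAsFactors = FALSE))
  meta <- meta[match(colnames(prof), meta$condition), , drop = FALSE]
  rownames(meta) <- NULL
  attr(prof, "conditions") <- meta
  prof
}

# Weighted Newman modularity of a partition (self-weights excluded).
.modularity <- function(W, membership) {
  m2 <- sum(W)  # = 2m for an undirected weight matrix with zero diagonal
  if (m2 <= 0) return(0)
  k <- rowSums(W)
  q <- 0
  for (mod in unique(membership)) {
    i <- membership == mod
    q <- q + sum(W[i, i]) / m2 - (sum(k[i]) / m2)^2
  }
  q
}

#' Modularity clustering of condition-mean profiles
#'
#' Clusters genes by similarity of their condition-mean expression profiles
#' in the modulated-modularity style: the gene-gene adjacency is
#' \eqn{w_{ij} = |\rho_{ij}|^s} with \eqn{\rho} the Spearman correlation of
#' profiles, the sharpness exponent s is chosen from a grid to maximize the
#' achieved Newman modularity, and modules are grown by greedy agglomeration
#' (merge the pair with the largest positive modularity gain; ties broken by
#' the lexicographically smallest module pair, so the output is deterministic
#' and invariant to input order). Constant (zero-variance) profiles are set
#' aside as singleton modules and recorded in the \code{"log"} attribute.
#'
#' @param profiles Profile matrix from [build_profiles()] (>= 2 contigs).
#' @param sharpness_grid Candidate sharpness exponents (default 1, 2, 4, 8).
#' @param seed Unused (the algorithm is deterministic); accepted so callers
#'   can treat all stages uniformly.
#' @return data.frame(contig_id, module_id) sorted by contig_id, with
#'   attributes \code{"modularity"}, \code{"sharpness"} and \code{"log"}.
#' @export
mmc_cluster <- function(profiles, sharpness_grid = c(1, 2, 4, 8),
                        seed = NULL) {
  if (nrow(profiles) < 2) {
    if (nrow(profiles) == 1) {
      out <- data.frame(contig_id = rownames(profiles), module_id = "M01",
                        stringsAsFactors = FALSE)
      attr(out, "modularity") <- 0
      attr(out, "sharpness") <- sharpness_grid[1]
      attr(out, "log") <- character(0)
      return(out)
    }
    stop("need at least one contig to cluster")
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  vr <- apply(profiles, 1, stats::var)
  flat <- vr < 1e-18
  log_lines <- if (any(flat)) {
    paste0("constant profile, assigned singleton module: ",
           rownames(profiles)[flat])
  } else character(0)
  act <- rownames(profiles)[!flat]
  best <- NULL
  if (length(act) >= 2) {
    rho <- stats::cor(t(profiles[act, , drop = FALSE]), method = "spearman")
    rho[is.na(rho)] <- 0
    diag(rho) <- 0
    for (s in sharpness_grid) {
      W <- abs(rho)^s
      memb <- .greedy_modularity(W)
      q <- .modularity(W, memb)
      if (is.null(best) || q > best$q + 1e-12) {
        best <- list(q = q, s = s, memb = memb)
      }
    }
    membership <- best$memb
  } else {
    membership <- rep(1L, length(act))
    best <- list(q = 0, s = sharpness_grid[1])
  }
  # relabel modules in order of first (lexicographic) member, singletons last
  all_ids <- c(act, rownames(profiles)[flat])
  all_memb <- c(membership, if (any(flat)) max(c(membership, 0L)) +
                  seq_len(sum(flat)) else integer(0))
  first_member <- tapply(all_ids, all_memb, min)
  new_label <- match(all_memb, names(sort(first_member)))
  out <- data.frame(contig_id = all_ids,
                    module_id = sprintf("M%02d", new_label),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "modularity") <- best$q
  attr(out, "sharpness") <- best$s
  attr(out, "log") <- log_lines
  out
}

# Greedy agglomerative modularity maximization on a weight matrix whose rows
# are ordered lexicographically by contig id. Modules are identified by their
# smallest row index; ties in the merge gain are broken by the smallest
# (i, j) pair in that ordering.
.greedy_modularity <- function(W) {
  n <- nrow(W)
  m2 <- sum(W)
  if (m2 <= 0) return(seq_len(n))
  memb <- seq_len(n)
  E <- W / m2          # inter-module weight fractions
  a <- rowSums(W) / m2 # degree fractions
  alive <- rep(TRUE, n)
  repeat {
    # gain of merging modules i < j: 2 * (E[i,j] - a_i a_j)
    G <- 2 * (E - outer(a, a))
    G[!alive, ] <- -Inf
    G[, !alive] <- -Inf
    G[lower.tri(G, diag = TRUE)] <- -Inf
    gmax <- max(G)
    if (!is.finite(gmax) || gmax <= 1e-12) break
    hit <- which(G >= gmax - 1e-15, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[i, i] <- 0  # self-weight never enters the gain
    a[i] <- a[i] + a[j]
    alive[j] <- FALSE
    E[j, ] <- 0; E[, j] <- 0; a[j] <- 0
    memb[memb == j] <- i
  }
  memb
}

# Oriented red-vs-non-red tissue pairs realized by a condition set: forewing
# section pairs within a morph, same-section cross-morph pairs, and hindwing
# race pairs, kept when the two tissues differ in color and exactly one is
# red; the red tissue is listed first.
.red_tissue_pairs <- function(meta) {
  tis <- unique(meta[, c("wing", "morph", "section", "color")])
  tis$id <- paste(tis$wing, tis$morph, tis$section, sep = ".")
  if (nrow(tis) < 2) return(NULL)
  pr <- utils::combn(nrow(tis), 2)
  a <- tis[pr[1, ], ]; b <- tis[pr[2, ], ]
  fam_ok <- (a$wing == "forewing" & b$wing == "forewing" &
               (a$morph == b$morph | a$section == b$section)) |
            (a$wing == "hindwing" & b$wing == "hindwing")
  red_one <- (a$color == "red") + (b$color == "red") == 1 & a$color != b$color
  keep <- fam_ok & red_one
  if (!any(keep)) return(NULL)
  a <- a[keep, ]; b <- b[keep, ]
  swap <- b$color == "red"
  data.frame(red = ifelse(swap, b$id, a$id),
             other = ifelse(swap, a$id, b$id),
             stringsAsFactors = FALSE)
}

#' Per-module summary against the color phenotype
#'
#' For each module the mean profile is contrasted against the color
#' phenotype at the ommochrome and melanin stages, at the resolution of the
#' study's red-vs-non-red tissue pairs (each pair oriented red tissue minus
#' non-red tissue). A stage supports the module when every pair contrast
#' reaches the floor \code{eps} with a single shared sign; the module is
#' consistent when at least one pigment stage supports it and no two
#' supporting stages disagree in sign. This is what removes genes whose
#' differential expression follows the proximal-distal axis or a whole-morph
#' difference rather than color: such profiles leave some red-vs-non-red
#' pair flat or flip its sign. The aggregate red-minus-black contrast per
#' pigment stage is reported for reference.
#'
#' @param modules Module assignment from [mmc_cluster()].
#' @param profiles Profile matrix (with its \code{"conditions"} attribute).
#' @param eps Consistency floor in log2 units (default 0.5).
#' @param pigment_stages Stages at which the contrast is assessed.
#' @return data.frame(module_id, size, contrast_ommo, contrast_mela,
#'   consistent, direction) where direction is "upregulated",
#'   "downregulated" or NA.
#' @export
module_summary <- function(modules, profiles, eps = 0.5,
                           pigment_stages = c("OMMO", "MELA")) {
  meta <- attr(profiles, "conditions")
  if (is.null(meta)) stop("profiles must carry a 'conditions' attribute")
  pairs <- .red_tissue_pairs(meta)
  cond_of <- function(tissue, st) {
    i <- which(paste(meta$wing, meta$morph, meta$section, sep = ".") ==
                 tissue & meta$stage == st)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  rows <- lapply(split(modules$contig_id, modules$module_id), function(ids) {
    mp <- colMeans(profiles[ids, , drop = FALSE])
    agg <- vapply(pigment_stages, function(st) {
      red <- meta$color == "red" & meta$stage == st
      black <- meta$color == "black" & meta$stage == st
      if (!any(red) || !any(black)) return(NA_real_)
      mean(mp[red]) - mean(mp[black])
    }, 0)
    verdict <- vapply(pigment_stages, function(st) {
      if (is.null(pairs)) return(NA_real_)
      pc <- mapply(function(r, o) {
        ir <- cond_of(r, st); io <- cond_of(o, st)
        if (is.na(ir) || is.na(io)) NA_real_ else mp[ir] - mp[io]
      }, pairs$red, pairs$other)
      pc <- pc[!is.na(pc)]
      if (length(pc) == 0) return(NA_real_)
      if (all(pc >= eps)) 1 else if (all(pc <= -eps)) -1 else 0
    }, 0)
    v <- verdict[!is.na(verdict) & verdict != 0]
    consistent <- length(v) > 0 && (all(v > 0) || all(v < 0))
    direction <- if (!consistent) NA_character_
                 else if (v[1] > 0) "upregulated" else "downregulated"
    data.frame(size = length(ids),
               contrast_ommo = agg[match("OMMO", pigment_stages)],
               contrast_mela = agg[match("MELA", pigment_stages)],
               consistent = consistent, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- cbind(data.frame(module_id = names(rows),
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Remove candidates inconsistent with the color phenotype
#'
#' A candidate contig is kept iff its module's mean profile shows a
#' red-minus-black contrast of magnitude at least \code{eps} during the
#' ommochrome or melanin stage, with a single consistent sign across those
#' stages. The output never adds contigs: it is a subset of the candidates.
#'
#' @param candidates data.frame(contig_id, source) from
#'   [combine_with_anova()] (or any data.frame with a contig_id column).
#' @param modules Module assignment from [mmc_cluster()] covering the
#'   candidates.
#' @param profiles Profile matrix used for clustering.
#' @param eps Consistency floor in log2 units (default 0.5).
#' @return The candidate rows that survive, with columns \code{module_id}
#'   and \code{direction} appended; the module summary is attached as
#'   attribute \code{"modules"}.
#' @export
filter_inconsistent <- function(candidates, modules, profiles, eps = 0.5) {
  summ <- module_summary(modules, profiles, eps = eps)
  mod_of <- modules$module_id[match(candidates$contig_id, modules$contig_id)]
  keep <- summ$consistent[match(mod_of, summ$module_id)]
  keep[is.na(keep)] <- FALSE
  out <- candidates[keep, , drop = FALSE]
  out$module_id <- mod_of[keep]
  out$direction <- summ$direction[match(out$module_id, summ$module_id)]
  rownames(out) <- NULL
  attr(out, "modules") <- summ
  out
}
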