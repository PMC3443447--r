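#' Score configuration for the capped Fisher filter
#'
#' @param cap Lower cap applied to each p-value before log-summation
#'   (default 1e-4, close to the global FDR threshold); prevents a single
#'   overwhelmingly significant comparison from dominating the sum.
#' @param p0 Per-comparison retention p (default 0.01): the retention
#'   threshold is the score obtained if every comparison had p = p0.
#' @return List of class \code{"score_config"}.
#' @export
score_config <- function(cap = 1e-4, p0 = 0.01) {
  if (!(cap > 0 && cap < p0 && p0 < 1)) stop("need 0 < cap < p0 < 1")
  structure(list(cap = cap, p0 = p0), class = "score_config")
}

#' Capped Fisher score
#'
#' Combines the p-values of a designed comparison set as
#' \deqn{S = -2 \sum_i \ln \max(p_i, cap)}
#' i.e. Fisher's method for p-value summation with small p-values floored at
#' the cap. Missing comparisons contribute \eqn{\ln(1) = 0} (conservative;
#' missing data never manufacture evidence) and their count is attached as
#' the \code{"n_missing"} attribute.
#'
#' @param pvals Numeric vector, one p per comparison-set member; values in
#'   (0, 1], NA allowed for missing comparisons.
#' @param config A [score_config()].
#' @return The score S (numeric scalar) with attribute \code{n_missing}.
#' @export
fisher_score <- function(pvals, config = score_config()) {
  miss <- is.na(pvals)
  if (any(pvals[!miss] <= 0) || any(pvals[!miss] > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p <- pmax(pvals[!miss], config$cap)
  structure(-2 * sum(log(p)), n_missing = sum(miss))
}

#' Retention threshold for the capped Fisher score
#'
#' The score value obtained if every one of the k comparisons had exactly
#' p = p0: \eqn{T = -2 k \ln(p0)}. Scores strictly above T are retained.
#'
#' @param k Number of comparisons in the set (>= 1).
#' @param config A [score_config()].
#' @return The threshold T.
#' @export
score_threshold <- function(k, config = score_config()) {
  if (k < 1) stop("k must be >= 1")
  -2 * k * log(config$p0)
}

#' Retain contigs whose score exceeds the threshold
#'
#' @param scores Named numeric vector of capped Fisher scores (names are
#'   contig ids).
#' @param T Retention threshold from [score_threshold()].
#' @return Character vector of retained contig ids, ranked by score
#'   descending (strictly greater than T).
#' @export
retain_by_score <- function(scores, T) {
  kept <- scores[scores > T]
  names(kept)[order(-kept, names(kept))]
}

#' The red-consistency comparison set
#'
#' The tissue-pair comparisons in which a truly red-specific gene must show
#' differential expression: every registry pair whose two tissues differ in
#' color with exactly one of them red. On the full design this realizes the
#' study's eight pairs — red vs black and red vs yellow hindwing races, the
#' hybrid proximal section against its medial and distal sections, the
#' petiverana medial section against its proximal and distal sections, and
#' the same-section cross-morph pairs for the proximal and medial sections —
#' and excludes all yellow-vs-black and black-vs-black pairs.
#'
#' @param design Design table (used to resolve tissue colors).
#' @param per_stage If TRUE, members are (pair, stage) comparison ids across
#'   all stages; if FALSE, one member id per pair (stage prefix dropped).
#' @return data.frame(comparison_id, stage, pair_id) listing the members.
#' @export
red_consistency_set <- function(design, per_stage = TRUE) {
  members <- NULL
  for (fam in c("pairwise_forewing", "pairwise_hindwing")) {
    spec <- model_spec(fam)
    d <- design[design$wing == spec$wing, , drop = FALSE]
    if (nrow(d) == 0) next
    reg <- comparison_registry(spec, design)
    if (is.null(reg)) next
    col_of <- function(tissue) {
      if (fam == "pairwise_hindwing") {
        tissue_color("hindwing", tissue, "whole")
      } else {
        tissue_color("forewing", sub("\\..*", "", tissue),
                     sub(".*\\.", "", tissue))
      }
    }
    ca <- vapply(reg$tissue_a, col_of, "")
    cb <- vapply(reg$tissue_b, col_of, "")
    keep <- (ca == "red") + (cb == "red") == 1 & ca != cb
    members <- rbind(members, reg[keep, c("comparison_id", "stage"),
                                  drop = FALSE])
  }
  if (is.null(members) || nrow(members) == 0) {
    stop("design realizes no red-consistency comparisons")
  }
  members$pair_id <- sub("^[^:]*:", "", members$comparison_id)
  rownames(members) <- NULL
  if (!per_stage) members <- members[!duplicated(members$pair_id),
                                     c("comparison_id", "pair_id")]
  members
}

#' Score contigs against the red-consistency set
#'
#' Applies the capped Fisher filter to pairwise-contrast results. Only
#' contigs already significant (q <= entry_fdr) in at least one pairwise
#' comparison enter scoring. By default the per-stage p-values of each
#' tissue pair are first collapsed into one p per pair by classical Fisher
#' combination (chi-square with 2x the number of observed stages degrees of
#' freedom), and the capped sum then runs over the k = 8 pairs; set
#' \code{collapse_stages = FALSE} to sum over every (pair, stage) member
#' instead. Missing member p-values contribute 1.
#'
#' @param results Pooled pairwise contrast results (forewing + hindwing) with
#'   q-values from one family-wide adjustment.
#' @param set Comparison set from [red_consistency_set()].
#' @param config A [score_config()].
#' @param entry_fdr Significance gate on the pairwise family for a contig to
#'   be scored at all.
#' @param collapse_stages Collapse per-stage p-values per pair before the
#'   capped sum (default TRUE).
#' @return data.frame(contig_id, S, T, k, n_missing, retained), ranked by S
#'   descending, with the entry-gated contig list as attribute
#'   \code{"entered"}.
#' @export
color_scores <- function(results, set, config = score_config(),
                         entry_fdr = 0.01, collapse_stages = TRUE) {
  sig <- unique(results$contig_id[!is.na(results$q) & results$q <= entry_fdr])
  sub <- results[results$contig_id %in% sig &
                   results$comparison_id %in% set$comparison_id, , drop = FALSE]
  pair_of <- set$pair_id[match(sub$comparison_id, set$comparison_id)]
  k <- if (collapse_stages) length(unique(set$pair_id)) else nrow(set)
  T <- score_threshold(k, config)
  rows <- lapply(split(seq_len(nrow(sub)), sub$contig_id), function(ix) {
    p <- sub$p[ix]
    if (collapse_stages) {
      pp <- tapply(p, pair_of[ix], function(v) {
        v <- v[!is.na(v)]
        if (length(v) == 0) return(NA_real_)
        stats::pchisq(-2 * sum(log(v)), df = 2 * length(v),
                      lower.tail = FALSE)
      })
      # pairs entirely absent from the results still count toward k, p = 1
      p <- as.numeric(pp)
      n_miss <- sum(is.na(p)) + (k - length(p))
    } else {
      idx <- match(set$comparison_id, sub$comparison_id[ix])
      p <- sub$p[ix][idx]
      n_miss <- sum(is.na(p))
    }
    S <- as.numeric(fisher_score(p, config))
    data.frame(contig_id = sub$contig_id[ix[1]], S = S, T = T, k = k,
               n_missing = n_miss, retained = S > T,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), S = numeric(), T = numeric(),
                      k = integer(), n_missing = integer(),
                      retained = logical(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(-out$S, out$contig_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "entered") <- sig
  out
}

#' Combine score-retained contigs with color-ANOVA hits
#'
#' Set union of the two candidate routes, tagging each contig with its
#' source: the capped-Fisher score, the color ANOVA, or both.
#'
#' @param score_retained Character vector of contigs retained by the score.
#' @param anova_color_hits Character vector of contigs significant in the
#'   color ANOVA (color pair within stage, q <= FDR).
#' @return data.frame(contig_id, source) with source in
#'   \{"score", "anova", "both"\}, sorted by contig_id.
#' @export
combine_with_anova <- function(score_retained, anova_color_hits) {
  ids <- sort(unique(c(score_retained, anova_color_hits)))
  source <- ifelse(ids %in% score_retained & ids %in% anova_color_hits,
                   "both",
                   ifelse(ids %in% score_retained, "score", "anova"))
  data.frame(contig_id = ids, source = source, stringsAsFactors = FALSE)
}
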