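#' Spatial quality-control masking
#'
#' Screens every array for regions of uneven intensity. The subarray grid is
#' tiled into \code{window x window} cells; a cell whose mean log2 intensity
#' deviates from the array median by more than \code{z_threshold} robust SDs
#' (MAD of the cell means) has all of its probes set to missing. Arrays whose
#' masked fraction exceeds \code{max_masked_fraction} are flagged for rerun,
#' mirroring the lab practice of re-hybridizing arrays with large uneven
#' regions.
#'
#' @param raw Intensity table (columns probe_id, x, y, contig_id, then one
#'   positive intensity column per sample).
#' @param window Cell side length in probes; must not exceed the grid
#'   extent. The default (NULL) picks \code{min(16, grid/8)} probes (at
#'   least 4), so the robust scale is always estimated from a few dozen
#'   cells whatever the array size.
#' @param z_threshold Robust z cutoff for a cell to be masked.
#' @param max_masked_fraction Masked-probe fraction above which an array is
#'   flagged \code{"rerun"}.
#' @return A list: \code{masked} (the intensity table with masked probes set
#'   to NA) and \code{report}, a data.frame per array with
#'   \code{masked_fraction}, \code{flag} ("ok"/"rerun"), and intensity
#'   quantiles (q01, q25, q50, q75, q99 of log2 intensity) for transcript and
#'   RANDOM probes.
#' @export
qc_mask <- function(raw, window = NULL, z_threshold = 4,
                    max_masked_fraction = 0.25) {
  stopifnot(all(c("probe_id", "x", "y", "contig_id") %in% names(raw)))
  samples <- setdiff(names(raw), c("probe_id", "x", "y", "contig_id"))
  gx <- max(raw$x) - min(raw$x) + 1L
  gy <- max(raw$y) - min(raw$y) + 1L
  if (is.null(window)) window <- max(4L, min(16L, min(gx, gy) %/% 8L))
  if (window > gx || window > gy) {
    stop("QC window (", window, ") exceeds grid extent (", gx, " x ", gy, ")")
  }
  cell <- interaction(raw$x %/% window, raw$y %/% window, drop = TRUE)
  out <- raw
  rows <- vector("list", length(samples))
  is_random <- raw$contig_id == "RANDOM"
  for (j in seq_along(samples)) {
    s <- samples[j]
    v <- log2(raw[[s]])
    cm <- tapply(v, cell, mean, na.rm = TRUE)
    center <- stats::median(v, na.rm = TRUE)
    scale <- stats::mad(cm, na.rm = TRUE)
    bad_cells <- names(cm)[!is.na(cm) & scale > 0 &
                             abs(cm - center) / scale > z_threshold]
    bad <- as.character(cell) %in% bad_cells
    out[[s]][bad] <- NA_real_
    q <- stats::quantile(v[!is_random], c(0.01, 0.25, 0.5, 0.75, 0.99),
                         na.rm = TRUE, names = FALSE)
    qr <- stats::quantile(v[is_random], c(0.01, 0.25, 0.5, 0.75, 0.99),
                          na.rm = TRUE, names = FALSE)
    mf <- mean(bad)
    rows[[j]] <- data.frame(sample_id = s, masked_fraction = mf,
                            flag = if (mf > max_masked_fraction) "rerun"
                                   else "ok",
                            q01 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
                            q99 = q[5],
                            random_q50 = qr[3],
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(masked = out, report = report)
}

#' Log2 transformation and reference-array loess normalization
#'
#' Log2-transforms each array and removes intensity-dependent trends by loess
#' against a reference pseudo-array (the probe-wise mean of all log2 arrays):
#' for each array, M = array - reference is regressed on A = (array +
#' reference)/2 with a loess curve fitted on the transcript probes only
#' (RANDOM control probes are excluded from the fit but are still
#' transformed), and the fitted trend is subtracted. After normalization the
#' MA trend of every array against the reference is approximately zero.
#'
#' @param masked Intensity table (positive intensities, NA allowed), or a
#'   table already on the log2 scale if \code{log2_input = TRUE}.
#' @param span Loess span (default 0.5, degree-1 local regression via
#'   \code{limma::loessFit}).
#' @param log2_input Set TRUE when the intensity columns already hold log2
#'   values (e.g. to re-apply normalization to its own output).
#' @param iterations Number of passes; the reference pseudo-array is
#'   recomputed between passes, so the result is (numerically) a fixed
#'   point of the procedure.
#' @return The intensity table with the sample columns replaced by normalized
#'   log2 values.
#' @export
log2_loess_normalize <- function(masked, span = 0.5, log2_input = FALSE,
                                 iterations = 3) {
  samples <- setdiff(names(masked), c("probe_id", "x", "y", "contig_id"))
  if (length(samples) < 2) stop("need at least two arrays to normalize")
  m <- as.matrix(masked[, samples, drop = FALSE])
  if (!log2_input) {
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-positive intensity for probe ",
           masked$probe_id[bad[1, 1]], " in array ", samples[bad[1, 2]])
    }
    m <- log2(m)
  }
  transcript <- masked$contig_id != "RANDOM"
  w <- as.numeric(transcript)
  for (it in seq_len(iterations)) {
    ref <- rowMeans(m, na.rm = TRUE)
    for (j in seq_along(samples)) {
      A <- (m[, j] + ref) / 2
      M <- m[, j] - ref
      ok <- !is.na(A) & !is.na(M)
      fit <- rep(NA_real_, length(A))
      fit[ok] <- limma::loessFit(M[ok], A[ok], weights = w[ok],
                                 span = span)$fitted
      m[, j] <- m[, j] - fit
    }
  }
  out <- masked
  out[, samples] <- m
  out
}

#' Summarize probe-level values to contig expression
#'
#' Expression of each transcript contig is the arithmetic mean of its
#' non-missing probe values; a contig with all probes missing in a sample is
#' missing there. RANDOM control probes are never summarized.
#'
#' @param norm Normalized intensity table (log2 scale) from
#'   [log2_loess_normalize()].
#' @param probemap data.frame(probe_id, contig_id) mapping every transcript
#'   probe to exactly one contig. Defaults to the mapping carried in the
#'   table's \code{contig_id} column.
#' @return Numeric matrix, contigs x samples, of log2 expression.
#' @export
summarize_probes <- function(norm, probemap = NULL) {
  samples <- setdiff(names(norm), c("probe_id", "x", "y", "contig_id"))
  tab <- norm[norm$contig_id != "RANDOM", , drop = FALSE]
  if (is.null(probemap)) {
    contig <- tab$contig_id
  } else {
    idx <- match(tab$probe_id, probemap$probe_id)
    if (anyNA(idx)) {
      stop("probe(s) not present in probemap: ",
           paste(utils::head(tab$probe_id[is.na(idx)], 3), collapse = ", "))
    }
    contig <- probemap$contig_id[idx]
  }
  m <- as.matrix(tab[, samples, drop = FALSE])
  present <- !is.na(m)
  m0 <- ifelse(present, m, 0)
  sums <- rowsum(m0, contig)
  counts <- rowsum(present + 0, contig)
  expr <- sums / counts  # 0/0 -> NaN where all probes missing
  expr[counts == 0] <- NA_real_
  expr
}
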