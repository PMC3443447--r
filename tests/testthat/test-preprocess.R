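# grid fixture: n probes on a side x side grid with given log2 means
grid_table <- function(log2_vals, side = 40, n_random = 0) {
  n <- side * side
  stopifnot(ncol(log2_vals) >= 1, nrow(log2_vals) == n)
  contig <- c(rep(sprintf("c%04d", seq_len(n - n_random)), 1),
              rep("RANDOM", n_random))
  data.frame(probe_id = sprintf("p%05d", seq_len(n)),
             x = (seq_len(n) - 1L) %% side,
             y = (seq_len(n) - 1L) %/% side,
             contig_id = contig,
             as.data.frame(2^log2_vals),
             stringsAsFactors = FALSE)
}

test_that("spatially uniform arrays are left unmasked", {
  set.seed(1)
  side <- 40
  m <- matrix(stats::rnorm(side * side * 3, mean = 8, sd = 0.3), ncol = 3,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  res <- qc_mask(grid_table(m, side), window = 8, z_threshold = 4)
  expect_equal(sum(is.na(res$masked[, c("s1", "s2", "s3")])), 0)
  expect_true(all(res$report$flag == "ok"))
  expect_true(all(res$report$masked_fraction == 0))
})

test_that("a planted rectangular artifact is masked and only it", {
  cfg <- generator_config(n_contigs = 1200, n_random_probes = 300, seed = 9,
                          slide_artifact = list(sample = 1L, x = c(0, 15),
                                                y = c(0, 15), bias = 2.0))
  d <- generate_design(cfg)
  sim <- simulate_intensities(d, cfg)
  res <- qc_mask(sim$intensity, window = 8, z_threshold = 4)
  s1 <- d$sample_id[1]
  in_block <- sim$intensity$x <= 15 & sim$intensity$y <= 15
  masked <- is.na(res$masked[[s1]])
  expect_gte(mean(masked[in_block]), 0.95)
  expect_lte(mean(masked[!in_block]), 0.01)
  # other arrays essentially untouched
  others <- setdiff(d$sample_id, s1)
  expect_lte(max(colMeans(is.na(res$masked[, others]))), 0.01)
})

test_that("arrays with large uneven regions are flagged for rerun", {
  set.seed(2)
  side <- 20
  m <- matrix(stats::rnorm(side * side * 2, 8, 0.1), ncol = 2,
              dimnames = list(NULL, c("ok_array", "bad_array")))
  # uneven region covering 37.5% of the grid, aligned to 5x5 windows
  xg <- (seq_len(side * side) - 1L) %% side
  yg <- (seq_len(side * side) - 1L) %/% side
  bad_region <- yg < 5 | (yg < 10 & xg < 10)
  m[bad_region, 2] <- m[bad_region, 2] + 3
  res <- qc_mask(grid_table(m, side), window = 5, z_threshold = 3,
                 max_masked_fraction = 0.25)
  expect_equal(res$report$flag[res$report$sample_id == "bad_array"], "rerun")
  expect_equal(res$report$flag[res$report$sample_id == "ok_array"], "ok")
})

test_that("QC window larger than the grid is rejected", {
  set.seed(3)
  m <- matrix(stats::rnorm(100, 8, 0.1), ncol = 1,
              dimnames = list(NULL, "s1"))
  expect_error(qc_mask(grid_table(m, 10), window = 11), "grid")
})

test_that("identical arrays normalize to their plain log2", {
  set.seed(4)
  side <- 30
  base <- stats::rnorm(side * side, 8, 1)
  m <- matrix(base, ncol = 3, nrow = side * side,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  tab <- grid_table(m, side)
  norm <- log2_loess_normalize(tab, span = 0.5)
  expect_equal(as.matrix(norm[, c("s1", "s2", "s3")]), m,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a 2x global scale factor is removed by normalization", {
  set.seed(5)
  side <- 40
  a <- stats::rnorm(side * side, 8, 1)
  m <- cbind(A = a, B = a + 1)  # array B = 2 x array A on the linear scale
  tab <- grid_table(m, side)
  norm <- log2_loess_normalize(tab, span = 0.5)
  expect_lt(mean(abs(norm$B - norm$A)), 0.01)
  # independent oracle: direct MA-lowess computation at span 0.5
  ref <- rowMeans(m)
  ora <- sapply(c("A", "B"), function(s) {
    M <- m[, s] - ref; A <- (m[, s] + ref) / 2
    fit <- stats::lowess(A, M, f = 0.5)
    m[, s] - stats::approx(fit$x, fit$y, xout = A, rule = 2)$y
  })
  expect_lt(mean(abs(as.matrix(norm[, c("A", "B")]) - ora)), 0.02)
})

test_that("post-normalization MA trends are flat for distorted arrays", {
  # arrays that differ by scale factors and smooth intensity-dependent
  # distortions (the regime loess normalization targets): after
  # normalization the refitted MA trend of every array is flat everywhere
  set.seed(14)
  side <- 50
  truth <- stats::runif(side * side, 5, 11)
  m <- sapply(1:8, function(j) {
    truth + stats::rnorm(side * side, 0, 0.05) +
      stats::runif(1, -0.5, 0.5) +
      stats::runif(1, -0.15, 0.15) * (truth - 8) +
      stats::runif(1, -0.2, 0.2) * sin((truth - 8) / 2)
  })
  colnames(m) <- paste0("s", 1:8)
  norm <- log2_loess_normalize(grid_table(m, side, n_random = 100),
                               span = 0.5)
  nm <- as.matrix(norm[, colnames(m)])
  ref <- rowMeans(nm, na.rm = TRUE)
  tp <- norm$contig_id != "RANDOM"
  worst <- max(sapply(colnames(m), function(s) {
    M <- nm[tp, s] - ref[tp]; A <- (nm[tp, s] + ref[tp]) / 2
    ok <- !is.na(M) & !is.na(A)
    fit <- stats::lowess(A[ok], M[ok], f = 0.5)
    grid <- seq(min(A[ok]), max(A[ok]), length.out = 100)
    max(abs(stats::approx(fit$x, fit$y, xout = grid, rule = 2)$y))
  }))
  expect_lt(worst, 0.05)
})

test_that("normalization is idempotent in its own regime", {
  # arrays differing only by smooth intensity-dependent trends, with probe
  # noise below the smoother's resolution: re-applying normalization to the
  # normalized output changes essentially nothing
  set.seed(6)
  side <- 60
  truth <- stats::runif(side * side, 5, 11)
  m <- cbind(s1 = truth,
             s2 = truth + 0.04 * (truth - 8),
             s3 = truth - 0.04 * (truth - 8) + 0.02 * sin(truth - 8)) +
    stats::rnorm(side * side * 3, 0, 0.003)
  colnames(m) <- c("s1", "s2", "s3")
  tab <- grid_table(m, side)
  n1 <- log2_loess_normalize(tab, span = 0.5)
  n2 <- log2_loess_normalize(n1, span = 0.5, log2_input = TRUE)
  cols <- c("s1", "s2", "s3")
  expect_lt(max(abs(as.matrix(n2[, cols]) - as.matrix(n1[, cols]))), 1e-3)
})

test_that("non-positive intensities are rejected with the probe id", {
  set.seed(7)
  m <- matrix(stats::rnorm(200, 8, 0.5), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  tab <- grid_table(m, 10)
  tab$s1[5] <- -1
  expect_error(log2_loess_normalize(tab), tab$probe_id[5])
})

test_that("probe summarization takes missing-aware means per contig", {
  tab <- data.frame(probe_id = paste0("p", 1:7),
                    x = 0:6, y = 0L,
                    contig_id = c("cA", "cA", "cA", "cB", "cC", "cC", "RANDOM"),
                    s1 = c(2, 4, 6, 7, 3, NA, 99),
                    s2 = c(3, NA, 5, 1, NA, NA, 99),
                    stringsAsFactors = FALSE)
  ex <- summarize_probes(tab)
  expect_equal(ex["cA", "s1"], 4)        # plain mean
  expect_equal(ex["cB", "s1"], 7)        # single probe
  expect_equal(ex["cA", "s2"], 4)        # missing-aware mean
  expect_true(is.na(ex["cC", "s2"]))     # all probes missing
  expect_false("RANDOM" %in% rownames(ex))
  # probe mapped to unknown contig is rejected
  pm <- data.frame(probe_id = paste0("p", 1:5),
                   contig_id = c("cA", "cA", "cA", "cB", "cC"),
                   stringsAsFactors = FALSE)
  expect_error(summarize_probes(tab, pm), "probemap")
})

test_that("summarization commutes with row-constant shifts", {
  sim <- small_sim()
  tab <- sim$intensity
  samples <- sim$design$sample_id
  tab[, samples] <- log2(tab[, samples])
  e1 <- summarize_probes(tab)
  shifted <- tab
  target <- shifted$contig_id == "contig00001"
  shifted[target, samples] <- shifted[target, samples] + 2.5
  e2 <- summarize_probes(shifted)
  expect_equal(e2["contig00001", ], e1["contig00001", ] + 2.5)
  other <- rownames(e1) != "contig00001"
  expect_equal(e2[other, ], e1[other, ])
})

test_that("masked probes never contribute to a contig mean", {
  sim <- small_sim()
  tab <- sim$intensity
  samples <- sim$design$sample_id
  tab[, samples] <- log2(tab[, samples])
  probes <- which(tab$contig_id == "contig00002")
  e1 <- summarize_probes(tab)
  tab[probes[1], samples[1]] <- NA
  e2 <- summarize_probes(tab)
  manual <- mean(unlist(tab[probes[-1], samples[1]]))
  if (length(probes) > 1) {
    expect_equal(unname(e2["contig00002", samples[1]]), manual)
  } else {
    expect_true(is.na(e2["contig00002", samples[1]]))
  }
})
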