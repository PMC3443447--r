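# profile matrix with a planted block structure; rows get a shared base
# pattern per block plus noise
block_profiles <- function(sizes, n_cond = 45, noise = 0.2, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rnorm(length(sizes) * n_cond, 0, 1),
                 nrow = length(sizes))
  prof <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    t(replicate(sizes[b], base[b, ] + stats::rnorm(n_cond, 0, noise)))
  }))
  rownames(prof) <- sprintf("g%03d", seq_len(nrow(prof)))
  colnames(prof) <- sprintf("cond%02d", seq_len(n_cond))
  list(profiles = prof, labels = rep(seq_along(sizes), sizes))
}

test_that("condition means define the profiles", {
  design <- data.frame(
    sample_id = c("a1", "a2", "b1"),
    wing = "hindwing", morph = c("emma", "emma", "favorinus"),
    section = "whole", stage = c("D1", "D1", "D1"),
    individual = c("i1", "i2", "i3"), slide = "s1",
    color = c("red", "red", "yellow"), stringsAsFactors = FALSE)
  expr <- matrix(c(1, 3, 5,
                   2, 2, 9), nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), design$sample_id))
  prof <- build_profiles(expr, design)
  expect_equal(unname(prof["c1", "hindwing.emma.whole.D1"]), 2)  # mean(1,3)
  expect_equal(unname(prof["c1", "hindwing.favorinus.whole.D1"]), 5)
  # identical per-sample values give identical profiles
  expr2 <- rbind(c1 = c(1, 3, 5), c3 = c(1, 3, 5))
  colnames(expr2) <- design$sample_id
  prof2 <- build_profiles(expr2, design)
  expect_equal(unname(prof2["c1", ]), unname(prof2["c3", ]))
  # a requested condition with no samples is rejected
  expect_error(build_profiles(expr, design,
                              conditions = "hindwing.amphitrite.whole.D1"),
               "no samples")
})

test_that("perfect two-block structure yields exactly two modules", {
  # within-block Spearman correlation 1 (affine copies), between-block 0
  v1 <- c(1, 2, 3, 4)
  v2 <- c(2, 4, 1, 3)  # rank correlation with v1 is exactly 0
  prof <- rbind(t(sapply(1:20, function(i) i * v1 + i)),
                t(sapply(1:20, function(i) i * v2 - i)))
  rownames(prof) <- sprintf("g%02d", 1:40)
  colnames(prof) <- paste0("cond", 1:4)
  mod <- mmc_cluster(prof)
  expect_equal(length(unique(mod$module_id)), 2)
  truth <- rep(1:2, each = 20)[match(mod$contig_id,
                                     sprintf("g%02d", 1:40))]
  expect_equal(length(unique(paste(mod$module_id, truth))), 2)
})

test_that("a single contig forms one singleton module", {
  prof <- matrix(1:5, 1, dimnames = list("g1", paste0("c", 1:5)))
  mod <- mmc_cluster(prof)
  expect_equal(nrow(mod), 1)
  expect_equal(length(unique(mod$module_id)), 1)
})

test_that("three planted correlation blocks are recovered (ARI >= 0.9)", {
  bp <- block_profiles(c(30, 30, 30), noise = 0.2, seed = 44)
  mod <- mmc_cluster(bp$profiles)
  ari <- mclust::adjustedRandIndex(
    mod$module_id[match(rownames(bp$profiles), mod$contig_id)], bp$labels)
  expect_gte(ari, 0.9)
})

test_that("clustering output is a partition with sane modularity", {
  bp <- block_profiles(c(15, 15, 10), noise = 0.3, seed = 45)
  mod <- mmc_cluster(bp$profiles)
  # partition: every contig exactly once
  expect_setequal(mod$contig_id, rownames(bp$profiles))
  expect_equal(anyDuplicated(mod$contig_id), 0)
  # beats the trivial one-module partition (modularity 0 by definition)
  expect_gte(attr(mod, "modularity"), 0)
  # cross-check the reported modularity with igraph on the same graph
  prof <- bp$profiles[order(rownames(bp$profiles)), ]
  rho <- stats::cor(t(prof), method = "spearman")
  W <- abs(rho)^attr(mod, "sharpness"); diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  memb <- as.integer(factor(mod$module_id[match(rownames(prof),
                                                mod$contig_id)]))
  q_igraph <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  expect_equal(attr(mod, "modularity"), q_igraph, tolerance = 1e-10)
})

test_that("clustering is deterministic and input-order invariant", {
  bp <- block_profiles(c(12, 12, 12), noise = 0.25, seed = 46)
  m1 <- mmc_cluster(bp$profiles)
  m2 <- mmc_cluster(bp$profiles)
  expect_identical(m1, m2)
  set.seed(1)
  shuffled <- bp$profiles[sample(nrow(bp$profiles)), ]
  m3 <- mmc_cluster(shuffled)
  expect_identical(m1, m3)
})

test_that("constant profiles become logged singleton modules", {
  bp <- block_profiles(c(10, 10), noise = 0.2, seed = 47)
  prof <- rbind(bp$profiles,
                gzzz = rep(2, ncol(bp$profiles)))
  mod <- mmc_cluster(prof)
  expect_true("gzzz" %in% mod$contig_id)
  expect_equal(sum(mod$module_id == mod$module_id[mod$contig_id == "gzzz"]),
               1)
  expect_match(attr(mod, "log"), "gzzz", all = FALSE)
})

test_that("module consistency follows the red-black contrast contract", {
  design <- generate_design(generator_config())
  samples <- design$sample_id
  n_cond <- 45
  # module A: red tissues up by ~1.2 (OMMO) and ~0.9 (MELA) -> kept
  # module B: sign flip between the pigment stages -> removed
  up <- function(delta_o, delta_m) {
    v <- stats::setNames(rep(0, length(samples)), samples)
    v[design$color == "red" & design$stage == "OMMO"] <- delta_o
    v[design$color == "red" & design$stage == "MELA"] <- delta_m
    v
  }
  expr <- rbind(cA1 = up(1.2, 0.9), cA2 = up(1.2, 0.9) + 0.01,
                cB1 = up(0.8, -0.8), cB2 = up(0.8, -0.8) + 0.01)
  prof <- build_profiles(expr, design)
  modules <- data.frame(contig_id = c("cA1", "cA2", "cB1", "cB2"),
                        module_id = c("M01", "M01", "M02", "M02"),
                        stringsAsFactors = FALSE)
  candidates <- data.frame(contig_id = rownames(expr),
                           source = "score", stringsAsFactors = FALSE)
  final <- filter_inconsistent(candidates, modules, prof, eps = 0.5)
  expect_setequal(final$contig_id, c("cA1", "cA2"))
  expect_true(all(final$direction == "upregulated"))
  summ <- attr(final, "modules")
  expect_equal(summ$contrast_ommo[summ$module_id == "M01"], 1.2,
               tolerance = 1e-6)
  expect_equal(summ$contrast_mela[summ$module_id == "M01"], 0.9,
               tolerance = 1e-6)
  expect_false(summ$consistent[summ$module_id == "M02"])
  # the filter never adds genes
  expect_true(all(final$contig_id %in% candidates$contig_id))
})

test_that("morph-global confounds are purged by the module filter", {
  run <- study_run()
  truth <- run$truth
  confounds <- truth$contig_id[truth$effect_class == "morph_global"]
  leaked <- intersect(confounds, run$candidates$contig_id)
  if (length(leaked) > 0) {
    expect_gte(mean(!(leaked %in% run$final$contig_id)), 0.9)
  }
  expect_false(any(confounds %in% run$final$contig_id))
})
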