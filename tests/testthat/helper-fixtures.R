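# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The seeded study-scale run used by recovery and acceptance tests:
# 2,000 contigs, planted log2 effect 1.5, default noise.
study_config <- function(seed = 101) {
  run_config(seed = seed,
             generator = generator_config(n_contigs = 2000,
                                          n_random_probes = 500,
                                          seed = seed))
}

study_run <- function() cached("study_run", run_pipeline(study_config()))

# A small, fast run for structural/determinism checks.
small_config <- function(seed = 5) {
  run_config(seed = seed,
             generator = generator_config(n_contigs = 150,
                                          n_random_probes = 120,
                                          seed = seed))
}

small_run <- function() cached("small_run", run_pipeline(small_config()))

# Raw simulated tables at small scale (probe level), shared by preprocess
# tests.
small_sim <- function() {
  cached("small_sim", {
    cfg <- generator_config(n_contigs = 150, n_random_probes = 120, seed = 5)
    design <- generate_design(cfg)
    c(simulate_intensities(design, cfg), list(design = design, config = cfg))
  })
}

# Exhaustive Benjamini-Hochberg step-up oracle: q_i = min over j with
# p_(j) >= p_(i) of m * p_(j) / j, computed directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepup <- m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(stepup)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# One-way two-group design for the closed-form contrast checks.
two_group_design <- function(values_a, values_b,
                             names = c("groupA", "groupB")) {
  n <- length(values_a) + length(values_b)
  design <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(names, c(length(values_a), length(values_b))),
    stringsAsFactors = FALSE)
  expr <- matrix(c(values_a, values_b), nrow = 1,
                 dimnames = list("contig1", design$sample_id))
  list(expr = expr, design = design)
}
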