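#' Whole-run configuration
#'
#' Assembles and validates the configuration for one end-to-end pipeline
#' run: generator settings, preprocessing parameters, the FDR and score
#' settings, and clustering parameters. One global seed drives every source
#' of randomness.
#'
#' @param seed Global integer seed.
#' @param generator A [generator_config()]; its seed is overridden by
#'   \code{seed}.
#' @param qc_window,qc_z,qc_max_masked QC masking parameters
#'   (see [qc_mask()]).
#' @param span Loess span for normalization.
#' @param fdr FDR threshold for every contrast family.
#' @param score A [score_config()].
#' @param collapse_stages Stage handling for the capped Fisher score
#'   (see [color_scores()]).
#' @param sharpness_grid,eps Clustering sharpness grid and consistency floor
#'   (see [mmc_cluster()] and [filter_inconsistent()]).
#' @param outdir Optional directory for stage artifacts (TSV/JSON/newick);
#'   NULL keeps everything in memory.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(),
                       qc_window = NULL, qc_z = 4, qc_max_masked = 0.25,
                       span = 0.5,
                       fdr = 0.01,
                       score = score_config(),
                       collapse_stages = TRUE,
                       sharpness_grid = c(1, 2, 4, 8),
                       eps = 0.5,
                       outdir = NULL) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(score, "score_config"),
            fdr > 0, fdr < 1, eps >= 0)
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 qc_window = qc_window, qc_z = qc_z,
                 qc_max_masked = qc_max_masked, span = span, fdr = fdr,
                 score = score, collapse_stages = collapse_stages,
                 sharpness_grid = sharpness_grid, eps = eps,
                 outdir = outdir),
            class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> QC mask -> log2 loess normalization (forewing and
#' hindwing separately, plus a joint normalization for the combined color
#' ANOVA) -> probe summarization -> the three contrast analyses
#' (section-within-stage, color-within-stage, pooled pairwise) -> capped
#' Fisher color scoring -> union with the color-ANOVA hits -> modularity
#' clustering with the phenotype-consistency filter -> recovery scoring
#' against the planted truth. Deterministic under the config seed.
#'
#' @param config A [run_config()].
#' @return List with all stage artifacts: \code{design}, \code{truth},
#'   \code{qc}, \code{expr} (per-wing and joint matrices),
#'   \code{section_results}, \code{pd_genes}, \code{color_results},
#'   \code{anova_color_hits}, \code{pairwise_results}, \code{scores},
#'   \code{candidates}, \code{modules}, \code{final}, and \code{report}
#'   (the recovery report, see [recovery_report()]).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  design <- generate_design(config$generator)
  sim <- simulate_intensities(design, config$generator)

  meta_cols <- c("probe_id", "x", "y", "contig_id")
  split_wing <- function(w) {
    ids <- design$sample_id[design$wing == w]
    sim$intensity[, c(meta_cols, ids), drop = FALSE]
  }
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  qc <- list(); expr <- list(); masked <- list()
  for (w in c("forewing", "hindwing")) {
    raw_w <- split_wing(w)
    qcres <- stage_err(paste0("qc_mask/", w),
                       qc_mask(raw_w, window = config$qc_window,
                               z_threshold = config$qc_z,
                               max_masked_fraction = config$qc_max_masked))
    qc[[w]] <- qcres$report
    masked[[w]] <- qcres$masked
    norm <- stage_err(paste0("normalize/", w),
                      log2_loess_normalize(qcres$masked, span = config$span))
    expr[[w]] <- stage_err(paste0("summarize/", w),
                           summarize_probes(norm, sim$probemap))
  }
  joint_masked <- cbind(masked$forewing,
                        masked$hindwing[, setdiff(names(masked$hindwing),
                                                  meta_cols), drop = FALSE])
  norm_joint <- stage_err("normalize/joint",
                          log2_loess_normalize(joint_masked,
                                               span = config$span))
  expr$joint <- stage_err("summarize/joint",
                          summarize_probes(norm_joint, sim$probemap))

  section_results <- stage_err("fit/section",
    fit_anova(expr$forewing, design, model_spec("section_within_stage")))
  pd_genes <- proximal_distal_genes(section_results, fdr = config$fdr)

  color_results <- stage_err("fit/color",
    fit_anova(expr$joint, design, model_spec("color_within_stage")))
  anova_color_hits <- sort(unique(
    color_results$contig_id[!is.na(color_results$q) &
                              color_results$q <= config$fdr]))

  pw_fw <- stage_err("fit/pairwise_forewing",
    fit_anova(expr$forewing, design, model_spec("pairwise_forewing"),
              adjust = FALSE))
  pw_hw <- stage_err("fit/pairwise_hindwing",
    fit_anova(expr$hindwing, design, model_spec("pairwise_hindwing"),
              adjust = FALSE))
  pairwise <- rbind(pw_fw, pw_hw)
  ok <- !is.na(pairwise$p)
  pairwise$q[ok] <- adjust_fdr(pairwise$p[ok])

  red_set <- red_consistency_set(design)
  scores <- stage_err("colorscore",
    color_scores(pairwise, red_set, config = config$score,
                 entry_fdr = config$fdr,
                 collapse_stages = config$collapse_stages))
  score_retained <- scores$contig_id[scores$retained]
  candidates <- combine_with_anova(score_retained, anova_color_hits)

  if (nrow(candidates) >= 2) {
    profiles <- stage_err("build_profiles",
      build_profiles(expr$joint[candidates$contig_id, , drop = FALSE],
                     design))
    modules <- stage_err("mmc_cluster",
      mmc_cluster(profiles, sharpness_grid = config$sharpness_grid,
                  seed = config$seed))
    final <- stage_err("filter_inconsistent",
      filter_inconsistent(candidates, modules, profiles, eps = config$eps))
  } else {
    profiles <- NULL
    modules <- data.frame(contig_id = candidates$contig_id,
                          module_id = rep("M01", nrow(candidates)),
                          stringsAsFactors = FALSE)
    final <- candidates[0, , drop = FALSE]
  }

  report <- recovery_report(
    truth = sim$truth, pd_genes = pd_genes, final = final,
    entered = attr(scores, "entered"), score_retained = score_retained,
    anova_color_hits = anova_color_hits, candidates = candidates)

  out <- list(design = design, truth = sim$truth, qc = qc, expr = expr,
              section_results = section_results, pd_genes = pd_genes,
              color_results = color_results,
              anova_color_hits = anova_color_hits,
              pairwise_results = pairwise, scores = scores,
              candidates = candidates, modules = modules, final = final,
              report = report)
  if (!is.null(config$outdir)) .write_run_artifacts(out, sim, config)
  out
}

#' Recovery report against the planted truth
#'
#' Summarizes how well the pipeline recovered the generator's planted
#' effects. For the final color list, a discovery is true when its planted
#' class is a color class (\code{color_red_up}, \code{color_yellow_up});
#' for the proximal-distal list, when its class is \code{proximal_up} or
#' \code{distal_up} (those contigs genuinely differ between wing sections).
#' Sensitivities are reported per planted class (NA when no contig of the
#' class was planted). Gate counts follow the score path of the funnel
#' (pairwise-significant, score-retained, post-cluster members of the score
#' branch), which is monotone non-increasing by construction; the
#' color-ANOVA branch and union are reported alongside.
#'
#' @param truth PlantedTruth table from the generator.
#' @param pd_genes Proximal-distal gene list.
#' @param final Final color gene list (post-cluster).
#' @param entered Contigs that entered scoring (pairwise-significant).
#' @param score_retained Contigs retained by the capped Fisher score.
#' @param anova_color_hits Color-ANOVA hit list.
#' @param candidates Union candidate list.
#' @return List with elements \code{gates}, \code{color} (sensitivity per
#'   class, realized FDR) and \code{proximal_distal}.
#' @export
recovery_report <- function(truth, pd_genes, final, entered, score_retained,
                            anova_color_hits, candidates) {
  class_of <- function(ids) {
    truth$effect_class[match(ids, truth$contig_id)]
  }
  sens <- function(list_ids, cls) {
    planted <- truth$contig_id[truth$effect_class == cls]
    if (length(planted) == 0) return(NA_real_)
    mean(planted %in% list_ids)
  }
  fdr_of <- function(list_ids, true_classes) {
    if (length(list_ids) == 0) return(NA_real_)
    mean(!(class_of(list_ids) %in% true_classes))
  }
  final_score_branch <- final$contig_id[final$source %in% c("score", "both")]
  gates <- c(pairwise_significant = length(entered),
             score_retained = length(score_retained),
             post_cluster_score_branch = length(final_score_branch),
             anova_color_hits = length(anova_color_hits),
             union_candidates = nrow(candidates),
             final_list = nrow(final))
  color_classes <- c("color_red_up", "color_yellow_up")
  list(
    gates = gates,
    color = list(
      sensitivity_red = sens(final$contig_id, "color_red_up"),
      sensitivity_yellow = sens(final$contig_id, "color_yellow_up"),
      realized_fdr = fdr_of(final$contig_id, color_classes),
      counts_by_class = table(class_of(final$contig_id))),
    proximal_distal = list(
      sensitivity_proximal = sens(pd_genes$contig_id, "proximal_up"),
      sensitivity_distal = sens(pd_genes$contig_id, "distal_up"),
      realized_fdr = fdr_of(pd_genes$contig_id,
                            c("proximal_up", "distal_up",
                              "color_red_up", "color_yellow_up")),
      counts_by_class = table(class_of(pd_genes$contig_id))))
}

#' Sample-level clustering and PCA diagnostic
#'
#' Average-linkage hierarchical clustering of samples on 1 - Pearson
#' correlation distance, plus the first two principal-component coordinates.
#' With the default generator most expression variance is developmental, so
#' samples cluster by stage first.
#'
#' @param expr Expression matrix (contigs x samples), >= 3 samples.
#' @param design Design table (for labels); optional.
#' @param outdir Optional directory: writes \code{sample_dendrogram.nwk}
#'   (newick) and \code{sample_pca.tsv}.
#' @return List: \code{hclust}, \code{phylo} (ape tree), \code{pca}
#'   (data.frame sample_id, PC1, PC2).
#' @export
sample_clustering_report <- function(expr, design = NULL, outdir = NULL) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  cc <- stats::cor(expr, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  pc <- stats::prcomp(t(expr[stats::complete.cases(expr), , drop = FALSE]),
                      center = TRUE, scale. = FALSE)
  pca <- data.frame(sample_id = colnames(expr),
                    PC1 = pc$x[, 1],
                    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                    stringsAsFactors = FALSE)
  rownames(pca) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(tree, file.path(outdir, "sample_dendrogram.nwk"))
    utils::write.table(pca, file.path(outdir, "sample_pca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(hclust = hc, phylo = tree, pca = pca)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

.write_run_artifacts <- function(out, sim, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  .write_tsv(out$design, p("design.tsv"))
  .write_tsv(sim$intensity, p("intensity.tsv"))
  .write_tsv(out$truth, p("truth.tsv"))
  .write_tsv(out$section_results, p("section_results.tsv"))
  .write_tsv(out$pairwise_results, p("pairwise_results.tsv"))
  .write_tsv(out$scores, p("scores.tsv"))
  .write_tsv(out$final, p("final_color_list.tsv"))
  .write_tsv(out$pd_genes, p("proximal_distal_genes.tsv"))
  .write_tsv(out$modules, p("modules.tsv"))
  for (w in names(out$qc)) .write_tsv(out$qc[[w]], p(paste0("qc_", w, ".tsv")))
  ev <- function(x) if (is.table(x)) as.list(x) else x
  jsonlite::write_json(
    list(gates = as.list(out$report$gates),
         color = lapply(out$report$color, ev),
         proximal_distal = lapply(out$report$proximal_distal, ev)),
    p("recovery_report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  ex <- out$expr$joint
  .write_tsv(cbind(data.frame(contig_id = rownames(ex)), as.data.frame(ex)),
             p("expression_joint.tsv"))
  invisible(NULL)
}
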