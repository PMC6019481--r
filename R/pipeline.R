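#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage parameter with the package's defaults: tolerance of
#' the iterative renormalizer, significance level, independence threshold,
#' CUT estimator, redundant-spot correction, WPR aggregation, TPR
#' side-effect mode and test scale.
#'
#' @param sim A [sim_config()] for the synthetic stage.
#' @param tol Renormalization tolerance (default 0.05).
#' @param max_iter Renormalization iteration cap (default 100).
#' @param alpha Significance level (default 0.05).
#' @param r_ind Coordination independence threshold (default 0.25).
#' @param cut_estimator `"plain"` or `"chisq"`.
#' @param correction `"bonferroni"` or `"sidak"`.
#' @param wpr_aggregate `"mean"` or `"sum"`.
#' @param adjust_side_effects Logical TPR mode (default FALSE).
#' @param test_scale `"log"` or `"linear"`.
#' @param unprotected Comparison `c(numerator, denominator)` for the insult
#'   without protection (default COS vs CON).
#' @param protected Comparison for the insult under protection (default CES
#'   vs CEN).
#' @param coordination_conditions Conditions to build edge tables for
#'   (default the two numerators' baselines, CEN and CES).
#' @param gmt Path to a GMT file of pathway gene sets (default the packaged
#'   fixture).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       tol = 0.05, max_iter = 100, alpha = 0.05,
                       r_ind = 0.25,
                       cut_estimator = c("plain", "chisq"),
                       correction = c("bonferroni", "sidak"),
                       wpr_aggregate = c("mean", "sum"),
                       adjust_side_effects = FALSE,
                       test_scale = c("log", "linear"),
                       unprotected = c("COS", "CON"),
                       protected = c("CES", "CEN"),
                       coordination_conditions = c("CEN", "CES"),
                       gmt = NULL) {
  structure(list(
    sim = sim, tol = tol, max_iter = max_iter, alpha = alpha, r_ind = r_ind,
    cut_estimator = match.arg(cut_estimator),
    correction = match.arg(correction),
    wpr_aggregate = match.arg(wpr_aggregate),
    adjust_side_effects = adjust_side_effects,
    test_scale = match.arg(test_scale),
    unprotected = unprotected, protected = protected,
    coordination_conditions = coordination_conditions,
    gmt = if (is.null(gmt)) pathway_fixture() else gmt
  ), class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline: simulate, normalize, regulate, score, coordinate
#'
#' Chains every stage on a synthetic experiment and writes all outputs plus
#' a machine-readable run manifest (package version, parameters and file
#' digests) to a result directory. Deterministic given the simulation seed.
#'
#' @param config A [run_config()].
#' @param out_dir Result directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results: `experiment`,
#'   `em`, `regulation` (list per comparison), `scores`, `edges` (list per
#'   condition), `switches`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) {
    stop("config must be built with run_config()", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pipeline_log("simulate", "generating synthetic experiment (seed %d, %d genes)",
               config$sim$seed, config$sim$n_genes)
  exp <- simulate_experiment(config$sim)
  write_tsv(exp$spots, file.path(out_dir, "spots.tsv"))
  write_tsv(exp$design, file.path(out_dir, "design.tsv"))
  write_tsv(exp$truth$regulation, file.path(out_dir, "truth_regulation.tsv"))
  write_tsv(exp$truth$coordination,
            file.path(out_dir, "truth_coordination.tsv"))
  write_tsv(exp$truth$expression, file.path(out_dir, "truth_expression.tsv"))

  pipeline_log("normalize", "normalizing %d spots", nrow(exp$spots))
  em <- normalize_spots(exp$spots, exp$design, tol = config$tol,
                        max_iter = config$max_iter)
  pipeline_log("normalize", "converged in %d iterations (final delta %.4f)",
               attr(em, "iterations"), attr(em, "final_delta"))
  write_expr_matrix(em, out_dir)

  comparisons <- list(unprotected = config$unprotected,
                      protected = config$protected)
  regulation <- lapply(comparisons, function(cmp) {
    pipeline_log("regulate", "%s vs %s", cmp[1], cmp[2])
    reg <- regulate(em, cmp[1], cmp[2], alpha = config$alpha,
                    test_scale = config$test_scale,
                    cut_estimator = config$cut_estimator,
                    correction = config$correction)
    write_tsv(reg, file.path(out_dir,
                             sprintf("regulation_%s_vs_%s.tsv", cmp[1], cmp[2])))
    reg
  })

  pipeline_log("pathway-scores", "scoring %s", basename(config$gmt))
  gene_sets <- read_gmt(config$gmt)
  scores <- pathway_scores(gene_sets, regulation$unprotected,
                           regulation$protected,
                           aggregate = config$wpr_aggregate,
                           adjust_side_effects = FALSE)
  write_tsv(scores, file.path(out_dir, "pathway_scores.tsv"))

  shared_genes <- complete_genes(em, config$coordination_conditions)
  edges <- lapply(config$coordination_conditions, function(cond) {
    pipeline_log("coordination", "condition %s", cond)
    e <- coordination_edges(em, cond, genes = shared_genes,
                            alpha = config$alpha,
                            r_ind = config$r_ind, scale = config$test_scale)
    write_tsv(e, file.path(out_dir, sprintf("edges_%s.tsv", cond)))
    e
  })
  names(edges) <- config$coordination_conditions

  switches <- NULL
  if (length(edges) >= 2) {
    pipeline_log("switches", "%s -> %s", names(edges)[1], names(edges)[2])
    switches <- detect_switches(edges[[1]], edges[[2]])
    write_tsv(switches, file.path(out_dir, "switches.tsv"))
  }

  manifest <- list(
    package = "pathprotect",
    version = as.character(utils::packageVersion("pathprotect")),
    seed = config$sim$seed,
    parameters = list(
      n_genes = config$sim$n_genes,
      n_replicates = config$sim$n_replicates,
      tol = config$tol, alpha = config$alpha, r_ind = config$r_ind,
      cut_estimator = config$cut_estimator, correction = config$correction,
      wpr_aggregate = config$wpr_aggregate, test_scale = config$test_scale,
      unprotected = paste(config$unprotected, collapse = "_vs_"),
      protected = paste(config$protected, collapse = "_vs_")
    ),
    renormalization = list(iterations = attr(em, "iterations"),
                           final_delta = attr(em, "final_delta")),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.tsv$")))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(experiment = exp, em = em, regulation = regulation,
                 scores = scores, edges = edges, switches = switches))
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$planted_regulation)) {
    sim_args$planted_regulation <-
      as.data.frame(do.call(rbind, lapply(sim_args$planted_regulation,
                                          as.data.frame)))
  }
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  y$sim <- NULL
  do.call(run_config, c(list(sim = sim), y))
}
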