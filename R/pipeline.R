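# End-to-end orchestration: DE-table combination -> feature selection ->
# network construction -> module detection -> permutation significance,
# writing every stage's artifact to a run directory.

#' Pipeline configuration
#'
#' Collects all tunable parameters with the pipeline's standard defaults:
#' stringent feature selection (FDR \\eqn{\\le 10^{-5}}, fold change
#' \\eqn{\\ge} 1.5 i.e. |log2FC| >= 0.59), soft threshold chosen by the
#' scale-free criterion at \\eqn{R^2 = 0.9} over powers 1..20 (or a fixed
#' power), hard edge filter |r| >= 0.7, modularity-density optimization and
#' a 1000-permutation significance test.
#'
#' @param fdr_max FDR cutoff for feature selection.
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @param beta Soft-threshold power, or `"auto"`.
#' @param powers Candidate powers for auto selection.
#' @param target_r2 Scale-free fit target.
#' @param min_abs_cor Hard edge threshold on |r|.
#' @param objective `"density"` or `"modularity"`.
#' @param n_permutations Permutations for the significance test (0 disables).
#' @param null_model `"uniform"` or `"degree"`.
#' @param min_module_size Minimum module size kept as a module.
#' @param seed Global seed.
#' @param sweep_cutoffs Optional FDR grid; when given, [run_pipeline()] also
#'   writes an FDR-sweep table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_max = 1e-5, min_abs_log2fc = 0.59,
                            beta = "auto", powers = 1:20, target_r2 = 0.9,
                            min_abs_cor = 0.7,
                            objective = c("density", "modularity"),
                            n_permutations = 1000L,
                            null_model = c("uniform", "degree"),
                            min_module_size = 1L, seed = 1L,
                            sweep_cutoffs = NULL) {
  structure(list(fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                 beta = beta, powers = powers, target_r2 = target_r2,
                 min_abs_cor = min_abs_cor,
                 objective = match.arg(objective),
                 n_permutations = as.integer(n_permutations),
                 null_model = match.arg(null_model),
                 min_module_size = as.integer(min_module_size),
                 seed = as.integer(seed),
                 sweep_cutoffs = sweep_cutoffs),
            class = "pipeline_config")
}

#' Run the full co-expression module pipeline
#'
#' Combines the DE tables, filters genes, builds the thresholded weighted
#' network on the expression matrix, detects modules, and (optionally) runs
#' the permutation significance test and the FDR sweep. All artifacts are
#' written under `out_dir`:
#' \\itemize{
#'   \\item `combined_de.tsv`, `selected_genes.tsv` — combined and filtered
#'     DE records
#'   \\item `edges.tsv`, `network.graphml` — the thresholded network
#'   \\item `partition.tsv` — gene -> module (0 = unassigned)
#'   \\item `report.json` — objective, Q, Qds, module sizes, soft-threshold
#'     fit, permutation null summary
#'   \\item `fdr_sweep.tsv` — when `sweep_cutoffs` given
#'   \\item `run_log.txt` — effective configuration and session info
#' }
#'
#' @param expr Expression matrix (genes x samples) or path to its TSV.
#' @param de_tables List of [de_table()] objects, or character vector of TSV
#'   paths.
#' @param out_dir Output directory (created if absent).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `selected`, `graph`, `detection`,
#'   `significance` (`NULL` when disabled), `sweep` (`NULL` unless
#'   requested), and `out_dir`.
#' @export
run_pipeline <- function(expr, de_tables, out_dir,
                         config = pipeline_config()) {
  .check(inherits(config, "pipeline_config"), "`config` must be a pipeline_config")
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(de_tables)) de_tables <- lapply(de_tables, read_de_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  combined <- combine_de_tables(de_tables)
  missing_expr <- setdiff(combined$gene_id, rownames(expr))
  if (length(missing_expr)) {
    stop("genes in DE tables absent from expression matrix: ",
         paste(head(missing_expr, 10L), collapse = ", "),
         if (length(missing_expr) > 10L)
           sprintf(" (and %d more)", length(missing_expr) - 10L) else "",
         call. = FALSE)
  }
  selected <- filter_de_genes(combined, fdr_max = config$fdr_max,
                              min_abs_log2fc = config$min_abs_log2fc)
  .check(nrow(selected) >= 3L,
         sprintf("only %d genes pass the filters; need at least 3", nrow(selected)))
  write_combined_de(combined, file.path(out_dir, "combined_de.tsv"))
  write_combined_de(selected, file.path(out_dir, "selected_genes.tsv"))

  expr_sel <- expr[selected$gene_id, , drop = FALSE]
  graph <- build_network(expr_sel, beta = config$beta,
                         min_abs_cor = config$min_abs_cor,
                         powers = config$powers, target_r2 = config$target_r2)
  write_edge_list(graph, file.path(out_dir, "edges.tsv"))
  write_graphml(graph, file.path(out_dir, "network.graphml"))

  detection <- detect_modules(graph, objective = config$objective,
                              seed = config$seed,
                              min_module_size = config$min_module_size)
  write_partition(detection$partition, file.path(out_dir, "partition.tsv"))

  signif <- NULL
  if (config$n_permutations > 0L) {
    signif <- module_significance(graph,
                                  n_permutations = config$n_permutations,
                                  objective = config$objective,
                                  seed = config$seed,
                                  null_model = config$null_model,
                                  min_module_size = config$min_module_size)
  }

  sweep <- NULL
  if (!is.null(config$sweep_cutoffs)) {
    sweep <- fdr_sweep(combined, expr, cutoffs = config$sweep_cutoffs,
                       min_abs_log2fc = config$min_abs_log2fc,
                       beta = config$beta, min_abs_cor = config$min_abs_cor,
                       objective = config$objective,
                       min_module_size = config$min_module_size,
                       seed = config$seed)
    write.table(sweep, file.path(out_dir, "fdr_sweep.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fit <- attr(graph, "soft_threshold_fit")
  report <- list(
    n_genes_selected = nrow(selected),
    beta = if (!is.null(fit)) fit$beta else config$beta,
    beta_r_squared = if (!is.null(fit)) fit$r_squared else NA,
    beta_met_target = if (!is.null(fit)) fit$met_target else NA,
    min_abs_cor = config$min_abs_cor,
    n_edges = graph_edge_count(graph),
    objective = detection$objective,
    objective_value = detection$objective_value,
    Q = detection$q,
    Qds = detection$qds,
    n_modules = detection$n_modules,
    n_unassigned = detection$n_unassigned,
    module_sizes = detection$module_sizes,
    significance = if (!is.null(signif)) {
      signif[c("n_permutations", "q_observed", "q_null_mean", "q_null_sd",
               "z_score", "null_model", "degenerate")]
    },
    seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  log_lines <- c(
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("package version: %s", as.character(utils::packageVersion("wgcnam"))),
    sprintf("R version: %s", R.version.string),
    "effective configuration:",
    vapply(names(config), function(k) {
      sprintf("  %s = %s", k, paste(format(config[[k]]), collapse = ", "))
    }, character(1L)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(selected = selected, graph = graph, detection = detection,
                 significance = signif, sweep = sweep, out_dir = out_dir))
}
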