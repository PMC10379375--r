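#' Run the full TI masking-analysis pipeline
#'
#' Orchestrates every stage with one configuration and one seed:
#' simulate (or ingest) -> smooth/select/average curves -> extract the 14
#' TI parameters -> VAS masking scores -> correlation pruning ->
#' top-vs-bottom Mann-Whitney comparison -> standardized PCA + seeded
#' k-means classification. Returns a run report bundling every stage
#' artifact; rerunning with the same config and seed reproduces it
#' exactly.
#'
#' Inputs come from `config$inputs` when `curves` and `vas` paths are set
#' there; otherwise a synthetic study is generated from
#' `config$synthetic`.
#'
#' @param config Run configuration (see [default_run_config()]); the
#'   global `config$seed` fans out to deterministic per-stage seeds.
#' @param out_dir Optional directory; when given, all stage artifacts and
#'   the report are written there.
#' @return Object of class `ti_run_report`.
#' @export
run_ti_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  inputs <- config$inputs
  synthetic <- is.null(inputs$curves) || is.null(inputs$vas)
  if (synthetic) {
    study <- stage("simulate", generate_study(config))
    curves <- study$curves
    vas <- study$vas
    materials <- study$materials
    truth <- study$truth
  } else {
    curves <- stage("ingest", read_ti_curves(inputs$curves))
    vas <- stage("ingest", read_vas(inputs$vas))
    materials <- if (!is.null(inputs$materials)) {
      stage("ingest", read_materials(inputs$materials))
    } else {
      NULL
    }
    truth <- NULL
  }

  avg <- stage("curves", process_curves(curves, config))
  params <- stage("extract", extract_ti_parameters(avg, config))
  masking <- stage("score", masking_scores(vas))

  if (!setequal(params$material_id, masking$material_id)) {
    abort("pipeline: curve and VAS tables cover different materials")
  }

  pruned <- stage("prune", prune_correlated(
    params,
    r_threshold = config$stats$r_threshold,
    mode = config$stats$prune_mode
  ))
  comparison <- stage("compare", compare_top_bottom(
    pruned$matrix, masking, k = config$stats$top_bottom_k
  ))
  model <- stage("classify", classify_materials(
    pruned$matrix, masking,
    k = config$classify$k,
    seed = stage_seed(config$seed, "classify"),
    n_init = config$classify$n_init,
    cluster_space = config$classify$cluster_space
  ))
  cluster_summary <- stage("classify", summarize_clusters(model))
  loadings <- loading_report(model)

  counts <- tibble::tibble(
    stage = c("curves", "average_curves", "parameters", "vas", "masking",
              "comparison", "clusters"),
    rows = c(nrow(curves), nrow(avg), nrow(params), nrow(vas), nrow(masking),
             nrow(comparison), nrow(model$labels))
  )
  report <- structure(
    list(
      config = config,
      seed = config$seed,
      synthetic = synthetic,
      counts = counts,
      materials = materials,
      params = params,
      masking = masking,
      retained = pruned$retained,
      exclusions = pruned$exclusions,
      comparison = comparison,
      model = model,
      cluster_summary = cluster_summary,
      loading_report = loadings,
      truth = truth,
      version = as.character(utils::packageVersion("timask"))
    ),
    class = "ti_run_report"
  )
  if (!is.null(out_dir)) {
    write_run_report(report, out_dir)
  }
  report
}

#' Write all artifacts of a pipeline run
#'
#' Stores the parameter matrix, phase annotation, masking scores,
#' comparison table, cluster assignments and loading report as CSV, the
#' model (loadings, explained variance, labels, seed) as JSON, and a
#' human-readable `report.txt`.
#'
#' @param report A `ti_run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_parameter_matrix(report$params, file.path(dir, "params.csv"))
  readr::write_csv(phase_annotation(report$params), file.path(dir, "phases.csv"))
  readr::write_csv(report$masking, file.path(dir, "masking.csv"))
  readr::write_csv(report$comparison, file.path(dir, "comparison.csv"))
  readr::write_csv(report$model$labels, file.path(dir, "clusters.csv"))
  readr::write_csv(report$loading_report, file.path(dir, "loading_report.csv"))
  model <- report$model
  jsonlite::write_json(
    list(
      k = model$k,
      seed = model$seed,
      inertia = model$inertia,
      explained_variance_ratio = model$pca$explained_variance_ratio,
      loadings = data.frame(
        parameter = rownames(model$pca$loadings),
        model$pca$loadings,
        row.names = NULL
      ),
      labels = model$labels,
      retained = report$retained
    ),
    file.path(dir, "model.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  writeLines(format_run_report(report), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Format a run report as human-readable text lines
#'
#' @param report A `ti_run_report`.
#' @return Character vector of report lines.
#' @export
format_run_report <- function(report) {
  fmt_tbl <- function(df) {
    utils::capture.output(print(as.data.frame(df), row.names = FALSE))
  }
  summary_tbl <- report$cluster_summary$clusters |>
    dplyr::mutate(
      mean_masking_score = round(.data$mean_masking_score, 1),
      members = vapply(.data$members, function(m) paste(m, collapse = " "), "")
    )
  c(
    sprintf("timask run report (version %s, seed %d)", report$version, report$seed),
    sprintf("input: %s", if (report$synthetic) "synthetic study" else "supplied CSV tables"),
    "", "row counts per stage:", fmt_tbl(report$counts),
    "", sprintf("retained parameters: %s", paste(report$retained, collapse = ", ")),
    "", "exclusions:", fmt_tbl(report$exclusions),
    "", "top vs bottom masking groups (Mann-Whitney U, two-tailed):",
    fmt_tbl(dplyr::mutate(
      report$comparison,
      p_two_tailed = signif(.data$p_two_tailed, 3)
    )),
    "", sprintf(
      "clusters (k = %d, inertia = %.3f, PC1 %.1f%% / PC2 %.1f%% of variance):",
      report$model$k, report$model$inertia,
      100 * report$model$pca$explained_variance_ratio[1],
      100 * report$model$pca$explained_variance_ratio[2]
    ),
    fmt_tbl(summary_tbl),
    if (!is.null(report$cluster_summary$test)) {
      sprintf(
        "highest-masking cluster %d vs rest: U = %g, p = %.4g",
        report$cluster_summary$test$cluster,
        report$cluster_summary$test$U,
        report$cluster_summary$test$p_two_tailed
      )
    } else {
      report$cluster_summary$note
    },
    "", "PC1 loading magnitudes:",
    fmt_tbl(report$loading_report),
    sprintf(
      "top-two loading ratio: %.2f",
      attr(report$loading_report, "ratio_top2")
    )
  )
}

#' @export
print.ti_run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}
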