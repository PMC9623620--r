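#' Assemble a machine-readable analysis report
#'
#' Flattens an [ftpi_eval()] fit into a plain list mirroring the printed
#' analysis: run metadata (configuration echo, dataset provenance, package
#' version), the descriptive table, the correlation table, the per-test
#' performance table at the optimal cutoffs, the constrained-threshold table,
#' and any fixed-cutoff or borderline-exclusion blocks. The list serializes
#' losslessly to JSON and back.
#'
#' @param fit an [ftpi_eval()] object.
#' @return a named list of data frames and scalars.
#' @seealso [write_report()]
#' @export
report_list <- function(fit) {
  stopifnot(inherits(fit, "ftpi_eval"))
  rep <- list(
    meta = list(package = "ftpidta", version = fit$version,
                provenance = as.list(get_provenance(fit$data) %||% character(0)),
                config = fit$config[!vapply(fit$config, is.null, TRUE)]),
    n_input = fit$n_input, n_analysed = fit$n,
    filter_counts = as.list(fit$filter_counts),
    prevalence = fit$prevalence,
    n_ftpi_pos = fit$n_ftpi_pos, n_ftpi_neg = fit$n_ftpi_neg,
    descriptives = fit$descriptives,
    correlations = fit$correlations,
    performance = fit$performance,
    constrained = fit$constrained)
  if (!is.null(fit$fixed)) rep$fixed <- fit$fixed
  if (!is.null(fit$sensitivity)) {
    rep$sensitivity <- fit$sensitivity
    rep$sensitivity_n_excluded <- attr(fit$sensitivity, "n_excluded")
  }
  rep
}

#' Write the analysis report to disk
#'
#' Writes `report.json` (full machine-readable report, numbers at full
#' precision) and CSV analogues of the three result tables
#' (`descriptives.csv`, `performance.csv`, `constrained.csv`) into a
#' directory.
#'
#' @param fit an [ftpi_eval()] object.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_report <- function(fit, dir) {
  rep <- report_list(fit)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  utils::write.csv(fit$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$constrained, file.path(dir, "constrained.csv"),
                   row.names = FALSE)
  invisible(dir)
}
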