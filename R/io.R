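# Run configuration and report serialization.

run_config_defaults <- function() {
  list(dialect = "methods", atol = 1e-8, rtol = 1e-6,
       report_step = 1, seed = 0, out_dir = ".", verbose = FALSE)
}

#' Load a run configuration
#'
#' Reads a JSON or YAML key-value file; absent keys take defaults
#' (methods dialect, tolerances 1e-8/1e-6, reporting step 1 min, seed 0).
#' Unknown keys are rejected with a nearest-name suggestion.
#'
#' @param path Path to a config file; `NULL` returns pure defaults.
#' @return Named list of class `"pias3net_config"`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      hint <- vapply(unknown, closest_name, character(1),
                     candidates = names(cfg))
      stop("unknown config key(s): ",
           paste(sprintf("'%s' (did you mean '%s'?)", unknown, hint),
                 collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  if (cfg$atol <= 0 || cfg$rtol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(cfg, class = "pias3net_config")
}

#' Save a run configuration
#' @param config A `"pias3net_config"`.
#' @param path Output path (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  vals <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a machine-readable experiment report
#'
#' Serializes a batch result as JSON: per-experiment pass/fail with
#' clause-level diagnostics and readouts, plus the full resolved
#' parameter set and seed for provenance.
#'
#' @param batch A `"pias3net_batch"` from [run_all_experiments()].
#' @param params The parameter vector the batch was run with.
#' @param path Output JSON path.
#' @param seed Seed recorded for provenance (reports themselves are
#'   deterministic).
#' @return `path`, invisibly.
#' @export
write_report <- function(batch, params, path, seed = 0) {
  experiments <- lapply(batch$results, function(r) {
    list(id = r$id,
         pass = if (is.na(r$pass)) NULL else r$pass,
         errored = !is.null(r$error),
         error = r$error,
         readouts = as.list(r$readouts),
         clauses = if (!is.null(r$clauses)) {
           lapply(seq_len(nrow(r$clauses)), function(i) {
             list(what = r$clauses$what[i],
                  value = r$clauses$value[i],
                  pass = r$clauses$pass[i])
           })
         })
  })
  report <- list(
    n_pass = batch$n_pass,
    n_experiments = length(batch$passes),
    failed = as.list(names(batch$passes)[!batch$passes %in% TRUE]),
    seed = seed,
    parameters = as.list(stats::setNames(
      as.numeric(params[c(core_parameter_names(), "RSK1_total")]),
      c(core_parameter_names(), "RSK1_total"))),
    experiments = experiments)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
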