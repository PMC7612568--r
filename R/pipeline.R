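## Config-driven entry points. A run configuration is a plain named list (or
## a YAML file of one) declaring the column schema, model terms, calibration
## method and MSM design; run_pipeline() executes
## load -> fit models -> initial weights -> restrictions -> calibrate ->
## MSM -> diagnostics and writes the artifacts plus a machine-readable run
## log. These functions, together with the exported fitting functions, are
## the package's interface; no shell wrapper is shipped.

parse_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_stage("config", "config must be a list or a path")
  config
}

as_formula_spec <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) > 1L) lapply(x, stats::as.formula)
  else if (is.character(x)) stats::as.formula(x)
  else x
}

validate_run_config <- function(config) {
  for (field in c("input", "schema", "models", "msm"))
    if (is.null(config[[field]]))
      stop_stage("config", "missing '", field, "' block")
  cal <- config$calibration %||% list()
  method <- cal$method %||% "type1"
  if (!method %in% c("type1", "type2", "mle", "unweighted"))
    stop_stage("config", "unknown calibration method '", method, "'")
  if (isTRUE(cal$normalization) && !is.null(config$models$censoring))
    stop_stage("config", "normalization restrictions are redundant given ",
               "censoring restrictions; drop one")
  invisible(config)
}

config_roles <- function(config) {
  s <- config$schema
  panel_roles(id = s$id %||% "id", visit = s$visit %||% "visit",
              in_study = s$in_study %||% "r",
              treatment = unlist(s$treatment) %||% "a",
              outcome = s$outcome %||% "y",
              tv = unlist(s$tv) %||% character(),
              baseline = unlist(s$baseline) %||% character(),
              kind = s$kind %||% "binary")
}

#' Run the full estimation pipeline from a configuration
#'
#' @param config a named list or path to a YAML file with blocks `input`
#'   (`path` to the person-period CSV), `schema` (column roles: `id`,
#'   `visit`, `in_study`, `treatment`, `outcome`, `tv`, `baseline`, `kind`),
#'   `models` (`denominator`, `numerator`, optional `censoring` and `balance`
#'   formulas, as strings), `calibration` (`method`, optional `tol`), `msm`
#'   (`formula`, optional `bootstrap` count and `seed`) and optional `output`
#'   (directory for artifacts).
#' @return The fitted [cbwmsm()] object, invisibly; artifacts (weights,
#'   coefficient table, balance report, run log) are written when an output
#'   directory is configured.
#' @export
run_pipeline <- function(config) {
  config <- parse_config(config)
  validate_run_config(config)
  roles <- config_roles(config)
  table <- read_panel(config$input$path, roles,
                      sep = config$input$sep %||% ",")
  mdl <- config$models
  fit <- cbwmsm(table,
                denominator = as_formula_spec(mdl$denominator),
                numerator = as_formula_spec(mdl$numerator),
                censoring = as_formula_spec(mdl$censoring),
                balance = as_formula_spec(mdl$balance),
                msm = stats::as.formula(config$msm$formula),
                method = config$calibration$method %||% "type1",
                rescale = config$calibration$rescale %||% "none",
                boot = config$msm$bootstrap %||% 0L,
                seed = config$msm$seed %||% 1L,
                control = config$calibration$control %||% list())
  out_dir <- config$output$dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    idx <- uncensored_index(table)
    utils::write.csv(data.frame(id = idx$id, visit = idx$visit,
                                weight = weights(fit)),
                     file.path(out_dir, "weights.csv"), row.names = FALSE)
    ct <- data.frame(term = names(coef(fit)), estimate = unname(coef(fit)))
    if (!is.null(fit$msm$se)) ct$boot_se <- unname(fit$msm$se)
    utils::write.csv(ct, file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    if (!is.null(fit$diagnostics))
      jsonlite::write_json(
        list(residual_norm = fit$diagnostics$residual_norm,
             calibration_factor_variance =
               fit$diagnostics$calibration_factor_variance,
             per_visit = fit$diagnostics$per_visit,
             balance = fit$diagnostics$balance_table),
        file.path(out_dir, "balance.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config_hash = config_hash(config),
           seed = config$msm$seed %||% 1L,
           package_version = as.character(utils::packageVersion("cbwmsm")),
           method = fit$method,
           converged = is.null(fit$calibration) || fit$calibration$converged,
           n = attr(table, "n"), T = attr(table, "T"),
           m = nrow(idx)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}

#' Simulate a scenario from a configuration
#'
#' @param config a named list or YAML path with the [sim_config()] fields
#'   (unknown fields are rejected) and optionally `output.dir`.
#' @param seed integer seed.
#' @return The [generate_scenario()] result, invisibly; the table CSV and a
#'   truth JSON are written when an output directory is configured.
#' @export
run_simulation <- function(config, seed = 1L) {
  config <- parse_config(config)
  out_dir <- config$output$dir
  config$output <- NULL
  known <- names(formals(sim_config))
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop_stage("config", "unknown simulation field(s): ",
               paste(bad, collapse = ", "))
  cfg <- do.call(sim_config, config)
  scn <- generate_scenario(cfg, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel(scn$table, file.path(out_dir, "panel.csv"))
    jsonlite::write_json(
      list(gamma = as.list(scn$truth$gamma), seed = scn$truth$seed,
           config_hash = scn$truth$config_hash),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(scn)
}
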