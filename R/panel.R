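#' Declare column roles for a person-period table
#'
#' Maps the columns of a long-format longitudinal data set onto the roles the
#' estimation machinery needs: patient identifier, integer visit index,
#' in-study indicator, treatment column(s), time-varying covariates, baseline
#' covariates, and the outcome.
#'
#' @param id name of the patient identifier column.
#' @param visit name of the integer visit column (0 = baseline).
#' @param in_study name of the binary in-study indicator column (1 while the
#'   patient remains under follow-up; dropout is monotone).
#' @param treatment treatment column name. For `kind = "ordinal"` a character
#'   vector of length two: the "any treatment" indicator followed by the
#'   "highest level" indicator (the second can be 1 only when the first is).
#' @param outcome name of the longitudinal outcome column.
#' @param tv character vector of time-varying covariate column names.
#' @param baseline character vector of baseline covariate column names
#'   (constant within patient).
#' @param kind treatment scale: `"binary"`, `"ordinal"` (3-level, coded by two
#'   nested indicators), or `"continuous"`.
#' @return An object of class `panel_roles`.
#' @export
panel_roles <- function(id = "id", visit = "visit", in_study = "r",
                        treatment = "a", outcome = "y",
                        tv = character(), baseline = character(),
                        kind = c("binary", "ordinal", "continuous")) {
  kind <- match.arg(kind)
  if (kind == "ordinal" && length(treatment) != 2L)
    stop("ordinal treatment needs two columns: c(any, high)", call. = FALSE)
  if (kind != "ordinal" && length(treatment) != 1L)
    stop("binary/continuous treatment needs a single column", call. = FALSE)
  structure(list(id = id, visit = visit, in_study = in_study,
                 treatment = treatment, outcome = outcome,
                 tv = tv, baseline = baseline, kind = kind),
            class = "panel_roles")
}

treatment_cols <- function(roles) unname(roles$treatment)

## internal fast constructor: attach attributes without re-validating
## (used by the bootstrap, where resampling preserves validity)
new_person_period_table <- function(data, roles, T, n) {
  structure(data, roles = roles, T = T, n = n,
            class = c("person_period_table", "data.frame"))
}

## Fill in rows a file may omit after dropout, so every patient carries
## visits 0..T with in_study = 0 past the dropout visit. Assumes `data` is
## sorted by (id, visit).
materialize_dropout_rows <- function(data, roles, T = NULL) {
  idc <- roles$id; vc <- roles$visit; rc <- roles$in_study
  T <- T %||% max(data[[vc]])
  n <- length(unique(data[[idc]]))
  ## fast path: already a complete 0..T grid
  if (nrow(data) == n * (T + 1) &&
      identical(as.integer(data[[vc]]), rep(0:T, n)))
    return(data)
  if (anyDuplicated(paste(data[[idc]], data[[vc]], sep = "\r")))
    stop_stage("panel", "duplicate (id, visit) rows present")
  split_idx <- split(seq_len(nrow(data)), factor(data[[idc]],
                                                 levels = unique(data[[idc]])))
  add <- list()
  for (pid in names(split_idx)) {
    rows <- split_idx[[pid]]
    vis <- data[[vc]][rows]
    if (!identical(as.integer(vis), seq.int(0L, length(vis) - 1L)))
      stop_stage("panel", "patient ", pid,
                 " has a gap in its visit sequence (visits must be 0..k)")
    k <- max(vis)
    if (k < T) {
      pad <- data[rep(rows[1], T - k), , drop = FALSE]
      pad[setdiff(names(pad), c(idc, vc, rc, roles$baseline))] <- NA
      pad[[vc]] <- seq.int(k + 1L, T)
      pad[[rc]] <- 0
      add[[pid]] <- pad
    }
  }
  if (length(add)) {
    data <- rbind(data, do.call(rbind, add))
    data <- data[order(data[[idc]], data[[vc]]), , drop = FALSE]
  }
  data
}

#' Construct and validate a person-period table
#'
#' Checks the structural invariants of a long-format longitudinal panel with
#' monotone dropout: baseline complete for every patient, every patient
#' carrying visits `0..T` (rows after dropout are filled in with in-study
#' indicator 0 when the input omits them), once-out-always-out dropout,
#' measurements present exactly on in-study rows, baseline covariates constant
#' within patient, and (for ordinal treatment) the nesting of the two
#' treatment indicators. Intermittent missingness is rejected, not imputed:
#' any preprocessing is the caller's job.
#'
#' @param data a data frame, one row per person-period.
#' @param roles a [panel_roles()] mapping.
#' @param T number of follow-up visits; defaults to the maximum visit present.
#' @return A `person_period_table`: the validated data frame sorted by
#'   (patient, visit), with attributes `roles`, `n` (patients) and `T`.
#' @export
person_period_table <- function(data, roles, T = NULL) {
  stopifnot(inherits(roles, "panel_roles"))
  need <- c(roles$id, roles$visit, roles$in_study, treatment_cols(roles),
            roles$outcome, roles$tv, roles$baseline)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_stage("panel", "missing required column(s): ",
               paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data[[roles$id]] <- as.character(data[[roles$id]])
  if (nrow(data) == 0L)
    return(new_person_period_table(data, roles, T %||% 0L, 0L))
  data <- data[order(data[[roles$id]], data[[roles$visit]]), , drop = FALSE]
  rownames(data) <- NULL
  data <- materialize_dropout_rows(data, roles, T)
  rownames(data) <- NULL

  idv <- data[[roles$id]]; vis <- data[[roles$visit]]
  r <- data[[roles$in_study]]
  T <- max(vis)
  n <- length(unique(idv))
  if (!all(r %in% c(0, 1)))
    stop_stage("panel", "in-study indicator must be 0/1")
  if (nrow(data) != n * (T + 1) || !identical(as.integer(vis), rep(0:T, n)))
    stop_stage("panel", "every patient must carry visits 0..T")
  if (any(r[vis == 0] != 1)) {
    bad <- idv[vis == 0][r[vis == 0] != 1]
    stop_stage("panel", "patient ", bad[1], " is not in study at baseline")
  }
  ## monotone dropout: within a patient, r may only step down
  same <- idv[-1] == idv[-length(idv)]
  up <- which(diff(r) > 0 & same)
  if (length(up))
    stop_stage("panel", "non-monotone in-study sequence for patient ",
               idv[up[1] + 1])
  instudy <- r == 1
  fu <- instudy & vis >= 1
  for (cn in c(roles$tv, roles$outcome, roles$baseline))
    if (anyNA(data[[cn]][instudy]))
      stop_stage("panel", "missing values in '", cn, "' on in-study rows")
  for (cn in treatment_cols(roles))
    if (anyNA(data[[cn]][fu]))
      stop_stage("panel", "missing treatment '", cn, "' on in-study rows")
  for (cn in roles$baseline) {
    first <- data[[cn]][vis == 0]
    if (!isTRUE(all.equal(rep(first, each = T + 1)[instudy],
                          data[[cn]][instudy], check.attributes = FALSE)))
      stop_stage("panel", "baseline covariate '", cn,
                 "' varies within patient")
  }
  if (roles$kind %in% c("binary", "ordinal")) {
    for (cn in treatment_cols(roles))
      if (!all(data[[cn]][fu] %in% c(0, 1)))
        stop_stage("panel", "treatment '", cn, "' must be 0/1")
  }
  if (roles$kind == "ordinal") {
    a0 <- data[[roles$treatment[1]]][fu]; a1 <- data[[roles$treatment[2]]][fu]
    if (any(a1 > a0))
      stop_stage("panel", "'", roles$treatment[2], "' = 1 requires '",
                 roles$treatment[1], "' = 1")
  }
  new_person_period_table(data, roles, T, n)
}

#' Read a person-period table from a delimited text file
#'
#' @param path path to a delimited text file with a header row.
#' @param roles a [panel_roles()] mapping.
#' @param sep field separator (default comma).
#' @param T number of follow-up visits (defaults to the maximum visit found).
#' @return A validated [person_period_table()].
#' @export
read_panel <- function(path, roles, sep = ",", T = NULL) {
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  person_period_table(data, roles, T = T)
}

#' Write a person-period table to a delimited text file
#'
#' @param table a [person_period_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_panel <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Index of uncensored person-periods
#'
#' Returns the follow-up rows (visit >= 1) still in study, in (patient, visit)
#' order. This ordering is the single alignment used for weight vectors and
#' the rows of the restriction matrix.
#'
#' @param table a [person_period_table()].
#' @return A data frame with columns `row` (row number in `table`), `id` and
#'   `visit`; its number of rows is the number of weights `m`.
#' @export
uncensored_index <- function(table) {
  roles <- attr(table, "roles")
  sel <- which(table[[roles$visit]] >= 1 & table[[roles$in_study]] == 1)
  data.frame(row = sel, id = table[[roles$id]][sel],
             visit = table[[roles$visit]][sel], stringsAsFactors = FALSE)
}

#' @export
print.person_period_table <- function(x, ...) {
  roles <- attr(x, "roles")
  m <- nrow(uncensored_index(x))
  cat(sprintf(
    "person_period_table: %d patients, T = %d follow-up visits, %s treatment\n",
    attr(x, "n"), attr(x, "T"), roles$kind))
  cat(sprintf("  %d rows, %d uncensored person-periods (retention %.1f%%)\n",
              nrow(x), m, 100 * m / (attr(x, "n") * attr(x, "T"))))
  invisible(x)
}

#' Augment a person-period table with history columns
#'
#' Adds the derived columns model formulas may reference: `<var>_lag1` for
#' every time-varying covariate and the outcome (the value at the previous
#' visit; at visit 1 this is the baseline value), treatment lags
#' (`<a>_lag1`, 0 at visit 1 since no treatment precedes the first follow-up),
#' the treatment dose `dose` (binary/continuous: the treatment itself;
#' ordinal: any + highest, i.e. 0/1/2), `dose_lag1`, the cumulative dose
#' `dose_cum`, and for ordinal treatment also `cum_low` (cumulative count of
#' low-level-only periods) and `cum_high` (cumulative count of highest-level
#' periods), plus `a_cum` for binary/continuous treatment.
#'
#' @param table a [person_period_table()].
#' @return A plain data frame, row-aligned with `table`.
#' @export
augment_history <- function(table) {
  roles <- attr(table, "roles")
  df <- as.data.frame(table)
  idv <- df[[roles$id]]
  gf <- factor(idv, levels = unique(idv))
  lag1 <- function(v) ave(v, gf, FUN = function(z) c(NA, z[-length(z)]))
  cum0 <- function(v) ave(v, gf, FUN = function(z) cumsum(ifelse(is.na(z), 0, z)))
  for (cn in c(roles$tv, roles$outcome)) {
    nm <- paste0(cn, "_lag1")
    if (nm %in% names(df))
      stop_stage("panel", "derived column '", nm,
                 "' collides with an existing column")
    df[[nm]] <- lag1(df[[cn]])
  }
  zero_lag <- function(v) {
    out <- lag1(v)
    out[df[[roles$visit]] == 1] <- 0
    out
  }
  if (roles$kind == "ordinal") {
    a0 <- roles$treatment[1]; a1 <- roles$treatment[2]
    df[[paste0(a0, "_lag1")]] <- zero_lag(df[[a0]])
    df[[paste0(a1, "_lag1")]] <- zero_lag(df[[a1]])
    df$dose <- df[[a0]] + df[[a1]]
    df$dose_lag1 <- df[[paste0(a0, "_lag1")]] + df[[paste0(a1, "_lag1")]]
    df$dose_cum <- cum0(df$dose)
    df$cum_low <- cum0(df[[a0]] - df[[a1]])
    df$cum_high <- cum0(df[[a1]])
  } else {
    a <- roles$treatment
    df[[paste0(a, "_lag1")]] <- zero_lag(df[[a]])
    df$a_cum <- cum0(df[[a]])
    df$dose <- df[[a]]
    df$dose_lag1 <- df[[paste0(a, "_lag1")]]
    df$dose_cum <- df$a_cum
  }
  df
}
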