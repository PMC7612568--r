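## Marginal structural model fitting by weighted estimating equations with
## identity link, unit working variance and independence working correlation,
## i.e. weighted least squares over uncensored person-periods; standard
## errors come from a patient-resampling bootstrap of the whole pipeline.

#' Build the MSM design over uncensored person-periods
#'
#' Evaluates an outcome formula against [augment_history()], restricted to
#' the uncensored follow-up rows. Treatment-history constructors available in
#' the formula include `dose` (current treatment dose), `dose_cum`
#' (cumulative dose), and for ordinal treatment `cum_low`/`cum_high`
#' (cumulative counts of low-level-only and highest-level periods), all of
#' which vanish on the never-treated sequence, as the marginal-mean model
#' requires; baseline covariates and `visit` may enter too.
#'
#' @param table a [person_period_table()].
#' @param formula two-sided formula, outcome on the left.
#' @return list with design matrix `X`, response `y` and the row index.
#' @export
msm_design <- function(table, formula) {
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  dat <- aug[idx$row, , drop = FALSE]
  X <- stats::model.matrix(formula, dat)
  if (nrow(X) != nrow(idx))
    stop_stage("msm", "design undefined on some uncensored person-periods")
  y <- stats::model.response(stats::model.frame(formula, dat))
  list(X = X, y = y, idx = idx)
}

#' Fit a marginal structural model by weighted least squares
#'
#' Solves the weighted estimating equations
#' `sum_ij R_ij w_ij D_ij {Y_ij - mu(A-bar_ij, gamma)} = 0` for the identity
#' link, unit working variance and independence working correlation, which is
#' exactly weighted least squares over the uncensored person-periods. The
#' solution is invariant to rescaling all weights by a positive constant.
#'
#' @param table a [person_period_table()].
#' @param weights a `weight_set`, a `calibration_result`, or a positive
#'   numeric vector aligned to [uncensored_index()].
#' @param formula the MSM formula (see [msm_design()]).
#' @return An `msm_fit` with coefficients `gamma`, fitted values and
#'   residuals on the uncensored rows.
#' @export
fit_msm <- function(table, weights, formula) {
  d <- msm_design(table, formula)
  w <- weight_vector(weights)
  stopifnot(length(w) == nrow(d$X))
  if (any(w < 0)) stop_stage("msm", "negative weights")
  sw <- sqrt(w)
  qx <- qr(d$X * sw)
  if (qx$rank < ncol(d$X)) {
    dep <- colnames(d$X)[qx$pivot[seq.int(qx$rank + 1L, ncol(d$X))]]
    stop_stage("msm", "singular weighted design; collinear terms: ",
               paste(dep, collapse = ", "))
  }
  gamma <- qr.coef(qx, d$y * sw)
  fitted <- drop(d$X %*% gamma)
  structure(list(coefficients = gamma, formula = formula,
                 fitted = fitted, residuals = d$y - fitted,
                 weights = w, idx = d$idx,
                 n = attr(table, "n"), m = nrow(d$X),
                 se = NULL, vcov = NULL, n_boot = 0L, n_failed = 0L),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("msm_fit: %d patients, %d person-periods\n", x$n, x$m))
  if (is.null(x$se)) {
    print(round(x$coefficients, 4))
  } else {
    tab <- cbind(estimate = x$coefficients, boot_se = x$se)
    print(round(tab, 4))
    cat(sprintf("  (%d bootstrap replicates, %d failed)\n",
                x$n_boot, x$n_failed))
  }
  invisible(x)
}

#' @export
coef.msm_fit <- function(object, ...) object$coefficients

#' @export
vcov.msm_fit <- function(object, ...) object$vcov

#' @export
residuals.msm_fit <- function(object, ...) object$residuals

#' Patient-resampling bootstrap of a fitting pipeline
#'
#' Resamples patients with replacement and re-runs a user-supplied pipeline
#' (typically: refit the weight models, rebuild the restrictions, recalibrate,
#' refit the MSM) on each replicate. Replicates whose pipeline fails (e.g.
#' calibration does not converge) are dropped and counted.
#'
#' @param table a [person_period_table()].
#' @param fitter function taking a resampled `person_period_table` and
#'   returning a named coefficient vector.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; with the same seed results are bit-identical.
#' @return list with `se`, `vcov`, the replicate matrix `replicates`
#'   (failed rows omitted) and `n_failed`.
#' @export
bootstrap_pipeline <- function(table, fitter, B, seed = 1L) {
  if (B < 2L) stop_stage("bootstrap", "B must be at least 2")
  roles <- attr(table, "roles")
  T <- attr(table, "T")
  df <- as.data.frame(table)
  ids <- unique(df[[roles$id]])
  block <- T + 1L
  first <- match(ids, df[[roles$id]])  # row of visit 0 per patient
  set.seed(seed)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    pick <- sample(length(ids), length(ids), replace = TRUE)
    rows <- rep(first[pick], each = block) + rep(0:T, length(pick))
    bdf <- df[rows, , drop = FALSE]
    ## fresh ids keep duplicated patients distinct
    bdf[[roles$id]] <- rep(sprintf("b%06d", seq_along(pick)), each = block)
    btab <- new_person_period_table(bdf, roles, T, length(pick))
    val <- tryCatch(fitter(btab), error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1L else reps[[b]] <- val
  }
  reps <- do.call(rbind, Filter(Negate(is.null), reps))
  if (is.null(reps) || nrow(reps) < 2L)
    stop_stage("bootstrap", "all bootstrap replicates failed")
  V <- stats::cov(reps)
  list(se = sqrt(diag(V)), vcov = V, replicates = reps, n_failed = n_failed)
}
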