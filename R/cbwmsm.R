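#' Fit a marginal structural model with calibrated balancing weights
#'
#' One-stop fitting function: fits the treatment-assignment (and optionally
#' dropout) process models by pooled maximum likelihood, forms initial
#' stabilized inverse-probability weights, builds the covariate-balance
#' moment conditions for both processes, calibrates the weights (convex
#' exponential tilting by default), and fits the marginal structural model by
#' weighted least squares, optionally with patient-resampling bootstrap
#' standard errors that re-run the entire pipeline per replicate.
#'
#' @param data a [person_period_table()], or a data frame together with
#'   `roles`.
#' @param roles a [panel_roles()] mapping (ignored when `data` is already a
#'   person-period table).
#' @param denominator treatment model terms conditioning on covariate
#'   history: a one-sided formula (binary), a list of two (ordinal stages or
#'   continuous mean/log-variance).
#' @param numerator stabilization model terms (treatment history only), same
#'   shape as `denominator`.
#' @param censoring one-sided formula for the dropout model history terms, or
#'   `NULL` to ignore dropout (treatment weighting only).
#' @param balance one-sided formula for the censoring balance functionals
#'   (see [build_censoring_restrictions()]); defaults to the baseline
#'   covariates. Ignored when `censoring` is `NULL`, in which case per-visit
#'   normalization restrictions are used instead for the tilting method.
#' @param msm the marginal structural model formula (see [msm_design()]).
#' @param method `"type1"` (exponential tilting of the initial weights, the
#'   default), `"type2"` (re-solving the weight-model estimating equations),
#'   `"mle"` (no calibration) or `"unweighted"`.
#' @param rescale passed to [compute_initial_weights()].
#' @param boot number of bootstrap replicates for standard errors (0 = none).
#' @param seed seed for the bootstrap and the type-2 multi-start draws.
#' @param control list of solver options: `tol`, `max_iter`, `n_starts`.
#' @return A `cbwmsm` object with components `msm` (the fitted [fit_msm()]
#'   object), `calibration`, `diagnostics`, `weights`, `models` and `system`;
#'   methods: `print`, `summary`, `coef`, `vcov`, `weights`, `residuals`,
#'   `predict`.
#' @export
cbwmsm <- function(data, roles = NULL, denominator, numerator,
                   censoring = NULL, balance = NULL, msm,
                   method = c("type1", "type2", "mle", "unweighted"),
                   rescale = "none", boot = 0L, seed = 1L,
                   control = list()) {
  method <- match.arg(method)
  table <- if (inherits(data, "person_period_table")) data
           else person_period_table(data, roles)
  fit_once <- function(tab) {
    cbwmsm_fit(tab, denominator, numerator, censoring, balance, msm,
               method, rescale, control)
  }
  res <- fit_once(table)
  if (boot >= 2L) {
    bt <- bootstrap_pipeline(table, function(tab) coef(fit_once(tab)$msm),
                             B = boot, seed = seed)
    res$msm$se <- bt$se
    res$msm$vcov <- bt$vcov
    res$msm$n_boot <- boot
    res$msm$n_failed <- bt$n_failed
  }
  res$call <- match.call()
  res
}

## single pass of the pipeline (no bootstrap)
cbwmsm_fit <- function(table, denominator, numerator, censoring, balance,
                       msm, method, rescale, control) {
  roles <- attr(table, "roles")
  tol <- control$tol %||% NULL
  if (roles$kind == "binary") {
    den <- fit_binary_treatment(table, denominator)
    num <- fit_binary_treatment(table, numerator)
  } else if (roles$kind == "ordinal") {
    den <- fit_ordinal_treatment(table, denominator[[1]], denominator[[2]])
    num <- fit_ordinal_treatment(table, numerator[[1]], numerator[[2]])
  } else {
    den <- fit_continuous_treatment(table, denominator[[1]], denominator[[2]])
    num <- fit_continuous_treatment(table, numerator[[1]], numerator[[2]])
  }
  cens <- if (!is.null(censoring)) fit_censoring_model(table, censoring)
  w_init <- compute_initial_weights(table, den, num, cens, rescale = rescale)
  system <- NULL; cal <- NULL; dg <- NULL
  w_msm <- w_init
  if (method %in% c("type1", "type2")) {
    trt_block <- build_treatment_restrictions(table, num, denominator)
    if (!is.null(cens)) {
      bal <- balance %||% stats::reformulate(
        if (length(roles$baseline)) roles$baseline else "1")
      blocks <- list(trt_block, build_censoring_restrictions(table, bal))
      initial <- w_init
    } else if (method == "type1") {
      blocks <- list(trt_block, build_normalization_restrictions(table))
      initial <- w_init$sw_treat
    } else {
      blocks <- list(trt_block)
      initial <- w_init$sw_treat
    }
    system <- assemble_system(blocks, method = method)
    cal <- if (method == "type1")
      solve_type1(initial, system, tol = tol,
                  max_iter = control$max_iter %||% 200L)
    else
      solve_type2(table, num, den, cens, system,
                  n_starts = control$n_starts %||% 5L, tol = tol,
                  max_iter = control$max_iter %||% 200L)
    if (!cal$converged)
      stop_stage("calibrate", "weight calibration did not converge ",
                 "(max residual ", format(max(abs(cal$residuals)),
                                          digits = 3), ")")
    dummy_init <- if (is.numeric(initial)) {
      d <- w_init; d$w_product <- initial; d
    } else initial
    dg <- diagnose(cal, system, dummy_init)
    w_msm <- cal
  } else if (method == "unweighted") {
    w_msm <- rep(1, nrow(w_init))
  }
  fit <- fit_msm(table, w_msm, msm)
  structure(list(msm = fit, calibration = cal, diagnostics = dg,
                 weights = w_init, models = list(denominator = den,
                                                 numerator = num,
                                                 censoring = cens),
                 system = system, method = method, table = table),
            class = "cbwmsm")
}

#' @export
print.cbwmsm <- function(x, ...) {
  cat("Marginal structural model with",
      switch(x$method,
             type1 = "calibrated weights (exponential tilting)",
             type2 = "calibrated weights (estimating equations)",
             mle = "maximum-likelihood weights",
             unweighted = "no weighting"), "\n")
  print(x$msm)
  invisible(x)
}

#' @export
summary.cbwmsm <- function(object, ...) {
  structure(list(fit = object), class = "summary.cbwmsm")
}

#' @export
print.summary.cbwmsm <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$calibration)) {
    print(x$fit$calibration)
    print(x$fit$diagnostics)
  }
  invisible(x)
}

#' @export
coef.cbwmsm <- function(object, ...) coef(object$msm)

#' @export
vcov.cbwmsm <- function(object, ...) object$msm$vcov

#' @export
residuals.cbwmsm <- function(object, ...) object$msm$residuals

#' @export
weights.cbwmsm <- function(object, ...) {
  if (!is.null(object$calibration)) object$calibration$weights_star
  else weight_vector(object$weights)
}

#' Predicted marginal means under treatment sequences
#'
#' @param object a fitted `cbwmsm`.
#' @param newdata data frame holding the design variables of the MSM formula
#'   (e.g. `dose_cum`, `dose`, baseline covariates); when omitted, fitted
#'   values on the uncensored person-periods are returned.
#' @param ... unused.
#' @export
predict.cbwmsm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$msm$fitted)
  f <- object$msm$formula
  X <- stats::model.matrix(f[-2], newdata)
  drop(X %*% coef(object$msm))
}
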