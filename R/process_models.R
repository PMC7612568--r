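## Pooled maximum-likelihood fits for the treatment-assignment and dropout
## processes, and the initial stabilized inverse-probability weights built
## from them. All model formulas are one-sided and are evaluated against
## augment_history(table), so terms may reference lag-1 covariates
## (`x_lag1`), treatment-history lags (`a_lag1`, `dose_lag1`), baseline
## covariates, and the visit index.

rhs_formula <- function(formula) {
  if (length(formula) == 3L) formula[-2] else formula
}

## logistic fit with explicit degenerate-data and separation diagnostics
fit_logistic <- function(y, X, label) {
  if (length(unique(y)) < 2L)
    stop_stage("process_models", label,
               ": response is constant (all ", y[1], "); degenerate data")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  if (!fit$converged)
    stop_stage("process_models", label, ": logistic fit did not converge")
  p <- fit$fitted.values
  if (all(abs(y - p) < 1e-6))
    stop_stage("process_models", label,
               ": perfect separation (a covariate fully predicts the response)")
  list(coefficients = fit$coefficients, fitted = p,
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)))
}

#' Fit a pooled binary treatment-assignment model
#'
#' Logistic regression of the binary treatment on functions of the observed
#' history, pooled over the uncensored follow-up person-periods.
#'
#' @param table a [person_period_table()] with binary treatment.
#' @param formula one-sided formula of history terms (see
#'   [augment_history()] for the derived column names). A numerator
#'   (stabilization) model uses treatment-history terms only, e.g.
#'   `~ a_lag1`; a denominator model adds covariates.
#' @return A `process_model` with the coefficient vector, per-row fitted
#'   probabilities (aligned to the full table, `NA` off-domain) and the
#'   maximized log-likelihood.
#' @export
fit_binary_treatment <- function(table, formula) {
  roles <- attr(table, "roles")
  stopifnot(roles$kind == "binary")
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  X <- stats::model.matrix(rhs_formula(formula), aug[idx$row, , drop = FALSE])
  y <- aug[[roles$treatment]][idx$row]
  fit <- fit_logistic(y, X, "binary treatment model")
  e <- rep(NA_real_, nrow(table)); e[idx$row] <- fit$fitted
  structure(list(kind = "binary_logistic", formula = formula,
                 coefficients = fit$coefficients, e = e,
                 loglik = fit$loglik),
            class = "process_model")
}

#' Fit a two-stage (continuation-ratio) ordinal treatment model
#'
#' Stage 1 is a pooled logistic model for the "any treatment" indicator on
#' all uncensored person-periods; stage 2 is a pooled logistic model for the
#' "highest level" indicator on the subset where any treatment was given.
#' The implied category probabilities are
#' `pr(none) = 1 - e0`, `pr(low) = e0 (1 - e1)`, `pr(high) = e0 e1`.
#'
#' @param table a [person_period_table()] with ordinal treatment.
#' @param formula0,formula1 one-sided history formulas for the two stages.
#' @return A `process_model` holding both coefficient vectors and per-row
#'   fitted probabilities `e0` (everywhere uncensored) and `e1` (where the
#'   stage-1 indicator is 1).
#' @export
fit_ordinal_treatment <- function(table, formula0, formula1) {
  roles <- attr(table, "roles")
  stopifnot(roles$kind == "ordinal")
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  a0 <- aug[[roles$treatment[1]]][idx$row]
  a1 <- aug[[roles$treatment[2]]][idx$row]
  X0 <- stats::model.matrix(rhs_formula(formula0), aug[idx$row, , drop = FALSE])
  f0 <- fit_logistic(a0, X0, "ordinal treatment model, stage 1")
  s2 <- which(a0 == 1)
  if (!length(s2))
    stop_stage("process_models",
               "ordinal stage 2 has no person-periods with any treatment")
  X1 <- stats::model.matrix(rhs_formula(formula1),
                            aug[idx$row[s2], , drop = FALSE])
  f1 <- fit_logistic(a1[s2], X1, "ordinal treatment model, stage 2")
  e0 <- rep(NA_real_, nrow(table)); e0[idx$row] <- f0$fitted
  e1 <- rep(NA_real_, nrow(table)); e1[idx$row[s2]] <- f1$fitted
  structure(list(kind = "ordinal_two_stage",
                 formula0 = formula0, formula1 = formula1,
                 coefficients = list(stage1 = f0$coefficients,
                                     stage2 = f1$coefficients),
                 e0 = e0, e1 = e1,
                 loglik = f0$loglik + f1$loglik),
            class = "process_model")
}

#' Fit a heteroscedastic normal model for a continuous treatment
#'
#' Joint maximum likelihood for `A ~ N(x_mu' b_mu, exp(x_sigma' b_sigma))`,
#' pooled over uncensored person-periods.
#'
#' @param table a [person_period_table()] with continuous treatment.
#' @param mean_formula,var_formula one-sided history formulas for the mean and
#'   the log-variance.
#' @return A `process_model` with coefficient vectors `mu` and `sigma`,
#'   per-row fitted means `mu` and variances `sig2`.
#' @export
fit_continuous_treatment <- function(table, mean_formula, var_formula) {
  roles <- attr(table, "roles")
  stopifnot(roles$kind == "continuous")
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  a <- aug[[roles$treatment]][idx$row]
  if (stats::var(a) == 0)
    stop_stage("process_models",
               "constant treatment value; variance model is degenerate")
  Xm <- stats::model.matrix(rhs_formula(mean_formula),
                            aug[idx$row, , drop = FALSE])
  Xs <- stats::model.matrix(rhs_formula(var_formula),
                            aug[idx$row, , drop = FALSE])
  pm <- ncol(Xm); ps <- ncol(Xs)
  if (length(a) < pm + ps)
    stop_stage("process_models", "fewer person-periods than parameters")
  if (qr(Xm)$rank < pm || qr(Xs)$rank < ps)
    stop_stage("process_models", "rank-deficient design in treatment model")
  ols <- stats::lm.fit(Xm, a)
  start <- c(ols$coefficients,
             log(mean(ols$residuals^2)), rep(0, ps - 1L))
  nll <- function(par) {
    bm <- par[seq_len(pm)]; bs <- par[pm + seq_len(ps)]
    eta <- pmin(pmax(drop(Xs %*% bs), -40), 40)
    res <- a - drop(Xm %*% bm)
    0.5 * sum(eta + res^2 * exp(-eta))
  }
  gr <- function(par) {
    bm <- par[seq_len(pm)]; bs <- par[pm + seq_len(ps)]
    eta <- pmin(pmax(drop(Xs %*% bs), -40), 40)
    res <- a - drop(Xm %*% bm)
    w <- exp(-eta)
    c(-drop(crossprod(Xm, res * w)),
      0.5 * drop(crossprod(Xs, 1 - res^2 * w)))
  }
  opt <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0)
    stop_stage("process_models",
               "heteroscedastic normal fit did not converge (code ",
               opt$convergence, ")")
  bm <- opt$par[seq_len(pm)]; bs <- opt$par[pm + seq_len(ps)]
  mu <- rep(NA_real_, nrow(table)); s2 <- rep(NA_real_, nrow(table))
  mu[idx$row] <- drop(Xm %*% bm)
  s2[idx$row] <- exp(drop(Xs %*% bs))
  structure(list(kind = "continuous_heteroscedastic",
                 mean_formula = mean_formula, var_formula = var_formula,
                 coefficients = list(mu = stats::setNames(bm, colnames(Xm)),
                                     sigma = stats::setNames(bs, colnames(Xs))),
                 mu = mu, sig2 = s2, loglik = -opt$value -
                   0.5 * length(a) * log(2 * pi)),
            class = "process_model")
}

#' Fit a pooled logistic dropout (censoring) model
#'
#' Regresses the in-study indicator at visit `j` on functions of the history
#' through visit `j - 1`, over all at-risk person-periods (those in study at
#' `j - 1`), pooled over `j = 1..T`.
#'
#' When the data contain no dropout events the retention probability is set
#' to a continuity-corrected constant (weights are then approximately 1) and
#' the model is flagged rather than failing.
#'
#' @param table a [person_period_table()].
#' @param formula one-sided formula for the history terms; lag-1 columns of
#'   [augment_history()] express dependence on the previous visit.
#' @return A `process_model` with coefficients `theta` and per-row fitted
#'   retention probabilities `pi` (on at-risk rows).
#' @export
fit_censoring_model <- function(table, formula) {
  roles <- attr(table, "roles")
  aug <- augment_history(table)
  vis <- aug[[roles$visit]]
  gf <- factor(aug[[roles$id]], levels = unique(aug[[roles$id]]))
  r <- aug[[roles$in_study]]
  r_lag <- ave(r, gf, FUN = function(z) c(NA, z[-length(z)]))
  at_risk <- which(vis >= 1 & r_lag == 1)
  y <- r[at_risk]
  X <- stats::model.matrix(rhs_formula(formula), aug[at_risk, , drop = FALSE])
  if (nrow(X) != length(at_risk))
    stop_stage("process_models",
               "censoring model terms undefined on at-risk rows ",
               "(history term missing at the required lag)")
  no_events <- all(y == 1)
  if (no_events) {
    ## continuity-corrected retention probability
    p0 <- (length(y) - 0.5) / length(y)
    coefs <- stats::setNames(c(logit(p0), rep(0, ncol(X) - 1L)), colnames(X))
    pi_hat <- rep(NA_real_, nrow(table)); pi_hat[at_risk] <- p0
    warning("no dropout events; censoring weights will be ~1", call. = FALSE)
    return(structure(list(kind = "censoring_logistic", formula = formula,
                          coefficients = coefs, pi = pi_hat,
                          loglik = length(y) * log(p0),
                          no_censoring = TRUE),
                     class = "process_model"))
  }
  fit <- fit_logistic(y, X, "censoring model")
  pi_hat <- rep(NA_real_, nrow(table)); pi_hat[at_risk] <- fit$fitted
  structure(list(kind = "censoring_logistic", formula = formula,
                 coefficients = fit$coefficients, pi = pi_hat,
                 loglik = fit$loglik, no_censoring = FALSE),
            class = "process_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat("process_model:", x$kind, "\n")
  co <- x$coefficients
  if (is.list(co)) {
    for (nm in names(co)) {
      cat(" ", nm, "coefficients:\n")
      print(round(co[[nm]], 4))
    }
  } else print(round(co, 4))
  invisible(x)
}

## per-person-period probability (binary/ordinal) or density (continuous)
## of the observed treatment under a fitted process model
observed_treatment_prob <- function(table, model, rows) {
  roles <- attr(table, "roles")
  if (model$kind == "binary_logistic") {
    a <- table[[roles$treatment]][rows]
    e <- model$e[rows]
    e^a * (1 - e)^(1 - a)
  } else if (model$kind == "ordinal_two_stage") {
    a0 <- table[[roles$treatment[1]]][rows]
    a1 <- table[[roles$treatment[2]]][rows]
    e0 <- model$e0[rows]; e1 <- model$e1[rows]
    p <- ifelse(a0 == 0, 1 - e0,
                e0 * ifelse(a1 == 1, e1, 1 - e1))
    p
  } else if (model$kind == "continuous_heteroscedastic") {
    a <- table[[roles$treatment]][rows]
    stats::dnorm(a, model$mu[rows], sqrt(model$sig2[rows]))
  } else stop_stage("process_models", "not a treatment model: ", model$kind)
}

#' Initial stabilized inverse-probability weights
#'
#' Builds per person-period stabilized treatment weights (cumulative product
#' of numerator over denominator treatment probabilities), censoring weights
#' (cumulative product of inverse fitted retention probabilities), and their
#' product, aligned to [uncensored_index()].
#'
#' @param table a [person_period_table()].
#' @param denominator,numerator fitted treatment process models (the
#'   denominator conditions on covariate history, the numerator on treatment
#'   history only).
#' @param censoring optional fitted censoring model; when `NULL` the
#'   censoring weights are identically 1.
#' @param rescale `"none"` (default), `"iptw"` (scale the treatment weights
#'   to sum to the number of uncensored person-periods), or `"iptcw"` (scale
#'   the product weights to sum to `T` times the number of patients, the
#'   observation count of the dropout-free target population).
#' @param eps positivity guard: fitted probabilities are clipped to
#'   `[eps, 1 - eps]` (densities below at `eps`) before inversion; the number
#'   of clipped values is recorded in the `clipped` attribute.
#' @return A `weight_set` data frame with columns `id`, `visit`, `sw_treat`,
#'   `w_cens`, `w_product`.
#' @export
compute_initial_weights <- function(table, denominator, numerator,
                                    censoring = NULL,
                                    rescale = c("none", "iptw", "iptcw"),
                                    eps = 1e-8) {
  rescale <- match.arg(rescale)
  idx <- uncensored_index(table)
  m <- nrow(idx)
  clipped <- 0L
  guard <- function(p, density = FALSE) {
    if (anyNA(p))
      stop_stage("process_models", "fitted value missing at person-period (",
                 idx$id[which(is.na(p))[1]], ", visit ",
                 idx$visit[which(is.na(p))[1]], ")")
    q <- if (density) pmax(p, eps) else pmin(pmax(p, eps), 1 - eps)
    clipped <<- clipped + sum(q != p)
    q
  }
  dens <- denominator$kind == "continuous_heteroscedastic"
  p_den <- guard(observed_treatment_prob(table, denominator, idx$row), dens)
  p_num <- guard(observed_treatment_prob(table, numerator, idx$row), dens)
  gf <- factor(idx$id, levels = unique(idx$id))
  sw <- ave(p_num / p_den, gf, FUN = cumprod)
  if (!is.null(censoring)) {
    pi_hat <- guard(censoring$pi[idx$row])
    wc <- ave(1 / pi_hat, gf, FUN = cumprod)
  } else wc <- rep(1, m)
  scaling <- list(rescale = rescale, factor = 1)
  wp <- sw * wc
  if (rescale == "iptw") {
    scaling$factor <- m / sum(sw)
    sw <- sw * scaling$factor
    wp <- sw * wc
  } else if (rescale == "iptcw") {
    scaling$factor <- attr(table, "n") * attr(table, "T") / sum(wp)
    wp <- wp * scaling$factor
  }
  if (any(!is.finite(wp)) || any(wp <= 0))
    stop_stage("process_models", "non-positive or non-finite weight at (",
               idx$id[which(!is.finite(wp) | wp <= 0)[1]], ")")
  structure(data.frame(id = idx$id, visit = idx$visit,
                       sw_treat = sw, w_cens = wc, w_product = wp,
                       stringsAsFactors = FALSE),
            scaling = scaling, clipped = clipped,
            class = c("weight_set", "data.frame"))
}

## extract the aligned weight vector from the various containers
weight_vector <- function(weights) {
  if (inherits(weights, "weight_set")) weights$w_product
  else if (inherits(weights, "calibration_result")) weights$weights_star
  else if (is.numeric(weights)) weights
  else stop_stage("weights", "cannot interpret weights of class ",
                  paste(class(weights), collapse = "/"))
}
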