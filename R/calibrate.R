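## Solving K' W* = l for calibrated weights. The tilting (type 1) solver
## minimizes the strictly convex objective sum(W exp(K lambda)) - l'lambda,
## whose gradient is exactly the moment-condition residual; the estimating-
## equation (type 2) solver re-estimates the weight-model parameters so that
## standard-form inverse probability weights satisfy the same conditions.

new_calibration_result <- function(method, lam, wstar, residuals, converged,
                                   iterations, objective = NA_real_,
                                   tilt = NULL, multiple_solutions = FALSE,
                                   extra = list()) {
  structure(c(list(method = method, lam = lam, weights_star = wstar,
                   residuals = residuals, converged = converged,
                   iterations = iterations, objective = objective,
                   tilt = tilt, multiple_solutions = multiple_solutions),
              extra),
            class = "calibration_result")
}

#' Calibrate weights by convex exponential tilting
#'
#' Finds the unique weights of the form `W* = W exp(K lambda)` satisfying the
#' moment conditions `K' W* = l`, by damped Newton minimization of the convex
#' objective `1'{W exp(K lambda)} - l'lambda`. Convergence is declared when
#' the moment-condition residual (the objective gradient) has max-norm below
#' `tol`.
#'
#' @param initial initial weights: a `weight_set` (its product column is
#'   used) or a positive numeric vector aligned to [uncensored_index()].
#' @param system a `restriction_system` from [assemble_system()].
#' @param tol residual max-norm tolerance; default `1e-8 * max(1, sqrt(m))`.
#' @param max_iter Newton iteration cap.
#' @param lambda0 optional starting value (default 0, i.e. the initial
#'   weights).
#' @return A `calibration_result` with the tilt parameters `lam` (on the
#'   original column scaling), calibrated weights `weights_star`, the final
#'   `residuals = K'W* - l`, the `objective` value, a `converged` flag and
#'   the iteration count. Exponents are clipped at +-40 only inside line
#'   search evaluations, never at the reported solution.
#' @export
solve_type1 <- function(initial, system, tol = NULL, max_iter = 200L,
                        lambda0 = NULL) {
  w <- weight_vector(initial)
  if (any(!is.finite(w)) || any(w <= 0))
    stop_stage("calibrate", "initial weights must be positive and finite")
  K <- system$K; l <- system$l
  m <- system$m
  stopifnot(length(w) == m)
  tol <- tol %||% (1e-8 * max(1, sqrt(m)))
  ## column scaling for conditioning; solution in W* is invariant
  s <- apply(abs(K), 2, max)
  s[s == 0] <- 1
  Ks <- sweep(K, 2, s, "/")
  ls <- l / s
  lam <- if (is.null(lambda0)) rep(0, ncol(K)) else lambda0 * s
  obj <- function(lam) {
    eta <- pmin(drop(Ks %*% lam), 40)      # clip only inside search
    sum(w * exp(eta)) - sum(ls * lam)
  }
  f0 <- obj(lam)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Ks %*% lam)
    wstar <- w * exp(pmin(eta, 40))
    g <- drop(crossprod(Ks, wstar)) - ls
    ## convergence is assessed on the unscaled residual
    if (max(abs(g * s)) <= tol && all(eta < 40)) { converged <- TRUE; break }
    H <- crossprod(Ks, Ks * wstar)
    ridge <- 1e-12 * max(diag(H), 1)
    step <- tryCatch(-solve(H + diag(ridge, ncol(H)), g),
                     error = function(e) -g / max(diag(H), 1))
    ## Armijo backtracking
    t_ls <- 1
    gs <- sum(g * step)
    ok <- FALSE
    for (b in 1:60) {
      f1 <- obj(lam + t_ls * step)
      if (is.finite(f1) && f1 <= f0 + 1e-4 * t_ls * gs) { ok <- TRUE; break }
      t_ls <- t_ls / 2
    }
    if (!ok) break
    lam <- lam + t_ls * step
    f0 <- obj(lam)
    if (f0 < -1e12 || sqrt(sum(lam^2)) > 1e6) {
      dir <- lam / max(sqrt(sum(lam^2)), 1e-12)
      stop_stage("calibrate",
                 "tilting objective is unbounded below: the targets are not ",
                 "attainable with positive weights (descent direction: ",
                 paste(sprintf("%s=%.3f", system$labels, dir), collapse = ", "),
                 ")")
    }
  }
  eta <- drop(Ks %*% lam)
  wstar <- w * exp(eta)
  resid <- drop(crossprod(K, wstar)) - l
  converged <- converged && max(abs(resid)) <= tol
  if (!converged)
    warning("tilting solver did not reach tolerance (max residual ",
            format(max(abs(resid)), digits = 3), ")", call. = FALSE)
  new_calibration_result("type1", stats::setNames(lam / s, system$labels),
                         wstar, stats::setNames(resid, system$labels),
                         converged, it,
                         objective = sum(wstar) - sum(l * (lam / s)),
                         tilt = exp(eta),
                         extra = list(w_init = w, tol = tol))
}

## recompute standard-form IPTCW weights at given weight-model parameters,
## with the stabilization (numerator) fits held fixed
weights_at_parameters <- function(table, numerator, denominator, censoring,
                                  par, layout) {
  idx <- layout$idx
  gf <- layout$gf
  eps <- 1e-12
  take <- function(k) {
    out <- par[seq_len(k)]
    par <<- par[-seq_len(k)]
    out
  }
  if (layout$kind == "binary") {
    e <- expit(drop(layout$X %*% take(ncol(layout$X))))
    p_den <- ifelse(layout$a == 1, e, 1 - e)
  } else if (layout$kind == "ordinal") {
    e0 <- expit(drop(layout$X0 %*% take(ncol(layout$X0))))
    e1 <- expit(drop(layout$X1 %*% take(ncol(layout$X1))))
    p_den <- ifelse(layout$a0 == 0, 1 - e0,
                    e0 * ifelse(layout$a1 == 1, e1, 1 - e1))
  } else {
    mu <- drop(layout$Xm %*% take(ncol(layout$Xm)))
    s2 <- exp(pmin(pmax(drop(layout$Xs %*% take(ncol(layout$Xs))), -40), 40))
    p_den <- stats::dnorm(layout$a, mu, sqrt(s2))
  }
  sw <- ave(layout$p_num / pmax(p_den, eps), gf, FUN = cumprod)
  if (!is.null(layout$Xc)) {
    pi_hat <- expit(drop(layout$Xc %*% take(ncol(layout$Xc))))
    wc <- ave(1 / pmax(pi_hat, eps), gf, FUN = cumprod)
  } else wc <- 1
  sw * wc
}

#' Calibrate weights by re-solving the weight-model estimating equations
#'
#' Keeps the calibrated weights in standard inverse-probability form
#' `W(alpha_hat, beta, theta)` — with the stabilization fits `alpha_hat`
#' fixed at their unweighted maximum likelihood values — and root-finds the
#' denominator and censoring model parameters `(beta, theta)` so that the
#' moment conditions `K' W = l` hold. The number of free parameters must
#' equal the number of moment conditions, so treatment-only systems exclude
#' normalization columns. Unlike the tilting solver this problem is not
#' convex: non-convergence and multiple solutions are reported, not hidden.
#'
#' @param table a [person_period_table()].
#' @param numerator,denominator fitted treatment process models (the
#'   denominator supplies the starting values).
#' @param censoring optional fitted censoring model.
#' @param system a `restriction_system`; its columns must pair one-to-one
#'   with the free parameters.
#' @param n_starts number of starts (the maximum likelihood start plus
#'   random perturbations drawn from the current RNG stream).
#' @param tol residual max-norm tolerance; default as in [solve_type1()].
#' @param max_iter damped-Newton iteration cap per start.
#' @return A `calibration_result`; `lam` holds the stacked `(beta, theta)`
#'   estimates, `multiple_solutions` is `TRUE` when converged starts produce
#'   weight sets differing by more than a constant of proportionality, and
#'   `converged = FALSE` (with the best residual found) when no start meets
#'   the tolerance.
#' @export
solve_type2 <- function(table, numerator, denominator, censoring = NULL,
                        system, n_starts = 5L, tol = NULL, max_iter = 200L) {
  roles <- attr(table, "roles")
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  rows <- idx$row
  layout <- list(idx = idx, gf = factor(idx$id, levels = unique(idx$id)),
                 kind = roles$kind,
                 p_num = observed_treatment_prob(table, numerator, rows))
  start <- numeric(0)
  if (roles$kind == "binary") {
    layout$X <- stats::model.matrix(rhs_formula(denominator$formula),
                                    aug[rows, , drop = FALSE])
    layout$a <- aug[[roles$treatment]][rows]
    start <- c(start, denominator$coefficients)
  } else if (roles$kind == "ordinal") {
    layout$X0 <- stats::model.matrix(rhs_formula(denominator$formula0),
                                     aug[rows, , drop = FALSE])
    layout$X1 <- stats::model.matrix(rhs_formula(denominator$formula1),
                                     aug[rows, , drop = FALSE])
    layout$a0 <- aug[[roles$treatment[1]]][rows]
    layout$a1 <- aug[[roles$treatment[2]]][rows]
    start <- c(start, denominator$coefficients$stage1,
               denominator$coefficients$stage2)
  } else {
    layout$Xm <- stats::model.matrix(rhs_formula(denominator$mean_formula),
                                     aug[rows, , drop = FALSE])
    layout$Xs <- stats::model.matrix(rhs_formula(denominator$var_formula),
                                     aug[rows, , drop = FALSE])
    layout$a <- aug[[roles$treatment]][rows]
    start <- c(start, denominator$coefficients$mu,
               denominator$coefficients$sigma)
  }
  if (!is.null(censoring)) {
    layout$Xc <- stats::model.matrix(rhs_formula(censoring$formula),
                                     aug[rows, , drop = FALSE])
    start <- c(start, censoring$coefficients)
  }
  if (length(start) != system$r)
    stop_stage("calibrate", "estimating-equation calibration needs as many ",
               "free parameters (", length(start), ") as moment conditions (",
               system$r, ")")
  tol <- tol %||% (1e-8 * max(1, sqrt(system$m)))
  resid_fun <- function(par)
    drop(crossprod(system$K,
                   weights_at_parameters(table, numerator, denominator,
                                         censoring, par, layout))) - system$l
  newton <- function(par) {
    f <- resid_fun(par)
    for (it in seq_len(max_iter)) {
      if (max(abs(f)) <= tol)
        return(list(par = par, resid = f, converged = TRUE, iterations = it))
      J <- vapply(seq_along(par), function(k) {
        h <- 1e-6 * (abs(par[k]) + 1)
        pk <- par; pk[k] <- pk[k] + h
        (resid_fun(pk) - f) / h
      }, numeric(length(f)))
      J <- matrix(J, nrow = length(f))
      step <- tryCatch(-solve(J, f), error = function(e) NULL)
      if (is.null(step))
        step <- -drop(solve(crossprod(J) + diag(1e-8, ncol(J)),
                            crossprod(J, f)))
      t_ls <- 1; nf <- sum(f^2); ok <- FALSE
      for (b in 1:40) {
        f1 <- resid_fun(par + t_ls * step)
        if (all(is.finite(f1)) && sum(f1^2) < nf * (1 - 1e-4 * t_ls)) {
          ok <- TRUE; break
        }
        t_ls <- t_ls / 2
      }
      if (!ok)
        return(list(par = par, resid = f, converged = FALSE, iterations = it))
      par <- par + t_ls * step
      f <- f1
    }
    list(par = par, resid = f, converged = max(abs(f)) <= tol,
         iterations = max_iter)
  }
  sols <- list()
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    p0 <- if (s == 1L) start else
      start + stats::rnorm(length(start), 0, 0.25 * (abs(start) + 0.1))
    out <- newton(p0)
    if (is.null(best) || max(abs(out$resid)) < max(abs(best$resid)))
      best <- out
    if (out$converged) sols[[length(sols) + 1L]] <- out
  }
  multiple <- FALSE
  if (length(sols) >= 2L) {
    ws <- lapply(sols, function(sl)
      weights_at_parameters(table, numerator, denominator, censoring,
                            sl$par, layout))
    ws <- lapply(ws, function(w) w / mean(w))   # mod proportionality
    for (k in 2:length(ws))
      if (max(abs(ws[[k]] - ws[[1]])) > 1e-3 * max(abs(ws[[1]])))
        multiple <- TRUE
  }
  wstar <- weights_at_parameters(table, numerator, denominator, censoring,
                                 best$par, layout)
  if (!best$converged)
    warning("estimating-equation calibration did not converge (max residual ",
            format(max(abs(best$resid)), digits = 3), ")", call. = FALSE)
  new_calibration_result("type2", stats::setNames(best$par, system$labels),
                         wstar, stats::setNames(best$resid, system$labels),
                         best$converged, best$iterations,
                         multiple_solutions = multiple,
                         extra = list(n_converged_starts = length(sols),
                                      tol = tol))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result (%s): %s after %d iterations\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  max |K'W* - l| = %.3g; weights in [%.3g, %.3g]\n",
              max(abs(x$residuals)), min(x$weights_star),
              max(x$weights_star)))
  if (isTRUE(x$multiple_solutions))
    cat("  multiple solutions detected (weight sets differ beyond proportionality)\n")
  invisible(x)
}

#' Calibration diagnostics and balance table
#'
#' Summarizes a calibration: the residual max-norm, the variance of the
#' multiplicative calibration factor (which shrinks toward zero as the sample
#' grows when the initial weight models are correctly specified, making it a
#' model-checking statistic), per-visit weight summaries with effective
#' sample sizes, and the pre/post balance of every moment condition.
#'
#' @param result a `calibration_result`.
#' @param system the `restriction_system` it solved.
#' @param initial the initial `weight_set`.
#' @return A `calibration_diagnostics` list.
#' @export
diagnose <- function(result, system, initial) {
  w0 <- weight_vector(initial)
  w1 <- result$weights_star
  factor <- if (!is.null(result$tilt)) result$tilt else w1 / w0
  pre <- drop(crossprod(system$K, w0)) - system$l
  post <- result$residuals
  colsd <- apply(system$K, 2, stats::sd)
  std <- function(d) d / (pmax(colsd, 1e-12) * sqrt(system$m))
  vis <- initial$visit
  per_visit <- do.call(rbind, lapply(sort(unique(vis)), function(j) {
    wj <- w1[vis == j]
    data.frame(visit = j, n = length(wj), mean = mean(wj), max = max(wj),
               ess = sum(wj)^2 / sum(wj^2))
  }))
  structure(list(residual_norm = max(abs(post)),
                 calibration_factor_variance = stats::var(factor),
                 per_visit = per_visit,
                 balance_table = data.frame(
                   label = system$labels, pre = pre, post = post,
                   pre_std = std(pre), post_std = std(post)),
                 converged = result$converged),
            class = "calibration_diagnostics")
}

#' @export
print.calibration_diagnostics <- function(x, ...) {
  cat(sprintf("calibration diagnostics: max residual %.3g, tilt variance %.3g\n",
              x$residual_norm, x$calibration_factor_variance))
  cat("per-visit weights:\n")
  print(x$per_visit, row.names = FALSE, digits = 4)
  cat("balance (standardized deviations, pre -> post):\n")
  bt <- x$balance_table
  for (i in seq_len(nrow(bt)))
    cat(sprintf("  %-24s %9.4f -> %9.4f\n", bt$label[i], bt$pre_std[i],
                bt$post_std[i]))
  invisible(x)
}
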