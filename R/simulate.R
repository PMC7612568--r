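## Synthetic longitudinal panels with time-varying confounding and dependent
## monotone dropout, with known marginal-structural-model truth. Within each
## follow-up visit j the temporal order is: in-study indicator R_j (depends
## on the previous visit's confounder and treatment), then treatment A_j
## (depends on the previous confounder, the baseline covariate and its own
## history), then confounder X_j (responds to the current treatment), then
## outcome Y_j (depends on cumulative treatment and the current confounder).

#' Simulation scenario configuration
#'
#' @param n number of patients.
#' @param T number of follow-up visits.
#' @param treatment `"binary"`, `"ordinal"` (two nested indicators) or
#'   `"continuous"`.
#' @param censoring logical: generate covariate-dependent monotone dropout?
#' @param rho confounder autoregression (0 gives the closed-form causal
#'   truth).
#' @param kappa confounder response to the current treatment dose.
#' @param theta0,theta_a,theta_x outcome law: intercept, direct cumulative
#'   dose effect, confounder effect.
#' @param sd_x,sd_y confounder and outcome noise standard deviations.
#' @param trt_coef treatment-assignment logits (binary and both ordinal
#'   stages): intercept, previous-confounder, baseline and
#'   previous-own-indicator slopes. For continuous treatment these are the
#'   mean-model coefficients and the treatment is normal with variance
#'   `exp(var_coef[1] + var_coef[2] * x_lag1)`.
#' @param var_coef continuous-treatment log-variance coefficients.
#' @param psi dropout law: retention logit intercept, previous-confounder and
#'   previous-dose slopes (ignored when `censoring = FALSE`).
#' @param misspec `"none"`, or `"transform"`: the exported covariate columns
#'   (hence everything the analysis models and balance functionals see) are
#'   replaced by nonlinear transforms `exp(x/2)` and `v/(1+exp(v))` of the
#'   confounders that actually drive the data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 500L, T = 3L,
                       treatment = c("ordinal", "binary", "continuous"),
                       censoring = TRUE,
                       rho = 0, kappa = 0.8,
                       theta0 = 0, theta_a = 1, theta_x = 0.5,
                       sd_x = 1, sd_y = 1,
                       trt_coef = c(intercept = 0, x = 0.5, v = 0.4,
                                    prev = 0.6),
                       var_coef = c(0, 0),
                       psi = c(intercept = 2, x = -0.4, dose = 0.3),
                       misspec = c("none", "transform")) {
  treatment <- match.arg(treatment)
  misspec <- match.arg(misspec)
  stopifnot(n >= 1, T >= 1, sd_x > 0, sd_y > 0, rho >= 0, rho < 1)
  structure(list(n = as.integer(n), T = as.integer(T), treatment = treatment,
                 censoring = censoring, rho = rho, kappa = kappa,
                 theta0 = theta0, theta_a = theta_a, theta_x = theta_x,
                 sd_x = sd_x, sd_y = sd_y, trt_coef = trt_coef,
                 var_coef = var_coef, psi = psi, misspec = misspec),
            class = "sim_config")
}

sim_roles <- function(config) {
  panel_roles(id = "id", visit = "visit", in_study = "r",
              treatment = if (config$treatment == "ordinal") c("a0", "a1")
                          else "a",
              outcome = "y", tv = "x", baseline = "v",
              kind = config$treatment)
}

#' Generate a synthetic longitudinal panel
#'
#' Draws a scenario from [sim_config()]. Randomness is laid out in
#' per-patient blocks of a single stream, so growing `n` under the same seed
#' leaves earlier patients' trajectories unchanged. The returned table also
#' carries the true per-period treatment probability (`.p_a`) and retention
#' probability (`.pi`) columns, from which oracle inverse-probability weights
#' can be formed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `table` (a [person_period_table()]) and `truth` (the
#'   causal parameters of the canonical marginal structural model
#'   `y ~ dose_cum + dose`, the seed, and a config fingerprint).
#' @export
generate_scenario <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n; T <- config$T
  K <- 3L + 5L * T  # per-patient draw budget: v, x0, y0, then 5 per visit
  set.seed(seed)
  U <- matrix(stats::runif(n * K), n, K, byrow = TRUE)
  col_v <- 1L; col_x0 <- 2L; col_y0 <- 3L
  u_at <- function(j, k) U[, 3L + 5L * (j - 1L) + k]  # k in 1..5

  v <- stats::qnorm(U[, col_v])
  x <- stats::qnorm(U[, col_x0])          # confounder at visit 0
  tc <- config$trt_coef; psi <- config$psi
  ordinal <- config$treatment == "ordinal"

  ## storage, row-major (patient blocks of T+1 visits)
  nr <- n * (T + 1L)
  out <- data.frame(id = rep(sprintf("p%06d", seq_len(n)), each = T + 1L),
                    visit = rep(0:T, n), r = 1,
                    v = rep(v, each = T + 1L), x = NA_real_, y = NA_real_,
                    stringsAsFactors = FALSE)
  if (ordinal) { out$a0 <- NA_real_; out$a1 <- NA_real_ }
  else out$a <- NA_real_
  out$.p_a <- NA_real_; out$.pi <- NA_real_
  at <- function(j) which(out$visit == j)

  out$x[at(0)] <- x
  out$y[at(0)] <- config$theta0 + config$theta_x * x +
    config$sd_y * stats::qnorm(U[, col_y0])

  r <- rep(TRUE, n)
  a_prev <- rep(0, n)        # previous own indicator / value
  a1_prev <- rep(0, n)
  dose_prev <- rep(0, n)
  cumdose <- rep(0, n)
  for (j in 1:T) {
    rows <- at(j)
    ## dropout first: depends on (x_{j-1}, dose_{j-1})
    if (config$censoring) {
      pi_j <- expit(psi[1] + psi[2] * x + psi[3] * dose_prev)
      stay <- u_at(j, 1L) < pi_j
      out$.pi[rows] <- ifelse(r, pi_j, NA)
      r <- r & stay
    } else out$.pi[rows] <- 1
    out$r[rows] <- as.numeric(r)
    ## treatment
    if (config$treatment == "binary") {
      p1 <- expit(tc[1] + tc[2] * x + tc[3] * v + tc[4] * a_prev)
      a <- as.numeric(u_at(j, 2L) < p1)
      dose <- a
      out$a[rows][r] <- a[r]
      out$.p_a[rows][r] <- ifelse(a == 1, p1, 1 - p1)[r]
      a_prev <- ifelse(r, a, a_prev)
    } else if (ordinal) {
      p0 <- expit(tc[1] + tc[2] * x + tc[3] * v + tc[4] * a_prev)
      p1 <- expit(tc[1] + tc[2] * x + tc[3] * v + tc[4] * a1_prev)
      a0 <- as.numeric(u_at(j, 2L) < p0)
      a1 <- a0 * as.numeric(u_at(j, 3L) < p1)
      dose <- a0 + a1
      out$a0[rows][r] <- a0[r]
      out$a1[rows][r] <- a1[r]
      p_obs <- ifelse(a0 == 0, 1 - p0, p0 * ifelse(a1 == 1, p1, 1 - p1))
      out$.p_a[rows][r] <- p_obs[r]
      a_prev <- ifelse(r, a0, a_prev)
      a1_prev <- ifelse(r, a1, a1_prev)
    } else {
      mu <- tc[1] + tc[2] * x + tc[3] * v + tc[4] * a_prev
      s2 <- exp(config$var_coef[1] + config$var_coef[2] * x)
      a <- mu + sqrt(s2) * stats::qnorm(u_at(j, 2L))
      dose <- a
      out$a[rows][r] <- a[r]
      out$.p_a[rows][r] <- stats::dnorm(a, mu, sqrt(s2))[r]
      a_prev <- ifelse(r, a, a_prev)
    }
    dose <- ifelse(r, dose, 0)
    cumdose <- cumdose + dose
    dose_prev <- ifelse(r, dose, dose_prev)
    ## confounder responds to the current dose, outcome to both
    x_new <- config$rho * x + config$kappa * dose +
      config$sd_x * stats::qnorm(u_at(j, 4L))
    x <- ifelse(r, x_new, x)
    y <- config$theta0 + config$theta_a * cumdose + config$theta_x * x +
      config$sd_y * stats::qnorm(u_at(j, 5L))
    out$x[rows][r] <- x[r]
    out$y[rows][r] <- y[r]
  }
  if (config$misspec == "transform") {
    out$x <- exp(out$x / 2)
    out$v <- out$v / (1 + exp(out$v))
  }
  tab <- person_period_table(out, sim_roles(config), T = T)
  truth <- list(gamma = true_msm_parameters(config),
                seed = seed, config_hash = config_hash(unclass(config)))
  list(table = tab, truth = truth)
}

#' Causal truth of the canonical marginal structural model
#'
#' For the simulator's data-generating process the marginal potential-outcome
#' mean under a dose sequence is
#' `E(Y_j^a) = theta0 + theta_a * sum(dose) + theta_x * E(X_j^a)`, and the
#' confounder mean is a geometric sum of past doses. With `rho = 0` this is
#' exactly linear in (cumulative dose, current dose), so the MSM
#' `y ~ dose_cum + dose` is correctly specified with coefficients
#' `(theta0, theta_a, theta_x * kappa)`. With `rho > 0` that design is only
#' an approximation; the returned coefficients are the least-squares
#' projection of the exact potential-outcome means over all dose sequences
#' (enumerated for discrete treatments; unavailable for continuous).
#'
#' @param config a [sim_config()].
#' @return Named coefficient vector for `y ~ dose_cum + dose`.
#' @export
true_msm_parameters <- function(config) {
  if (config$rho == 0)
    return(c("(Intercept)" = config$theta0, dose_cum = config$theta_a,
             dose = config$theta_x * config$kappa))
  if (config$treatment == "continuous")
    stop_stage("simulate",
               "closed-form truth needs rho = 0 for continuous treatment")
  T <- config$T
  levels <- if (config$treatment == "ordinal") 0:2 else 0:1
  seqs <- as.matrix(expand.grid(rep(list(levels), T)))
  rows <- list(); k <- 0L
  for (j in 1:T) {
    cum <- rowSums(seqs[, 1:j, drop = FALSE])
    ex <- as.vector(seqs[, 1:j, drop = FALSE] %*%
                      (config$kappa * config$rho^((j - 1):0)))
    mu <- config$theta0 + config$theta_a * cum + config$theta_x * ex
    rows[[j]] <- cbind(1, cum, seqs[, j], mu)
  }
  M <- do.call(rbind, rows)
  fit <- stats::lm.fit(M[, 1:3, drop = FALSE], M[, 4])
  stats::setNames(fit$coefficients, c("(Intercept)", "dose_cum", "dose"))
}

## standard analysis formulas for simulated scenarios (used by the
## replication runner and by the acceptance checks)
sim_model_formulas <- function(config) {
  if (config$treatment == "ordinal") {
    list(den = list(~ x_lag1 + v + a0_lag1, ~ x_lag1 + v + a1_lag1),
         num = list(~ a0_lag1, ~ a1_lag1))
  } else {
    list(den = list(~ x_lag1 + v + a_lag1, ~ x_lag1),
         num = list(~ a_lag1, ~ 1))
  }
}

## one full weight-estimation pass on a simulated-style table; returns the
## available weight sets and calibration results
sim_weight_pipeline <- function(table, config, censor_weights = TRUE,
                                type2 = FALSE) {
  roles <- attr(table, "roles")
  ff <- sim_model_formulas(config)
  if (config$treatment == "ordinal") {
    den <- fit_ordinal_treatment(table, ff$den[[1]], ff$den[[2]])
    num <- fit_ordinal_treatment(table, ff$num[[1]], ff$num[[2]])
    trt_formula <- ff$den
  } else if (config$treatment == "binary") {
    den <- fit_binary_treatment(table, ff$den[[1]])
    num <- fit_binary_treatment(table, ff$num[[1]])
    trt_formula <- ff$den[[1]]
  } else {
    den <- fit_continuous_treatment(table, ff$den[[1]], ff$den[[2]])
    num <- fit_continuous_treatment(table, ff$num[[1]], ff$num[[2]])
    trt_formula <- ff$den
  }
  cens <- NULL
  if (censor_weights && config$censoring)
    cens <- fit_censoring_model(table, ~ x_lag1 + dose_lag1)
  w_init <- compute_initial_weights(table, den, num, cens)
  trt_block <- build_treatment_restrictions(table, num, trt_formula)
  if (!is.null(cens)) {
    blocks <- list(trt_block, build_censoring_restrictions(table, ~ v + x))
    sys <- suppressWarnings(assemble_system(blocks, method = "type1"))
    initial <- w_init
  } else {
    blocks <- list(trt_block, build_normalization_restrictions(table))
    sys <- suppressWarnings(assemble_system(blocks, method = "type1"))
    initial <- w_init$sw_treat
  }
  cal1 <- suppressWarnings(solve_type1(initial, sys))
  cal2 <- NULL
  if (type2) {
    sys2 <- suppressWarnings(assemble_system(list(trt_block),
                                             method = "type2"))
    if (!is.null(cens))
      sys2 <- suppressWarnings(
        assemble_system(blocks, method = "type2"))
    cal2 <- tryCatch(
      suppressWarnings(solve_type2(table, num, den, cens, sys2,
                                   n_starts = 1L)),
      error = function(e) NULL)
  }
  list(den = den, num = num, cens = cens, w_init = w_init,
       system = sys, cal1 = cal1, cal2 = cal2)
}

## oracle weights from the stored true probabilities; when a fitted
## treatment-history-only model is supplied its probabilities stabilize the
## numerator (the moment conditions are formulated for stabilized weights)
true_weights <- function(table, numerator = NULL) {
  idx <- uncensored_index(table)
  gf <- factor(idx$id, levels = unique(idx$id))
  p_num <- if (is.null(numerator)) rep(1, nrow(idx))
           else observed_treatment_prob(table, numerator, idx$row)
  ave(p_num / table$.p_a[idx$row], gf, FUN = cumprod) *
    ave(1 / table$.pi[idx$row], gf, FUN = cumprod)
}

#' Monte-Carlo comparison of weighting estimators
#'
#' Repeatedly simulates a scenario and fits the canonical marginal structural
#' model `y ~ dose_cum + dose` with each requested weighting estimator,
#' summarizing bias, standard deviation, mean squared error and median
#' absolute error per coefficient against the known causal truth.
#' Calibration failures are recorded per estimator, not raised.
#'
#' @param config a [sim_config()].
#' @param reps number of Monte-Carlo replicates.
#' @param estimators subset of `"unweighted"`, `"mle_iptw"`, `"mle_iptcw"`,
#'   `"cal1_iptw"`, `"cal1_iptcw"`, `"cal2_iptw"`, `"cal2_iptcw"`, `"true"`.
#' @param seed integer root seed; replicate seeds are derived from it.
#' @return A `replication_summary` with the summary table and the raw
#'   replicate draws.
#' @export
run_replication_study <- function(config, reps = 200L,
                                  estimators = c("mle_iptcw", "cal1_iptcw",
                                                 "true"),
                                  seed = 1L) {
  known <- c("unweighted", "mle_iptw", "mle_iptcw", "cal1_iptw",
             "cal1_iptcw", "cal2_iptw", "cal2_iptcw", "true")
  bad <- setdiff(estimators, known)
  if (length(bad))
    stop_stage("simulate", "unknown estimator(s): ", paste(bad, collapse = ", "))
  truth <- true_msm_parameters(config)
  msm_formula <- y ~ dose_cum + dose
  need_cens <- any(grepl("iptcw", estimators)) && config$censoring
  need_type2 <- any(grepl("cal2", estimators))
  draws <- lapply(estimators, function(e) matrix(NA_real_, reps, 3))
  names(draws) <- estimators
  for (b in seq_len(reps)) {
    rep_seed <- (seed + 7919 * b) %% 2147483647L
    scn <- generate_scenario(config, seed = rep_seed)
    tab <- scn$table
    pl <- tryCatch(
      sim_weight_pipeline(tab, config, censor_weights = need_cens,
                          type2 = need_type2),
      error = function(e) NULL)
    for (e in estimators) {
      w <- tryCatch(switch(e,
        unweighted = rep(1, nrow(uncensored_index(tab))),
        mle_iptw   = pl$w_init$sw_treat,
        mle_iptcw  = pl$w_init$w_product,
        cal1_iptw  = ,
        cal1_iptcw = if (!is.null(pl$cal1) && pl$cal1$converged)
          pl$cal1$weights_star else NULL,
        cal2_iptw  = ,
        cal2_iptcw = if (!is.null(pl$cal2) && pl$cal2$converged)
          pl$cal2$weights_star else NULL,
        true       = true_weights(tab, pl$num)),
        error = function(err) NULL)
      if (is.null(w) || anyNA(w)) next
      g <- tryCatch(coef(fit_msm(tab, w, msm_formula)),
                    error = function(err) NULL)
      if (!is.null(g)) draws[[e]][b, ] <- g
    }
  }
  terms <- names(truth)
  summ <- do.call(rbind, lapply(estimators, function(e) {
    G <- draws[[e]]
    ok <- stats::complete.cases(G)
    do.call(rbind, lapply(1:3, function(k) {
      g <- G[ok, k]
      data.frame(estimator = e, term = terms[k], true = unname(truth[k]),
                 n_ok = sum(ok), n_fail = reps - sum(ok),
                 bias = mean(g) - truth[[k]],
                 sd = if (sum(ok) > 1) stats::sd(g) else NA_real_,
                 mse = mean((g - truth[[k]])^2),
                 mae = stats::median(abs(g - truth[[k]])),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, draws = draws, truth = truth,
                 reps = reps, config = config, seed = seed),
            class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat(sprintf("replication study: %d reps, n = %d, T = %d, %s treatment%s\n",
              x$reps, x$config$n, x$config$T, x$config$treatment,
              if (x$config$misspec != "none") " (misspecified models)" else ""))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
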