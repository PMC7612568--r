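roles_bin <- panel_roles(tv = "x", kind = "binary")

test_that("intercept-only logistic fits recover closed-form logits", {
  a <- matrix(c(1, 1, 0, 0), 4, 1)
  tab <- binary_panel(a, x = c(1, -1, 1, -1))
  fit <- fit_binary_treatment(tab, ~ 1)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)  # logit(0.5)

  # ordinal: A0 frequency 0.8 over 10 periods, A1 | A0 = 1 frequency 0.25
  df <- grid_df(10, 1)
  df$x <- 0; df$y <- 0
  df$a0 <- ifelse(df$visit == 0, NA, rep(c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)))
  df$a1 <- ifelse(df$visit == 0, NA, rep(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0)))
  tab2 <- person_period_table(df, panel_roles(treatment = c("a0", "a1"),
                                              tv = "x", kind = "ordinal"))
  fo <- fit_ordinal_treatment(tab2, ~ 1, ~ 1)
  expect_equal(unname(fo$coefficients$stage1), log(0.8 / 0.2),
               tolerance = 1e-7)
  expect_equal(unname(fo$coefficients$stage2), log(0.25 / 0.75),
               tolerance = 1e-7)
  # implied category probabilities sum to 1 at every person-period
  idx <- uncensored_index(tab2)$row
  e0 <- fo$e0[idx]; e1 <- ifelse(is.na(fo$e1[idx]), 0.5, fo$e1[idx])
  expect_equal((1 - e0) + e0 * (1 - e1) + e0 * e1, rep(1, length(idx)))
  # stage-2 fitted values exist exactly where the stage-1 indicator is 1
  expect_equal(sum(!is.na(fo$e1[idx])), sum(df$a0[df$visit == 1] == 1))
})

test_that("perfect separation and degenerate treatment raise errors", {
  a <- matrix(c(1, 1, 0, 0), 4, 1)
  tab <- binary_panel(a, x = c(1, 1, -1, -1))  # x fully predicts a
  expect_error(fit_binary_treatment(tab, ~ x_lag1), "separation")
  tab2 <- binary_panel(matrix(1, 4, 1), x = c(1, -1, 1, -1))
  expect_error(fit_binary_treatment(tab2, ~ 1), "constant")
})

test_that("intercept-only heteroscedastic fit equals closed-form MLE", {
  set.seed(1)
  df <- grid_df(20, 1)
  df$x <- 0; df$y <- 0
  aval <- rnorm(20, 2, 1.5)
  df$a <- NA_real_
  df$a[df$visit == 1] <- aval
  tab <- person_period_table(df, panel_roles(tv = "x", kind = "continuous"))
  fit <- fit_continuous_treatment(tab, ~ 1, ~ 1)
  expect_equal(unname(fit$coefficients$mu), mean(aval), tolerance = 1e-6)
  expect_equal(unname(exp(fit$coefficients$sigma)),
               mean((aval - mean(aval))^2), tolerance = 1e-6)
  # constant treatment: degenerate variance model
  df$a[df$visit == 1] <- 3
  tabc <- person_period_table(df, panel_roles(tv = "x", kind = "continuous"))
  expect_error(fit_continuous_treatment(tabc, ~ 1, ~ 1), "degenerate")
})

test_that("large-sample fits recover the generating coefficients", {
  # treatment independent of the confounder: its coefficient ~ 0 within 3 SE
  cfg <- sim_config(n = 5000, T = 2, treatment = "binary", censoring = FALSE,
                    trt_coef = c(0, 0, 0.4, 0.6))
  tab <- generate_scenario(cfg, seed = 11)$table
  fit <- fit_binary_treatment(tab, ~ x_lag1 + v + a_lag1)
  aug <- augment_history(tab)
  idx <- uncensored_index(tab)$row
  oracle <- glm(a ~ x_lag1 + v + a_lag1, binomial(), aug[idx, ])
  se <- summary(oracle)$coefficients["x_lag1", 2]
  expect_lt(abs(fit$coefficients[["x_lag1"]]), 3 * se)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)

  # homoscedastic continuous treatment: variance-model slope ~ 0
  cfgc <- sim_config(n = 5000, T = 2, treatment = "continuous",
                     censoring = FALSE)
  tabc <- generate_scenario(cfgc, seed = 12)$table
  fitc <- fit_continuous_treatment(tabc, ~ x_lag1 + v + a_lag1, ~ x_lag1)
  m <- nrow(uncensored_index(tabc))
  expect_lt(abs(fitc$coefficients$sigma[["x_lag1"]]), 3 * sqrt(2 / m))

  # dropout model coefficient recovery
  cfgd <- sim_config(n = 5000, T = 3)
  tabd <- generate_scenario(cfgd, seed = 13)$table
  fitd <- fit_censoring_model(tabd, ~ x_lag1 + dose_lag1)
  expect_equal(unname(fitd$coefficients), c(2, -0.4, 0.3), tolerance = 0.15)
})

test_that("censoring fit handles no-dropout data with a flag, not an error", {
  cfg <- sim_config(n = 40, T = 2, censoring = FALSE)
  tab <- generate_scenario(cfg, seed = 5)$table
  expect_warning(fit <- fit_censoring_model(tab, ~ 1), "no dropout")
  expect_true(fit$no_censoring)
  idx <- uncensored_index(tab)$row
  expect_true(all(abs(fit$pi[idx] - 1) < 0.05))
})

test_that("censoring intercept matches the observed retention rate", {
  # 10% of at-risk person-periods censored, intercept-only model
  df <- grid_df(10, 1)
  df$x <- 0; df$y <- 0; df$a <- ifelse(df$visit == 0, NA, 1)
  df$r[df$id == "p01" & df$visit == 1] <- 0
  df[df$id == "p01" & df$visit == 1, c("x", "y", "a")] <- NA
  tab <- person_period_table(df, roles_bin)
  fit <- fit_censoring_model(tab, ~ 1)
  expect_equal(unname(fit$coefficients), log(0.9 / 0.1), tolerance = 1e-7)
})

test_that("initial weights telescope and degenerate cases behave", {
  # numerator = denominator spec gives SW == 1
  cfg <- sim_config(n = 60, T = 3, censoring = FALSE)
  tab <- generate_scenario(cfg, seed = 9)$table
  den <- fit_ordinal_treatment(tab, ~ x_lag1 + v + a0_lag1,
                               ~ x_lag1 + v + a1_lag1)
  ws <- compute_initial_weights(tab, den, den)
  expect_equal(ws$sw_treat, rep(1, nrow(ws)))
  expect_equal(ws$w_cens, rep(1, nrow(ws)))      # no censoring model
  expect_equal(ws$w_product, ws$sw_treat * ws$w_cens)

  # hand-telescoped censoring weights: pi = (0.8, 0.5) -> W^C = (1.25, 2.5)
  num <- fit_ordinal_treatment(tab, ~ a0_lag1, ~ a1_lag1)
  cens <- suppressWarnings(fit_censoring_model(tab, ~ 1))  # no dropout here
  cens$pi[uncensored_index(tab)$row] <- rep(c(0.8, 0.5, 0.9), 60)
  wc <- suppressWarnings(compute_initial_weights(tab, den, num, cens))
  one <- wc[wc$id == wc$id[1], ]
  expect_equal(one$w_cens, c(1.25, 2.5, 2.5 / 0.9), tolerance = 1e-12)

  # telescoping holds exactly for every patient in a dropout scenario:
  # the weight at visit j is the weight at j-1 times the visit-j factor
  scn <- generate_scenario(sim_config(n = 200, T = 4), seed = 21)
  pl <- cbwmsm:::sim_weight_pipeline(scn$table, sim_config(n = 200, T = 4))
  w <- pl$w_init
  for (col in c("sw_treat", "w_cens", "w_product")) {
    expect_true(all(is.finite(w[[col]])) && all(w[[col]] > 0))
    ok <- tapply(w[[col]], factor(w$id, unique(w$id)), function(z) {
      fac <- z / c(1, z[-length(z)])        # per-visit multiplicative factor
      all(abs(z - cumprod(fac)) < 1e-12 * max(z))
    })
    expect_true(all(unlist(ok)))
  }
})

test_that("stabilized treatment weights average to ~1 at each visit", {
  cfg <- sim_config(n = 5000, T = 3, treatment = "binary", censoring = FALSE)
  tab <- generate_scenario(cfg, seed = 31)$table
  den <- fit_binary_treatment(tab, ~ x_lag1 + v + a_lag1)
  num <- fit_binary_treatment(tab, ~ a_lag1)
  ws <- compute_initial_weights(tab, den, num)
  per_visit <- tapply(ws$sw_treat, ws$visit, mean)
  expect_true(all(abs(per_visit - 1) < 0.05))
})

test_that("weight rescaling hits the documented totals", {
  cfg <- sim_config(n = 150, T = 3)
  tab <- generate_scenario(cfg, seed = 41)$table
  den <- fit_ordinal_treatment(tab, ~ x_lag1 + v + a0_lag1,
                               ~ x_lag1 + v + a1_lag1)
  num <- fit_ordinal_treatment(tab, ~ a0_lag1, ~ a1_lag1)
  cens <- fit_censoring_model(tab, ~ x_lag1 + dose_lag1)
  m <- nrow(uncensored_index(tab))
  w1 <- compute_initial_weights(tab, den, num, rescale = "iptw")
  expect_equal(sum(w1$sw_treat), m)
  w2 <- compute_initial_weights(tab, den, num, cens, rescale = "iptcw")
  expect_equal(sum(w2$w_product), 150 * 3)
})
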