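test_that("binary treatment restrictions match the hand-computed scores", {
  # T = 1, A = (1,1,0,0), x = (1,-1,1,-1); intercept-only numerator gives
  # e = 0.5, so the columns of K are (A - 1/2) and (A - 1/2) x
  tab <- binary_panel(matrix(c(1, 1, 0, 0), 4, 1), x = c(1, -1, 1, -1))
  num <- fit_binary_treatment(tab, ~ 1)
  blk <- build_treatment_restrictions(tab, num, ~ x_lag1)
  expect_equal(unname(blk$M[, 1]), c(0.5, 0.5, -0.5, -0.5))
  expect_equal(unname(blk$M[, 2]), c(0.5, -0.5, -0.5, 0.5))
  expect_equal(blk$target, c(0, 0))
  # unit weights already satisfy this block
  expect_equal(unname(colSums(blk$M)), c(0, 0))
})

test_that("scores are cumulative over visits within a patient", {
  # 1 patient, T = 2, A = (1, 0), intercept-only numerator -> e = 0.5;
  # cumulative residuals are (0.5, 0.0)
  tab <- binary_panel(matrix(c(1, 0), 1, 2), x = 0)
  num <- fit_binary_treatment(tab, ~ 1)
  blk <- build_treatment_restrictions(tab, num, ~ 1)
  expect_equal(unname(blk$M[, 1]), c(0.5, 0.0))
})

test_that("scores from the saturated denominator fit vanish at unit weights", {
  set.seed(2)
  tab <- binary_panel(matrix(rbinom(40, 1, 0.5), 40, 1),
                      x = rep(c(0, 1), 20))
  den <- fit_binary_treatment(tab, ~ factor(x_lag1))
  blk <- build_treatment_restrictions(tab, den, ~ factor(x_lag1),
                                      e_override = list(e = den$e))
  expect_lt(max(abs(colSums(blk$M))), 1e-8)   # MLE score equations
})

test_that("ordinal stage-2 columns only accumulate where any treatment given", {
  df <- grid_df(2, 2)
  df$x <- 0; df$y <- 0
  df$a0 <- c(NA, 1, 0, NA, 1, 1)
  df$a1 <- c(NA, 1, 0, NA, 0, 1)
  tab <- person_period_table(df, panel_roles(treatment = c("a0", "a1"),
                                             tv = "x", kind = "ordinal"))
  num <- fit_ordinal_treatment(tab, ~ 1, ~ 1)
  blk <- build_treatment_restrictions(tab, num, list(~ 1, ~ 1))
  # e0 = 3/4, e1 = 2/3 by closed form; stage-2 contribution is 0 where a0 = 0
  e0 <- 3 / 4; e1 <- 2 / 3
  expect_equal(unname(blk$M[, 1]),
               c(1 - e0, 1 - e0 + 0 - e0, 1 - e0, 2 * (1 - e0)),
               tolerance = 1e-7)
  expect_equal(unname(blk$M[, 2]),
               c(1 - e1, 1 - e1, 0 - e1, 0 - e1 + 1 - e1), tolerance = 1e-7)
})

test_that("continuous restrictions carry standardized residual scores", {
  # 1 patient, T = 1, A = 2, mu = 1, sig2 = 1 -> row (1, 0)
  df <- grid_df(1, 1)
  df$x <- 0; df$y <- 0; df$a <- c(NA, 2)
  tab <- person_period_table(df, panel_roles(tv = "x", kind = "continuous"))
  num <- fake_continuous_model(tab, mu = c(NA, 1), sig2 = c(NA, 1))
  blk <- build_continuous_restrictions(tab, num, ~ 1, ~ 1)
  expect_equal(unname(blk$M[1, ]), c(1, 0))

  # zero residuals: mean columns 0, variance column -j
  df2 <- grid_df(1, 3)
  df2$x <- 0; df2$y <- 0; df2$a <- c(NA, 1, 1, 1)
  tab2 <- person_period_table(df2, panel_roles(tv = "x", kind = "continuous"))
  num2 <- fake_continuous_model(tab2, mu = rep(1, 4), sig2 = rep(1, 4))
  blk2 <- build_continuous_restrictions(tab2, num2, ~ 1, ~ 1)
  expect_equal(unname(blk2$M[, 1]), c(0, 0, 0))
  expect_equal(unname(blk2$M[, 2]), c(-1, -2, -3))

  # sig2 below tolerance errors
  num3 <- fake_continuous_model(tab2, mu = rep(1, 4), sig2 = rep(1e-12, 4))
  expect_error(build_continuous_restrictions(tab2, num3, ~ 1, ~ 1),
               "variance below tolerance")
})

test_that("iid standardized residuals give near-zero column means", {
  set.seed(4)
  n <- 5000
  df <- grid_df(n, 1)
  df$x <- 0; df$y <- 0; df$a <- NA_real_
  df$a[df$visit == 1] <- rnorm(n)
  tab <- person_period_table(df, panel_roles(tv = "x", kind = "continuous"))
  num <- fake_continuous_model(tab, mu = rep(0, 2 * n), sig2 = rep(1, 2 * n))
  blk <- build_continuous_restrictions(tab, num, ~ 1, ~ 1)
  expect_lt(abs(mean(blk$M[, 1])), 3 / sqrt(n))
  expect_lt(abs(mean(blk$M[, 2])), 3 * sqrt(2) / sqrt(n))
})

test_that("normalization restrictions target the per-visit uncensored counts", {
  tab <- binary_panel(matrix(1, 3, 2), x = c(1, 2, 3),
                      r = rbind(c(1, 1), c(1, 1), c(1, 0)))
  blk <- build_normalization_restrictions(tab)
  expect_equal(blk$target, c(3, 2))
  # K'w = l says the per-visit weight sums equal the per-visit counts,
  # i.e. any satisfying weight vector has per-visit mean weight 1
  expect_equal(drop(crossprod(blk$M, rep(1, 5))), blk$target,
               ignore_attr = TRUE)
})

test_that("censoring restrictions reproduce the size and balance identities", {
  # T = 1, constant functional: every row entry 1, target n
  tab <- binary_panel(matrix(1, 5, 1), x = 1:5)
  blk <- build_censoring_restrictions(tab, ~ 1)
  expect_equal(unname(blk$M[, 1]), rep(1, 5))
  expect_equal(blk$target, 5)

  # baseline covariate: satisfying weights equate the weighted average of v
  # over visits to the sample average of v
  df <- grid_df(4, 2)
  df$x <- 0; df$y <- 0; df$a <- ifelse(df$visit == 0, NA, 1)
  df$v <- rep(c(2, 4, 6, 8), each = 3)
  tab2 <- person_period_table(df, panel_roles(tv = "x", baseline = "v",
                                              kind = "binary"))
  blk2 <- build_censoring_restrictions(tab2, ~ v)
  expect_equal(unname(blk2$M[, "cens:v"]), rep(c(2, 4, 6, 8), each = 2))
  expect_equal(unname(blk2$target), c(2 * 4, 2 * sum(c(2, 4, 6, 8))))

  # any weights satisfying visit-indicator columns give per-visit size n and
  # per-visit balance of v (checked through an actual tilt solve)
  scn <- generate_scenario(sim_config(n = 120, T = 3), seed = 8)
  tab3 <- scn$table
  cfg <- sim_config(n = 120, T = 3)
  ff <- cbwmsm:::sim_model_formulas(cfg)
  den <- fit_ordinal_treatment(tab3, ff$den[[1]], ff$den[[2]])
  num <- fit_ordinal_treatment(tab3, ff$num[[1]], ff$num[[2]])
  cens <- fit_censoring_model(tab3, ~ x_lag1 + dose_lag1)
  w0 <- compute_initial_weights(tab3, den, num, cens)
  blocks <- list(build_treatment_restrictions(tab3, num, ff$den),
                 build_censoring_restrictions(tab3, ~ visitf + visitf:v))
  sys <- assemble_system(blocks, method = "type1")
  cal <- solve_type1(w0, sys)
  expect_true(cal$converged)
  idx <- uncensored_index(tab3)
  v <- tab3$v[match(idx$id, tab3$id)]
  for (j in 1:3) {
    sel <- idx$visit == j
    expect_equal(sum(cal$weights_star[sel]), 120, tolerance = 1e-6)
    expect_equal(sum(cal$weights_star[sel] * v[sel]),
                 sum(tab3$v[tab3$visit == 0]), tolerance = 1e-5)
  }
})

test_that("system assembly enforces labels, alignment and block rules", {
  tab <- binary_panel(matrix(c(1, 0, 1, 0), 4, 1), x = c(1, -1, 2, 0))
  num <- fit_binary_treatment(tab, ~ 1)
  trt <- build_treatment_restrictions(tab, num, ~ x_lag1)
  norm <- build_normalization_restrictions(tab)
  cens <- build_censoring_restrictions(tab, ~ 1)
  sys <- assemble_system(list(trt, norm), method = "type2")
  expect_equal(sys$r, 3L)
  expect_error(assemble_system(list(norm, cens)), "redundant")
  dup <- trt; dup$M <- trt$M[, c(1, 1)]
  expect_error(assemble_system(list(dup), method = "type2"), "duplicate")
  expect_warning(assemble_system(list(trt)), "zero weights")
  # rank deficiency is flagged with the offending labels
  trt2 <- trt; trt2$M <- cbind(trt$M, `trt:dup` = trt$M[, 1] * 2)
  trt2$target <- c(trt$target, 0)
  expect_warning(assemble_system(list(trt2), method = "type2"),
                 "rank-deficient")
})

test_that("moment conditions at oracle weights tighten as n grows", {
  # with correctly specified models, the per-row deviation of K'W from l at
  # the true inverse-probability weights shrinks stochastically like 1/sqrt(n)
  dev_at <- function(n, reps = 5) {
    mean(vapply(seq_len(reps), function(b) {
      cfg <- sim_config(n = n, T = 3)
      scn <- generate_scenario(cfg, seed = 1000 * b + n)
      pl <- cbwmsm:::sim_weight_pipeline(scn$table, cfg)
      w_true <- cbwmsm:::true_weights(scn$table, pl$num)
      max(abs(drop(crossprod(pl$system$K, w_true)) - pl$system$l)) / n
    }, 0))
  }
  devs <- c(dev_at(500), dev_at(2000), dev_at(8000))
  expect_true(all(diff(devs) < 0))
})

test_that("restriction systems export and re-import for audit", {
  tab <- binary_panel(matrix(c(1, 0, 1, 0), 4, 1), x = c(1, -1, 2, 0))
  num <- fit_binary_treatment(tab, ~ 1)
  sys <- assemble_system(list(build_treatment_restrictions(tab, num, ~ x_lag1),
                              build_normalization_restrictions(tab)),
                         method = "type2")
  path <- tempfile(fileext = ".csv")
  write_restriction_system(sys, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[1:4, -1]), sys$K, ignore_attr = TRUE)
  expect_equal(unlist(back[5, -1], use.names = FALSE), sys$l)
  unlink(path)
})
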