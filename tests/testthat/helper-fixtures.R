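# small in-code fixtures shared across tests

# complete (id, visit) grid with in-study indicator 1 everywhere
grid_df <- function(n, T) {
  data.frame(id = sprintf("p%02d", rep(seq_len(n), each = T + 1L)),
             visit = rep(0:T, n), r = 1, stringsAsFactors = FALSE)
}

# binary-treatment panel: a[i, j] treatment matrix (n x T), x[i] the
# time-varying covariate value carried at every visit (constant in time so
# its lag is itself), y defaults to 0
binary_panel <- function(a, x, y = NULL, r = NULL) {
  n <- nrow(a); T <- ncol(a)
  df <- grid_df(n, T)
  df$x <- rep(x, each = T + 1L)
  df$a <- NA_real_
  for (j in 1:T) df$a[df$visit == j] <- a[, j]
  df$y <- if (is.null(y)) 0 else as.vector(t(cbind(0, y)))
  if (!is.null(r)) for (j in 1:T) df$r[df$visit == j] <- r[, j]
  df$a[df$r == 0] <- NA
  df$y[df$r == 0 & df$visit > 0] <- NA
  df$x[df$r == 0 & df$visit > 0] <- NA
  person_period_table(df, panel_roles(tv = "x", kind = "binary"), T = T)
}

# fabricated process models (for feeding known fitted values into the
# restriction builders)
fake_binary_model <- function(table, e) {
  structure(list(kind = "binary_logistic", e = e), class = "process_model")
}
fake_continuous_model <- function(table, mu, sig2) {
  structure(list(kind = "continuous_heteroscedastic", mu = mu, sig2 = sig2),
            class = "process_model")
}

# generic dense least-squares root-finder oracle for
# K'(W o exp(K lambda)) = l, independent of the package's Newton solver:
# minimizes the squared residual norm by BFGS with its exact gradient
oracle_tilt <- function(w, K, l) {
  g <- function(lam) drop(crossprod(K, w * exp(drop(K %*% lam)))) - l
  f <- function(lam) sum(g(lam)^2)
  grad <- function(lam) {
    ws <- w * exp(drop(K %*% lam))
    drop(2 * crossprod(K, ws * drop(K %*% g(lam))))
  }
  best <- NULL
  for (s in 1:5) {
    lam0 <- if (s == 1) rep(0, ncol(K)) else stats::rnorm(ncol(K), 0, 0.3)
    o <- stats::optim(lam0, f, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16,
                                     abstol = 1e-22))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}
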