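## Calibration restrictions as a linear system in the calibrated weights:
## each block contributes columns of an m x r matrix K (rows aligned to
## uncensored_index) and a target vector l, so that covariate balance means
## K' W* = l.

new_restriction_block <- function(kind, M, target) {
  stopifnot(ncol(M) == length(target), !is.null(colnames(M)))
  if (any(!is.finite(M)) || any(!is.finite(target)))
    stop_stage("restrictions", "non-finite entries in ", kind, " block")
  structure(list(kind = kind, M = M, target = target),
            class = "restriction_block")
}

## cumulative within-patient sums of per-period score contributions:
## row (i, j) gets sum over k <= j of the period-k contribution
cumsum_by_patient <- function(S, id) {
  gf <- factor(id, levels = unique(id))
  out <- S
  for (k in seq_len(ncol(S))) out[, k] <- ave(S[, k], gf, FUN = cumsum)
  out
}

#' Treatment-process calibration restrictions
#'
#' Builds the moment conditions that force the weighted score equations of
#' the treatment-assignment model, evaluated at the treatment-history-only
#' fit, to hold exactly in the weighted sample: at row (i, j) and column c
#' the matrix carries the cumulative score
#' `sum_{k<=j} (A_ik - e_ik) * x_c(history at k-1)`; all targets are 0.
#' For ordinal treatment there is one column set per stage, the second
#' accumulating `A0_ik (A1_ik - e1_ik) * x_c`.
#'
#' @param table a [person_period_table()].
#' @param numerator the fitted treatment-history-only model supplying the
#'   predicted probabilities.
#' @param formula one-sided formula for the balance functionals of the
#'   history (typically the denominator-model terms). For ordinal treatment a
#'   list of two formulas, one per stage.
#' @param e_override optional list of fitted-probability vectors (aligned to
#'   the full table) replacing the numerator predictions, for diagnostics of
#'   other parameter values.
#' @return A `restriction_block`.
#' @export
build_treatment_restrictions <- function(table, numerator, formula,
                                         e_override = NULL) {
  roles <- attr(table, "roles")
  if (roles$kind == "continuous")
    return(build_continuous_restrictions(table, numerator,
                                         formula[[1]], formula[[2]]))
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  rows <- idx$row
  if (roles$kind == "binary") {
    X <- stats::model.matrix(rhs_formula(formula), aug[rows, , drop = FALSE])
    if (nrow(X) != length(rows))
      stop_stage("restrictions", "balance term undefined at the required lag")
    a <- aug[[roles$treatment]][rows]
    e <- (e_override$e %||% numerator$e)[rows]
    S <- X * (a - e)
    colnames(S) <- paste0("trt:", colnames(X))
    M <- cumsum_by_patient(S, idx$id)
  } else {
    if (!is.list(formula) || length(formula) != 2L)
      stop_stage("restrictions",
                 "ordinal treatment needs a list of two balance formulas")
    X0 <- stats::model.matrix(rhs_formula(formula[[1]]),
                              aug[rows, , drop = FALSE])
    X1 <- stats::model.matrix(rhs_formula(formula[[2]]),
                              aug[rows, , drop = FALSE])
    if (nrow(X0) != length(rows) || nrow(X1) != length(rows))
      stop_stage("restrictions", "balance term undefined at the required lag")
    a0 <- aug[[roles$treatment[1]]][rows]
    a1 <- aug[[roles$treatment[2]]][rows]
    e0 <- (e_override$e0 %||% numerator$e0)[rows]
    e1 <- (e_override$e1 %||% numerator$e1)[rows]
    e1z <- ifelse(a0 == 1, e1, 0)          # stage-2 term is 0 when a0 = 0
    S0 <- X0 * (a0 - e0)
    S1 <- X1 * (a0 * (a1 - e1z))
    colnames(S0) <- paste0("trt0:", colnames(X0))
    colnames(S1) <- paste0("trt1:", colnames(X1))
    M <- cbind(cumsum_by_patient(S0, idx$id), cumsum_by_patient(S1, idx$id))
  }
  new_restriction_block("treatment", M, rep(0, ncol(M)))
}

#' Continuous-treatment calibration restrictions
#'
#' Mean columns accumulate the precision-weighted residuals
#' `(A - mu) / sigma^2 * x_mu`; variance columns accumulate the standardized
#' squared-residual deviations `(-1 + (A - mu)^2 / sigma^2) * x_sigma`,
#' with the moments taken from the treatment-history-only heteroscedastic
#' normal fit. All targets are 0.
#'
#' @param table a [person_period_table()].
#' @param numerator fitted treatment-history-only heteroscedastic model.
#' @param mean_formula,var_formula one-sided balance formulas.
#' @param tol smallest admissible fitted variance.
#' @return A `restriction_block`.
#' @export
build_continuous_restrictions <- function(table, numerator, mean_formula,
                                          var_formula, tol = 1e-10) {
  roles <- attr(table, "roles")
  aug <- augment_history(table)
  idx <- uncensored_index(table)
  rows <- idx$row
  Xm <- stats::model.matrix(rhs_formula(mean_formula),
                            aug[rows, , drop = FALSE])
  Xs <- stats::model.matrix(rhs_formula(var_formula),
                            aug[rows, , drop = FALSE])
  a <- aug[[roles$treatment]][rows]
  mu <- numerator$mu[rows]; s2 <- numerator$sig2[rows]
  if (any(s2 < tol))
    stop_stage("restrictions", "fitted treatment variance below tolerance")
  Sm <- Xm * ((a - mu) / s2)
  Ss <- Xs * (-1 + (a - mu)^2 / s2)
  colnames(Sm) <- paste0("trt_mu:", colnames(Xm))
  colnames(Ss) <- paste0("trt_sig:", colnames(Xs))
  M <- cbind(cumsum_by_patient(Sm, idx$id), cumsum_by_patient(Ss, idx$id))
  new_restriction_block("treatment", M, rep(0, ncol(M)))
}

#' Per-visit weight-normalization restrictions
#'
#' One column per follow-up visit, carrying the visit indicator; the target is
#' the uncensored count at that visit, so a satisfying weight vector has
#' per-visit mean weight 1. Used with treatment-only calibration by
#' exponential tilting, where it rules out the degenerate all-zero solution;
#' redundant (and rejected) when censoring restrictions are present.
#'
#' @param table a [person_period_table()].
#' @return A `restriction_block`.
#' @export
build_normalization_restrictions <- function(table) {
  idx <- uncensored_index(table)
  T <- attr(table, "T")
  M <- sapply(1:T, function(j) as.numeric(idx$visit == j))
  dim(M) <- c(nrow(idx), T)
  colnames(M) <- paste0("norm:visit", 1:T)
  new_restriction_block("normalization", M,
                        as.numeric(tabulate(idx$visit, nbins = T)))
}

#' Censoring-process calibration restrictions
#'
#' For balance functionals `h` of the observed history, row (i, j) carries
#' `(T - j + 1) h(i, j) - (T - j) h(i, j + 1)` where `h(i, t)` evaluates the
#' functional for the visit-`t` transition (covariate values at visit
#' `t - 1`); the target is `T` times the baseline column sums. Any weight
#' vector satisfying the constant-term column therefore reweights the
#' uncensored person-periods to total `n * T`, the observation count of the
#' dropout-free target population, and columns in baseline covariates match
#' their weighted averages to the sample averages.
#'
#' @param table a [person_period_table()].
#' @param formula one-sided formula for `h`. Variables available: baseline
#'   covariates, time-varying covariates and the outcome (their value at the
#'   history visit `t - 1`), treatment columns and `dose` (value at the
#'   history visit, 0 at baseline), the transition index `visit`, and
#'   `visitf = factor(visit, levels = 1:T)` for per-visit balance columns.
#' @return A `restriction_block`.
#' @export
build_censoring_restrictions <- function(table, formula) {
  roles <- attr(table, "roles")
  df <- as.data.frame(table)
  idx <- uncensored_index(table)
  rows <- idx$row
  T <- attr(table, "T")
  vis <- idx$visit
  tvars <- c(roles$tv, roles$outcome)
  avars <- treatment_cols(roles)

  ## history frame for transition t: covariates at visit t-1, visit = t
  frame_at <- function(rws, trans) {
    fr <- df[rws, c(roles$id, roles$baseline), drop = FALSE]
    for (cn in tvars) fr[[cn]] <- df[[cn]][rws]
    for (cn in avars) fr[[cn]] <- ifelse(df[[roles$visit]][rws] == 0, 0,
                                         df[[cn]][rws])
    fr$dose <- if (roles$kind == "ordinal")
      fr[[avars[1]]] + fr[[avars[2]]] else fr[[avars]]
    fr$visit <- trans
    fr$visitf <- factor(trans, levels = 1:T)
    fr
  }
  base_rows <- which(df[[roles$visit]] == 0)
  next_sel <- which(vis < T)
  stacked <- rbind(frame_at(rows - 1L, vis),                  # h(i, j)
                   frame_at(rows[next_sel], vis[next_sel] + 1L), # h(i, j+1)
                   frame_at(base_rows, 1L))                   # h(i, 1)
  if (anyNA(stacked[setdiff(names(stacked), roles$id)]))
    stop_stage("restrictions",
               "balance functional undefined at baseline or history visit")
  H <- stats::model.matrix(rhs_formula(formula), stacked)
  if (nrow(H) != nrow(stacked))
    stop_stage("restrictions",
               "balance functional undefined at baseline or history visit")
  m <- length(rows)
  Hprev <- H[seq_len(m), , drop = FALSE]
  Hnext <- matrix(0, m, ncol(H))
  Hnext[next_sel, ] <- H[m + seq_along(next_sel), , drop = FALSE]
  H0 <- H[m + length(next_sel) + seq_along(base_rows), , drop = FALSE]
  M <- (T - vis + 1) * Hprev - (T - vis) * Hnext
  colnames(M) <- paste0("cens:", colnames(H))
  new_restriction_block("censoring", M, unname(T * colSums(H0)))
}

#' Assemble restriction blocks into one linear system
#'
#' Horizontally concatenates row-aligned blocks into the matrix `K` and the
#' target vector `l`, checking label uniqueness, block compatibility
#' (normalization and censoring blocks must not coexist, since the censoring
#' restrictions already pin the weighted sample size) and column rank.
#'
#' @param blocks a list of `restriction_block` objects.
#' @param method optional solver the system is intended for; a treatment-only
#'   system triggers a degenerate-solution warning for the tilting solver.
#' @return A `restriction_system` with elements `K`, `l`, `labels`, `m`, `r`.
#' @export
assemble_system <- function(blocks, method = NULL) {
  if (inherits(blocks, "restriction_block")) blocks <- list(blocks)
  if (!length(blocks)) stop_stage("restrictions", "no restriction blocks")
  kinds <- vapply(blocks, function(b) b$kind, "")
  if ("normalization" %in% kinds && "censoring" %in% kinds)
    stop_stage("restrictions",
               "normalization restrictions are redundant given censoring ",
               "restrictions; supply one of the two")
  ms <- vapply(blocks, function(b) nrow(b$M), 0L)
  if (length(unique(ms)) != 1L)
    stop_stage("restrictions", "blocks are not row-aligned")
  K <- do.call(cbind, lapply(blocks, function(b) b$M))
  l <- unlist(lapply(blocks, function(b) b$target), use.names = FALSE)
  labels <- colnames(K)
  if (anyDuplicated(labels))
    stop_stage("restrictions", "duplicate column labels: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (all(kinds == "treatment") && (is.null(method) || method == "type1"))
    warning("treatment-only restrictions: the tilting solver can drift ",
            "toward zero weights; add normalization or censoring restrictions",
            call. = FALSE)
  qrk <- qr(K)
  if (qrk$rank < ncol(K)) {
    dep <- labels[qrk$pivot[seq.int(qrk$rank + 1L, ncol(K))]]
    warning("rank-deficient restriction matrix; dependent columns: ",
            paste(dep, collapse = ", "), call. = FALSE)
  }
  structure(list(K = K, l = l, labels = labels,
                 m = nrow(K), r = ncol(K), rank = qrk$rank),
            class = "restriction_system")
}

#' @export
print.restriction_system <- function(x, ...) {
  cat(sprintf("restriction_system: m = %d person-periods, r = %d conditions (rank %d)\n",
              x$m, x$r, x$rank))
  cat("  columns:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Export a restriction system for audit
#'
#' Writes the labeled matrix `K` with the target vector `l` as the final row
#' (labeled `.target`) to a delimited text file.
#'
#' @param system a `restriction_system`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_restriction_system <- function(system, path, sep = ",") {
  out <- rbind(system$K, .target = system$l)
  df <- data.frame(row = c(seq_len(system$m), ".target"), out,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
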