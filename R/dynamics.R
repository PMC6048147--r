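# Linear dynamical fits to latent trajectories: unconstrained least squares,
# symmetric/skew decomposition, best-fit purely rotational (skew-symmetric)
# dynamics, and eigenvalue -> rotational-frequency conversion.
#
# All fits use the row-vector convention Xdot ~ X D on per-step derivatives,
# so fitted eigenvalues are in per-time-step units; frequency conversion
# divides by 2*pi*dt.

new_dynamics_fit <- function(D, kind, r2, dt_ms, r2_baseline) {
  ev <- eigen(D, only.values = TRUE)$values
  ev <- ev[order(-abs(Im(ev)), -Re(ev))]
  structure(list(D = D, kind = kind, r2 = r2, eigenvalues = ev,
                 frequencies_hz = eig_frequencies(ev, dt_ms),
                 dt_ms = dt_ms, r2_baseline = r2_baseline),
            class = "dynamics_fit")
}

# One frequency per conjugate pair (real eigenvalues contribute 0 Hz).
eig_frequencies <- function(ev, dt_ms) {
  im <- Im(ev)
  pos <- im[im > 1e-12]
  n_real <- sum(abs(im) <= 1e-12)
  sort(c(pos / (2 * pi * dt_ms / 1000), rep(0, n_real)), decreasing = TRUE)
}

r2_score <- function(X_dot, pred, baseline = c("mean", "zero")) {
  baseline <- match.arg(baseline)
  resid <- X_dot - pred
  tot <- if (baseline == "mean")
    sum(sweep(X_dot, 2, colMeans(X_dot), "-")^2) else sum(X_dot^2)
  if (tot <= 0) stopf("zero-variance derivative matrix: R^2 undefined")
  1 - sum(resid^2) / tot
}

check_dyn_inputs <- function(X, X_dot) {
  X <- as.matrix(X); X_dot <- as.matrix(X_dot)
  if (nrow(X) != nrow(X_dot) || ncol(X) != ncol(X_dot))
    stopf("X and X_dot must have identical shape")
  if (nrow(X) <= ncol(X))
    stopf("need more rows (%d) than columns (%d)", nrow(X), ncol(X))
  qrd <- qr(X)
  if (qrd$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qrd$pivot[seq_len(qrd$rank)])
    stopf("X is rank deficient; deficient column(s): %s",
          paste(bad, collapse = ", "))
  }
  list(X = X, X_dot = X_dot)
}

#' Fit unconstrained linear dynamics
#'
#' Least-squares fit of `X_dot ~ X D` (row-vector convention); `D` is the
#' pseudoinverse solution. Fit quality is
#' `R^2 = 1 - ||X_dot - X D||^2 / ||X_dot - baseline||^2`.
#'
#' @param X latent trajectories, `rows x k` (typically `CT x k_dyn`).
#' @param X_dot per-step time derivatives, same shape.
#' @param dt_ms time step in ms (for frequency conversion; default 10).
#' @param r2_baseline `"mean"` (default; residuals against column means of
#'   `X_dot`) or `"zero"`.
#' @return object of class `dynamics_fit` with elements `D`, `kind`, `r2`,
#'   `eigenvalues` (per-step units) and `frequencies_hz`.
#' @export
fit_linear_dynamics <- function(X, X_dot, dt_ms = 10,
                                r2_baseline = c("mean", "zero")) {
  r2_baseline <- match.arg(r2_baseline)
  v <- check_dyn_inputs(X, X_dot)
  D <- qr.solve(v$X, v$X_dot)
  new_dynamics_fit(D, "unconstrained",
                   r2_score(v$X_dot, v$X %*% D, r2_baseline),
                   dt_ms, r2_baseline)
}

#' Decompose fitted dynamics into symmetric and skew-symmetric parts
#'
#' Splits `D = D_sym + D_skew` with `D_sym = (D + D') / 2` and
#' `D_skew = (D - D') / 2`, and scores each part by the same `R^2` formula
#' using its own predictions. The skew part's `R^2` can be negative when `D`
#' is far from skew-symmetric.
#'
#' @param fit an unconstrained [fit_linear_dynamics()] result.
#' @param X,X_dot the data the fit was made on.
#' @return list with `sym` and `skew` (`dynamics_fit` objects).
#' @export
decompose_dynamics <- function(fit, X, X_dot) {
  stopifnot(inherits(fit, "dynamics_fit"))
  if (fit$kind != "unconstrained")
    stopf("decompose_dynamics expects an unconstrained fit")
  v <- check_dyn_inputs(X, X_dot)
  D_sym <- (fit$D + t(fit$D)) / 2
  D_skew <- (fit$D - t(fit$D)) / 2
  list(sym = new_dynamics_fit(D_sym, "sym_part",
                              r2_score(v$X_dot, v$X %*% D_sym, fit$r2_baseline),
                              fit$dt_ms, fit$r2_baseline),
       skew = new_dynamics_fit(D_skew, "skew_part",
                               r2_score(v$X_dot, v$X %*% D_skew, fit$r2_baseline),
                               fit$dt_ms, fit$r2_baseline))
}

# Basis of the k x k skew-symmetric matrices: E_ij - E_ji for i < j.
skew_basis <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(m) {
    B <- matrix(0, k, k)
    B[idx[m, 1], idx[m, 2]] <- 1
    B[idx[m, 2], idx[m, 1]] <- -1
    B
  })
}

#' Fit the best purely rotational (skew-symmetric) linear dynamics
#'
#' Minimizes `||X_dot - X D||_F` subject to `D = -D'`. The problem is linear
#' in the `k(k-1)/2` free skew parameters and is solved exactly via the
#' normal equations in that basis. In 2-D the solution reduces to the closed
#' form `omega = sum(x1 xdot2 - x2 xdot1) / sum(x1^2 + x2^2)`.
#'
#' @inheritParams fit_linear_dynamics
#' @return a `dynamics_fit` of kind `"best_skew"`; its eigenvalues are
#'   purely imaginary and give the rotational frequencies.
#' @export
fit_best_skew <- function(X, X_dot, dt_ms = 10,
                          r2_baseline = c("mean", "zero")) {
  r2_baseline <- match.arg(r2_baseline)
  v <- check_dyn_inputs(X, X_dot)
  k <- ncol(v$X)
  basis <- skew_basis(k)
  XB <- lapply(basis, function(B) v$X %*% B)
  m <- length(basis)
  G <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m)
    G[i, j] <- G[j, i] <- sum(XB[[i]] * XB[[j]])
  b <- vapply(XB, function(M) sum(M * v$X_dot), numeric(1))
  theta <- solve(G, b)
  D <- Reduce(`+`, Map(`*`, basis, theta))
  new_dynamics_fit(D, "best_skew",
                   r2_score(v$X_dot, v$X %*% D, r2_baseline),
                   dt_ms, r2_baseline)
}

#' Rotational frequencies from a dynamics fit
#'
#' Converts eigenvalue imaginary parts (per-time-step units) to rotational
#' frequencies in Hz: `f = |Im(lambda)| / (2 pi dt)` with `dt` in seconds.
#' One frequency is reported per conjugate pair (real eigenvalues give 0).
#'
#' @param fit a `dynamics_fit` (any kind), or a bare square matrix.
#' @param dt_ms time step in ms; defaults to the fit's own.
#' @return numeric vector of frequencies in Hz, descending.
#' @export
rotational_frequencies <- function(fit, dt_ms = NULL) {
  if (is.matrix(fit)) {
    if (is.null(dt_ms)) stopf("dt_ms is required when passing a bare matrix")
    ev <- eigen(fit, only.values = TRUE)$values
  } else {
    stopifnot(inherits(fit, "dynamics_fit"))
    if (is.null(dt_ms)) dt_ms <- fit$dt_ms
    ev <- fit$eigenvalues
  }
  if (dt_ms <= 0) stopf("dt_ms must be > 0")
  im <- Im(ev)
  pos <- im[im > 1e-12]
  n_real <- sum(abs(im) <= 1e-12)
  sort(c(pos / (2 * pi * dt_ms / 1000), rep(0, n_real)), decreasing = TRUE)
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat(sprintf("dynamics_fit (%s): k = %d, R^2 = %.3f (%s baseline)\n",
              x$kind, nrow(x$D), x$r2, x$r2_baseline))
  f <- rotational_frequencies(x)
  cat(sprintf("  rotational frequencies (Hz): %s\n",
              paste(sprintf("%.2f", f), collapse = ", ")))
  invisible(x)
}

#' Serialize a dynamics fit to JSON
#' @param fit a `dynamics_fit`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_dynamics_fit <- function(fit, path) {
  out <- list(kind = fit$kind, D = fit$D, r2 = fit$r2,
              r2_baseline = fit$r2_baseline,
              eigenvalues = data.frame(re = Re(fit$eigenvalues),
                                       im = Im(fit$eigenvalues)),
              frequencies_hz = rotational_frequencies(fit),
              dt_ms = fit$dt_ms)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
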