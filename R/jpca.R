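# HDR-independent dynamics assessments: jPCA (cross-condition mean removal
# -> top-6 PCA -> best skew-symmetric fit) and the PCA + unconstrained-LDS
# eigenvalue-spectrum analysis with a neuron bootstrap.

remove_cross_condition_mean <- function(M, C, T) {
  arr <- unstack_matrix(M, C, T)
  mt <- apply(arr, c(2, 3), mean)
  stack_tensor(sweep(arr, c(2, 3), mt, "-"))
}

#' jPCA: best rotational fit in the top condition-specific PCs
#'
#' Three steps: (1) remove each unit's cross-condition mean (so PCA finds
#' dimensions where activity co-varies across conditions); (2) project onto
#' the top `n_dims` principal components; (3) fit the best purely rotational
#' (skew-symmetric) linear dynamics in those dimensions.
#'
#' @param S a [build_matrices()] result (typically of soft-normalized
#'   rates).
#' @param n_dims number of principal components to retain (default 6).
#' @return list with `fit` (a `dynamics_fit` of kind `"best_skew"`), `r2`,
#'   `frequencies_hz`, `projection` (`N x n_dims` PC loadings), `X`,
#'   `X_dot` (projected trajectories and derivatives).
#' @export
run_jpca <- function(S, n_dims = 6) {
  stopifnot(inherits(S, "stacked_matrices"))
  if (S$N < n_dims) stopf("need at least %d units, got %d", n_dims, S$N)
  R_A <- remove_cross_condition_mean(S$A, S$C, S$T)
  R_Ad <- remove_cross_condition_mean(S$A_dot, S$C, S$T)
  V <- svd(R_A, nu = 0, nv = n_dims)$v
  X <- R_A %*% V
  X_dot <- R_Ad %*% V
  fit <- fit_best_skew(X, X_dot, dt_ms = S$dt_ms)
  list(fit = fit, r2 = fit$r2,
       frequencies_hz = rotational_frequencies(fit),
       projection = V, X = X, X_dot = X_dot)
}

#' Eigenvalue spectra of PCA-projected linear dynamics under neuron bootstrap
#'
#' For each bootstrap repetition the unit population is redrawn with
#' replacement; the cross-condition mean is removed, the response is
#' projected onto the top `n_dims` PCs, and an unconstrained linear
#' dynamical system is fit, recording its eigenvalues and fit `R^2`.
#' Degenerate resamples (projection rank below `n_dims`) are redrawn and
#' counted. Standard errors are standard deviations across repetitions.
#'
#' @param resp a [population_response()] (soft-normalized internally by
#'   default).
#' @param window_ms analysis window for the fit (default `c(0, 200)` ms).
#' @param n_dims number of PCs (default 6).
#' @param n_reps bootstrap repetitions (default 100).
#' @param seed RNG seed.
#' @param soft_norm soft-normalize the response first (default `TRUE`).
#' @return object of class `eigen_spectrum_report`: `eigenvalues` (complex
#'   `n_reps x n_dims`), `r2` (per repetition), `max_im` (largest
#'   `|Im(lambda)|` per repetition), `r2_mean`, `r2_sem`, `max_im_mean`,
#'   `max_im_sem`, `n_degenerate`, plus the non-resampled `observed` fit.
#' @export
pca_lds_spectrum <- function(resp, window_ms = c(0, 200), n_dims = 6,
                             n_reps = 100, seed = 1, soft_norm = TRUE) {
  stopifnot(inherits(resp, "population_response"))
  if (dim(resp$rates)[3] < n_dims) stopf("need at least %d units", n_dims)
  if (soft_norm) resp <- soft_normalize(resp)
  S <- build_matrices(resp, window_ms = window_ms)
  one_fit <- function(cols) {
    A <- remove_cross_condition_mean(S$A[, cols, drop = FALSE], S$C, S$T)
    Ad <- remove_cross_condition_mean(S$A_dot[, cols, drop = FALSE], S$C, S$T)
    sv <- svd(A, nu = 0, nv = min(n_dims, ncol(A)))
    if (sum(sv$d > 1e-10 * sv$d[1]) < n_dims) return(NULL)
    V <- sv$v
    fit_linear_dynamics(A %*% V, Ad %*% V, dt_ms = S$dt_ms)
  }
  observed <- one_fit(seq_len(S$N))
  if (is.null(observed)) stopf("population projection rank below %d", n_dims)
  eig <- matrix(NA_complex_, n_reps, n_dims)
  r2 <- numeric(n_reps)
  n_degenerate <- 0L
  with_seed(derive_seed(seed, 31), {
    for (b in seq_len(n_reps)) {
      repeat {
        fit <- one_fit(sample(S$N, S$N, replace = TRUE))
        if (!is.null(fit)) break
        n_degenerate <- n_degenerate + 1L
        if (n_degenerate > 100 * n_reps)
          stopf("too many degenerate bootstrap resamples")
      }
      eig[b, ] <- fit$eigenvalues
      r2[b] <- fit$r2
    }
  })
  max_im <- apply(abs(Im(eig)), 1, max)
  structure(list(eigenvalues = eig, r2 = r2, max_im = max_im,
                 r2_mean = mean(r2), r2_sem = stats::sd(r2),
                 max_im_mean = mean(max_im), max_im_sem = stats::sd(max_im),
                 n_degenerate = n_degenerate, n_reps = n_reps,
                 observed = observed, dt_ms = S$dt_ms, seed = seed),
            class = "eigen_spectrum_report")
}

#' @export
print.eigen_spectrum_report <- function(x, ...) {
  cat(sprintf("eigen_spectrum_report: %d bootstrap repetitions (%d redrawn)\n",
              x$n_reps, x$n_degenerate))
  cat(sprintf("  R^2 = %.3f +/- %.3f; max |Im(lambda)| = %.3f +/- %.3f per step\n",
              x$r2_mean, x$r2_sem, x$max_im_mean, x$max_im_sem))
  cat(sprintf("  observed (no resampling): R^2 = %.3f, max |Im| = %.3f (%.2f Hz)\n",
              x$observed$r2, max(abs(Im(x$observed$eigenvalues))),
              max(rotational_frequencies(x$observed))))
  invisible(x)
}
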