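# Hypothesis-guided dimensionality reduction: a tripartite cost over
# row-orthonormal projections W = [W_invar; W_dyn], minimized by projected
# gradient descent on the Stiefel manifold with QR retraction.
#
# f(W) = lambda_rec * ||A - A W'W||_F^2
#      + lambda_invar * tr(Wi C_across Wi') / tr(Wi C_ind Wi')
#      + lambda_dyn * ( -||X_dyn X_dyn^+ Xdot_dyn||_F^2 )
#
# The reconstruction term is the PCA cost; the invariance term is small when
# the condition-invariant latents vary with time but not condition; the
# dynamics term is small (very negative) when the dynamical latents are well
# fit by some linear dynamical system Xdot ~ X D.

#' HDR configuration
#'
#' @param k_total total number of latent dimensions K (default 6).
#' @param k_invar number of condition-invariant dimensions (default 2).
#' @param k_dyn number of dynamical dimensions (default `k_total - k_invar`).
#' @param lambda length-3 weights for the reconstruction, invariance and
#'   dynamics terms (default `c(1, 1, 1)`).
#' @param normalize_terms if `TRUE`, the reconstruction term is divided by
#'   the total variance of `A` and the dynamics term by the total variance of
#'   `A_dot`, making the weights scale-free; default `FALSE` (raw sums of
#'   squares).
#' @param max_iterations maximum gradient iterations per restart.
#' @param tol_abs,tol_rel convergence tolerances on the cost change over
#'   `tol_iters` iterations.
#' @param tol_iters window length for the convergence test.
#' @param n_restarts number of independent initializations (restart 1 is
#'   PCA-seeded, the rest random orthonormal).
#' @param seed RNG seed controlling the random restarts.
#' @return an object of class `hdr_config`.
#' @export
hdr_config <- function(k_total = 6, k_invar = 2, k_dyn = k_total - k_invar,
                       lambda = c(rec = 1, invar = 1, dyn = 1),
                       normalize_terms = FALSE,
                       max_iterations = 500,
                       tol_abs = 1e-10, tol_rel = 1e-8, tol_iters = 10,
                       n_restarts = 3, seed = 1) {
  if (k_invar < 0 || k_dyn < 0) stopf("k_invar and k_dyn must be >= 0")
  if (k_invar + k_dyn != k_total)
    stopf("k_invar + k_dyn must equal k_total")
  lambda <- as.numeric(lambda)
  if (length(lambda) != 3 || any(lambda < 0))
    stopf("lambda must be 3 nonnegative weights")
  structure(list(k_total = k_total, k_invar = k_invar, k_dyn = k_dyn,
                 lambda = stats::setNames(lambda, c("rec", "invar", "dyn")),
                 normalize_terms = normalize_terms,
                 max_iterations = max_iterations,
                 tol_abs = tol_abs, tol_rel = tol_rel, tol_iters = tol_iters,
                 n_restarts = n_restarts, seed = seed),
            class = "hdr_config")
}

#' Construct a projection basis
#'
#' A `K x N` matrix with orthonormal rows, partitioned into `k_invar`
#' condition-invariant rows followed by `k_dyn` dynamical rows.
#'
#' @param W numeric `K x N` matrix with orthonormal rows.
#' @param k_invar,k_dyn partition sizes (`k_invar + k_dyn = K`).
#' @return object of class `projection_basis`.
#' @export
projection_basis <- function(W, k_invar, k_dyn) {
  W <- as.matrix(W)
  if (k_invar + k_dyn != nrow(W)) stopf("partition sizes must sum to nrow(W)")
  err <- max(abs(tcrossprod(W) - diag(nrow(W))))
  if (err > 1e-8) stopf("W rows are not orthonormal (max deviation %.2e)", err)
  structure(list(W = W, k_invar = k_invar, k_dyn = k_dyn, K = nrow(W)),
            class = "projection_basis")
}

invar_rows <- function(basis) seq_len(basis$k_invar)
dyn_rows <- function(basis) basis$k_invar + seq_len(basis$k_dyn)

#' Split covariances into condition-independent and across-condition parts
#'
#' The cross-condition mean is each unit's average over conditions at each
#' time. `C_ind` is the (time-)covariance of that mean trace itself; and
#' `C_across` is the covariance of the residuals after removing the mean
#' from every condition. With population (divide-by-n) scaling the two parts
#' add up exactly to the total covariance of the column-centered data.
#'
#' @param S a [build_matrices()] result.
#' @return list with `C_ind` and `C_across` (`N x N` each) and the
#'   cross-condition mean trace `mean_trace` (`T x N`).
#' @export
split_covariances <- function(S) {
  stopifnot(inherits(S, "stacked_matrices"))
  if (S$C < 2) stopf("at least 2 conditions are required")
  arr <- unstack_matrix(S$A, S$C, S$T)              # C x T x N
  mean_trace <- apply(arr, c(2, 3), mean)           # T x N
  resid <- sweep(arr, c(2, 3), mean_trace, "-")
  Rm <- stack_tensor(resid)
  C_across <- crossprod(Rm) / (S$C * S$T)
  mc <- sweep(mean_trace, 2, colMeans(mean_trace), "-")
  C_ind <- crossprod(mc) / S$T
  list(C_ind = C_ind, C_across = C_across, mean_trace = mean_trace)
}

# Precomputed sufficient statistics for cost/gradient evaluation.
hdr_precompute <- function(S, cov = NULL) {
  if (is.null(cov)) cov <- split_covariances(S)
  list(G = crossprod(S$A),                  # A'A
       Gd = crossprod(S$A, S$A_dot),        # A'Adot
       C_ind = cov$C_ind, C_across = cov$C_across,
       total_var = sum(S$A^2),
       total_dvar = sum(S$A_dot^2))
}

#' Evaluate the HDR cost at a projection
#'
#' @param W a [projection_basis()] or bare `K x N` matrix.
#' @param S a [build_matrices()] result.
#' @param cov optional [split_covariances()] result (computed if missing).
#' @param cfg an [hdr_config()] (supplies partition sizes when `W` is bare,
#'   and the term weights).
#' @return list with `f_rec`, `f_invar`, `f_dyn` (unweighted term values)
#'   and `total` (weighted sum). A degenerate invariant subspace (zero
#'   condition-independent variance) yields `f_invar = Inf` with a warning.
#' @export
hdr_cost <- function(W, S, cov = NULL, cfg = hdr_config()) {
  if (inherits(W, "projection_basis")) {
    ki <- W$k_invar; kd <- W$k_dyn; W <- W$W
  } else {
    ki <- cfg$k_invar; kd <- cfg$k_dyn
  }
  pre <- hdr_precompute(S, cov)
  hdr_cost_terms(W, ki, kd, pre, cfg)
}

# W here is a bare matrix; exact values (no orthonormality assumed), so
# finite differences in the ambient space agree with the analytic gradient.
hdr_cost_terms <- function(W, ki, kd, pre, cfg) {
  G <- pre$G
  P <- W %*% G                                     # K x N
  WWt <- tcrossprod(W)
  f_rec <- sum(diag(G)) - 2 * sum(P * W) + sum((P %*% t(W)) * WWt)
  if (ki > 0) {
    Wi <- W[seq_len(ki), , drop = FALSE]
    num <- sum((Wi %*% pre$C_across) * Wi)
    den <- sum((Wi %*% pre$C_ind) * Wi)
    if (den <= .Machine$double.eps * max(1, num)) {
      warning("degenerate invariant subspace: zero condition-independent variance")
      f_invar <- Inf
    } else f_invar <- num / den
  } else f_invar <- 0
  if (kd > 0) {
    Wd <- W[ki + seq_len(kd), , drop = FALSE]
    M <- Wd %*% pre$G %*% t(Wd)
    B <- Wd %*% pre$Gd %*% t(Wd)
    f_dyn <- -sum(B * solve(M, B))
  } else f_dyn <- 0
  nr <- if (cfg$normalize_terms) pre$total_var else 1
  nd <- if (cfg$normalize_terms) pre$total_dvar else 1
  lam <- cfg$lambda
  list(f_rec = f_rec, f_invar = f_invar, f_dyn = f_dyn,
       total = lam["rec"] * f_rec / nr + lam["invar"] * f_invar +
         lam["dyn"] * f_dyn / nd)
}

#' Euclidean gradient of the total HDR cost
#'
#' Exact analytic gradient of the weighted total cost with respect to the
#' entries of `W` in the ambient space (no orthonormality assumed), suitable
#' for finite-difference verification; [fit_hdr()] projects it onto the
#' Stiefel tangent space internally.
#'
#' @inheritParams hdr_cost
#' @return `K x N` gradient matrix.
#' @export
hdr_gradient <- function(W, S, cov = NULL, cfg = hdr_config()) {
  if (inherits(W, "projection_basis")) {
    ki <- W$k_invar; kd <- W$k_dyn; W <- W$W
  } else {
    ki <- cfg$k_invar; kd <- cfg$k_dyn
  }
  pre <- hdr_precompute(S, cov)
  hdr_gradient_terms(W, ki, kd, pre, cfg)
}

hdr_gradient_terms <- function(W, ki, kd, pre, cfg) {
  G <- pre$G
  K <- nrow(W)
  WtW <- crossprod(W)
  # d/dW ||A - A W'W||^2 = -2 W (R'A + A'R) with R = A - A W'W,
  # expressed through G = A'A only.
  grad_rec <- -2 * W %*% (2 * G - WtW %*% G - G %*% WtW)
  grad <- (cfg$lambda["rec"] /
             (if (cfg$normalize_terms) pre$total_var else 1)) * grad_rec
  if (ki > 0 && cfg$lambda["invar"] > 0) {
    Wi <- W[seq_len(ki), , drop = FALSE]
    num <- sum((Wi %*% pre$C_across) * Wi)
    den <- sum((Wi %*% pre$C_ind) * Wi)
    gi <- (2 * Wi %*% pre$C_across * den - num * 2 * Wi %*% pre$C_ind) / den^2
    grad[seq_len(ki), ] <- grad[seq_len(ki), ] + cfg$lambda["invar"] * gi
  }
  if (kd > 0 && cfg$lambda["dyn"] > 0) {
    Wd <- W[ki + seq_len(kd), , drop = FALSE]
    V <- t(Wd)                                     # N x kd
    M <- crossprod(V, pre$G %*% V)
    B <- crossprod(V, pre$Gd %*% V)
    Minv_B <- solve(M, B)
    # grad of g = tr(B' M^{-1} B) w.r.t. V
    gV <- 2 * pre$Gd %*% V %*% t(Minv_B) +
      2 * t(pre$Gd) %*% V %*% Minv_B -
      2 * pre$G %*% V %*% (Minv_B %*% t(Minv_B))
    gd <- -t(gV)                                    # f_dyn = -g
    grad[ki + seq_len(kd), ] <- grad[ki + seq_len(kd), ] +
      (cfg$lambda["dyn"] /
         (if (cfg$normalize_terms) pre$total_dvar else 1)) * gd
  }
  grad
}

# One projected-gradient minimization from a given initial W.
hdr_optimize <- function(W0, ki, kd, pre, cfg) {
  W <- orthonormalize_rows(W0)
  costs <- hdr_cost_terms(W, ki, kd, pre, cfg)
  if (is.nan(costs$total)) stopf("NaN in HDR cost at initialization")
  trace <- list(costs)
  step <- 1
  converged <- FALSE
  iters <- 0L
  W_prev <- NULL
  xi_prev <- NULL
  for (it in seq_len(cfg$max_iterations)) {
    Grad <- hdr_gradient_terms(W, ki, kd, pre, cfg)
    # Stiefel tangent projection (for V = W' with orthonormal columns):
    # xi = G - V sym(V'G), expressed here in row form.
    GWt <- W %*% t(Grad)
    xi <- Grad - 0.5 * (GWt + t(GWt)) %*% W
    gnorm2 <- sum(xi^2)
    if (gnorm2 < 1e-24) { converged <- TRUE; iters <- it; break }
    # Barzilai-Borwein initial step (safeguarded), then Armijo backtracking
    # with QR retraction
    if (!is.null(W_prev)) {
      s <- W - W_prev
      y <- xi - xi_prev
      sy <- abs(sum(s * y))
      alpha <- if (sy > 1e-300) min(max(sum(s * s) / sy, 1e-10), 1e6)
      else step * 2
    } else alpha <- step * 2
    accepted <- FALSE
    for (ls in 1:60) {
      W_new <- orthonormalize_rows(W - alpha * xi)
      costs_new <- hdr_cost_terms(W_new, ki, kd, pre, cfg)
      if (is.nan(costs_new$total)) stopf("NaN in HDR cost during optimization")
      if (is.finite(costs_new$total) &&
          costs_new$total <= costs$total - 1e-4 * alpha * gnorm2) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { converged <- TRUE; iters <- it; break }
    step <- alpha
    W_prev <- W
    xi_prev <- xi
    W <- W_new
    costs <- costs_new
    trace[[length(trace) + 1L]] <- costs
    iters <- it
    nt <- length(trace)
    if (nt > cfg$tol_iters) {
      old <- trace[[nt - cfg$tol_iters]]$total
      dlt <- abs(old - costs$total)
      if (dlt < cfg$tol_abs || dlt < cfg$tol_rel * abs(old)) {
        converged <- TRUE
        break
      }
    }
  }
  trace_df <- data.frame(
    iteration = seq_along(trace) - 1L,
    f_rec = vapply(trace, `[[`, numeric(1), "f_rec"),
    f_invar = vapply(trace, `[[`, numeric(1), "f_invar"),
    f_dyn = vapply(trace, `[[`, numeric(1), "f_dyn"),
    total = vapply(trace, `[[`, numeric(1), "total"))
  list(W = W, cost = costs$total, trace = trace_df,
       converged = converged, n_iterations = iters)
}

# PCA-seeded initialization: invariant rows seeded by the leading directions
# of the cross-condition mean, the rest by the top principal components.
hdr_init_pca <- function(S, pre, ki, K) {
  sv <- svd(S$A, nu = 0, nv = K)
  pcs <- t(sv$v)                                   # K x N
  if (ki > 0) {
    ei <- eigen(pre$C_ind, symmetric = TRUE)
    seed_rows <- t(ei$vectors[, seq_len(ki), drop = FALSE])
    W0 <- rbind(seed_rows, pcs)
  } else W0 <- pcs
  orthonormalize_rows(W0)[seq_len(K), , drop = FALSE]
}

#' Fit hypothesis-guided dimensionality reduction
#'
#' Minimizes the tripartite HDR cost over row-orthonormal `K x N` matrices by
#' projected gradient descent with a QR retraction (the constraint set is
#' the Stiefel manifold). Runs `cfg$n_restarts` independent initializations
#' (restart 1 PCA-seeded, the rest random) and returns the best, together
#' with cross-restart principal angles as a stability diagnostic. Returned
#' dimensions are ordered: condition-invariant dimensions by captured
#' variance (descending), dynamical dimensions grouped into rotational
#' planes ordered by frequency (descending).
#'
#' @param S a [build_matrices()] result (typically of soft-normalized rates).
#' @param cfg an [hdr_config()].
#' @return object of class `hdr_result`: `basis` ([projection_basis()]),
#'   `latents` (list with `X`, `X_dot`, `X_invar`, `X_dyn`, `X_dot_dyn`,
#'   `condition`, `time_ms`), `cost` (terms at the optimum), `cost_trace`
#'   (best restart), `converged`, `n_iterations`, `restart_costs`,
#'   `restart_angles_deg` (max principal angle between each restart's total
#'   subspace and the winner's), `captured` ([captured_variance()]), `cfg`.
#' @export
fit_hdr <- function(S, cfg = hdr_config()) {
  stopifnot(inherits(S, "stacked_matrices"))
  K <- cfg$k_total; ki <- cfg$k_invar; kd <- cfg$k_dyn
  if (S$N < K) stopf("need at least K = %d units, got %d", K, S$N)
  if (S$C < 2) stopf("need at least 2 conditions")
  pre <- hdr_precompute(S)
  runs <- vector("list", cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    W0 <- if (r == 1) hdr_init_pca(S, pre, ki, K) else
      with_seed(derive_seed(cfg$seed, r), random_orthonormal_rows(K, S$N))
    runs[[r]] <- hdr_optimize(W0, ki, kd, pre, cfg)
  }
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  best <- which.min(costs)
  W <- runs[[best]]$W
  angles <- vapply(seq_along(runs), function(r) {
    if (r == best) return(0)
    max(principal_angles(t(W), t(runs[[r]]$W))) * 180 / pi
  }, numeric(1))

  W <- order_hdr_dimensions(W, ki, kd, S)
  basis <- projection_basis(W, ki, kd)
  X <- S$A %*% t(W)
  X_dot <- S$A_dot %*% t(W)
  latents <- list(X = X, X_dot = X_dot,
                  X_invar = X[, invar_rows(basis), drop = FALSE],
                  X_dyn = X[, dyn_rows(basis), drop = FALSE],
                  X_dot_dyn = X_dot[, dyn_rows(basis), drop = FALSE],
                  condition = S$condition, time_ms = S$time_ms)
  structure(list(
    basis = basis, latents = latents,
    cost = hdr_cost_terms(W, ki, kd, pre, cfg),
    cost_trace = runs[[best]]$trace,
    converged = runs[[best]]$converged,
    n_iterations = runs[[best]]$n_iterations,
    restart_costs = costs, best_restart = best,
    restart_angles_deg = angles,
    captured = captured_variance(basis, S),
    dt_ms = S$dt_ms, window_ms = S$window_ms, cfg = cfg),
    class = "hdr_result")
}

# Rotate within each partition (cost-invariant) into a canonical order:
# invariant rows by variance, dynamical rows into rotational planes by
# frequency (descending), counter-clockwise sense in plotted coordinates.
order_hdr_dimensions <- function(W, ki, kd, S) {
  if (ki > 1) {
    Xi <- S$A %*% t(W[seq_len(ki), , drop = FALSE])
    Xi <- sweep(Xi, 2, colMeans(Xi), "-")
    R <- svd(Xi, nu = 0)$v
    W[seq_len(ki), ] <- t(R) %*% W[seq_len(ki), , drop = FALSE]
  }
  if (kd > 1) {
    Wd <- W[ki + seq_len(kd), , drop = FALSE]
    Xd <- S$A %*% t(Wd)
    Xd_dot <- S$A_dot %*% t(Wd)
    sk <- fit_best_skew(Xd, Xd_dot, dt_ms = S$dt_ms)
    R <- skew_plane_basis(sk$D)
    W[ki + seq_len(kd), ] <- t(R) %*% Wd
  }
  W
}

# Real orthonormal basis grouping a skew matrix into rotational planes,
# ordered by |Im(eigenvalue)| descending; second vector of each plane signed
# so that the in-plane rotation is counter-clockwise (positive upper-right
# entry of the in-plane dynamics).
skew_plane_basis <- function(D) {
  k <- nrow(D)
  ev <- eigen(D)
  om <- Im(ev$values)
  used <- rep(FALSE, k)
  cols <- list()
  for (i in order(-abs(om))) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(om[i]) < 1e-12) {
      cols[[length(cols) + 1L]] <- Re(ev$vectors[, i])
      next
    }
    j <- which(!used & abs(om + om[i]) < 1e-9 * max(1, abs(om[i])))[1]
    if (!is.na(j)) used[j] <- TRUE
    v <- ev$vectors[, i]
    b1 <- Re(v); b2 <- Im(v)
    plane <- qr.Q(qr(cbind(b1, b2)))
    # ensure counter-clockwise: D in-plane = [[0, w], [-w, 0]] with w > 0
    w_in <- (t(plane) %*% D %*% plane)[1, 2]
    if (w_in < 0) plane[, 2] <- -plane[, 2]
    cols[[length(cols) + 1L]] <- plane
  }
  R <- do.call(cbind, cols)
  qr.Q(qr(R))[, seq_len(k), drop = FALSE]
}

#' Variance captured by a projection
#'
#' Percentage of the total variance of the (column-centered) data matrix
#' captured by the latent dimensions, reported per dimension and summed per
#' partition. By construction no orthonormal `K`-dimensional projection can
#' exceed the top-`K` PCA value.
#'
#' @param basis a [projection_basis()] (or bare orthonormal `K x N` matrix).
#' @param S a [build_matrices()] result.
#' @return list with `per_dimension` (percent per latent), `invar`, `dyn`
#'   and `total` percentages.
#' @export
captured_variance <- function(basis, S) {
  if (!inherits(basis, "projection_basis"))
    basis <- projection_basis(as.matrix(basis), 0, nrow(as.matrix(basis)))
  Ac <- if (isTRUE(S$centered)) S$A else sweep(S$A, 2, colMeans(S$A), "-")
  tot <- sum(Ac^2)
  if (tot <= 0) stopf("zero-variance data matrix")
  X <- Ac %*% t(basis$W)
  per <- 100 * colSums(sweep(X, 2, colMeans(X), "-")^2) / tot
  list(per_dimension = per,
       invar = sum(per[invar_rows(basis)]),
       dyn = sum(per[dyn_rows(basis)]),
       total = sum(per))
}

#' @export
print.hdr_result <- function(x, ...) {
  cat(sprintf("hdr_result: K = %d (%d invariant + %d dynamical), N = %d units\n",
              x$basis$K, x$basis$k_invar, x$basis$k_dyn, ncol(x$basis$W)))
  cat(sprintf("  cost %.6g after %d iterations (%s), best of %d restarts\n",
              x$cost$total, x$n_iterations,
              if (x$converged) "converged" else "not converged",
              length(x$restart_costs)))
  cat(sprintf("  variance captured: invariant %.1f%%, dynamical %.1f%%, total %.1f%%\n",
              x$captured$invar, x$captured$dyn, x$captured$total))
  cat(sprintf("  max cross-restart principal angle: %.2f deg\n",
              max(x$restart_angles_deg)))
  invisible(x)
}

#' Serialize an HDR result to disk
#'
#' Writes `hdr_result.json` (config, cost trace, diagnostics), `W.csv`
#' (rows = dimensions, columns = units) and `X.csv` (rows = condition-major
#' stacked times, columns = latents) into `dir`.
#'
#' @param res an [fit_hdr()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hdr_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(cfg = unclass(res$cfg), cost = res$cost,
               converged = res$converged, n_iterations = res$n_iterations,
               restart_costs = res$restart_costs,
               restart_angles_deg = res$restart_angles_deg,
               captured = res$captured,
               dt_ms = res$dt_ms, window_ms = res$window_ms,
               cost_trace = res$cost_trace,
               layout = list(W = "rows = dimensions (invariant first), columns = units",
                             X = "rows = (condition-major) stacked times, columns = latents"))
  jsonlite::write_json(meta, file.path(dir, "hdr_result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(res$basis$W), file.path(dir, "W.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$latents$X), file.path(dir, "X.csv"),
                   row.names = FALSE)
  invisible(dir)
}
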