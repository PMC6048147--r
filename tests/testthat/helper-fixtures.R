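# Fixtures built in code: small random populations and latent/derivative
# pairs with known structure.

# A random population_response with valid metadata (C conditions recycled
# over the 8 directions x 3 contexts grid).
make_random_resp <- function(C = 6, T = 12, N = 10, seed = 1, dt_ms = 10) {
  set.seed(seed)
  dirs <- rep(seq(0, 315, by = 45), length.out = C)
  ctxs <- rep(c("cue", "self", "quasi"), length.out = C)
  conditions <- data.frame(
    condition_id = sprintf("c%02d", seq_len(C)),
    direction_deg = dirs, context = ctxs)
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(N)),
                      population_label = "M1")
  rates <- array(stats::rnorm(C * T * N, mean = 10, sd = 3), c(C, T, N))
  time_ms <- seq(0, by = dt_ms, length.out = T)
  population_response(rates, time_ms, conditions, units, dt_ms = dt_ms)
}

# Trajectories generated exactly by a discrete linear system xdot = x D.
make_lds_data <- function(D, n_rollouts = 5, T = 40, seed = 1, x0_sd = 1) {
  set.seed(seed)
  k <- nrow(D)
  M <- diag(k) + D
  X <- matrix(NA_real_, n_rollouts * T, k)
  X_dot <- matrix(NA_real_, n_rollouts * T, k)
  for (r in seq_len(n_rollouts)) {
    x <- stats::rnorm(k, sd = x0_sd)
    for (t in seq_len(T)) {
      row <- (r - 1) * T + t
      X[row, ] <- x
      X_dot[row, ] <- x %*% D
      x <- as.numeric(x %*% M)
    }
  }
  list(X = X, X_dot = X_dot)
}

# A random skew-symmetric k x k matrix.
random_skew <- function(k, seed = NULL, sd = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(k * k, sd = sd), k, k)
  (Z - t(Z)) / 2
}

# Stacked-matrices object from raw A/A_dot (for operations that only need
# the matrix view).
make_stacked <- function(A, A_dot, C, T, dt_ms = 10) {
  conds <- data.frame(condition_id = sprintf("c%02d", seq_len(C)),
                      direction_deg = rep(seq(0, 315, by = 45), length.out = C),
                      context = rep(c("cue", "self", "quasi"), length.out = C))
  structure(list(A = A, A_dot = A_dot,
                 condition = rep(seq_len(C), each = T),
                 time_ms = rep(seq(0, by = dt_ms, length.out = T), C),
                 window_ms = c(0, dt_ms * (T - 1)), dt_ms = dt_ms,
                 C = C, T = T, N = ncol(A),
                 conditions = conds,
                 units = data.frame(unit_id = sprintf("u%02d", seq_len(ncol(A))),
                                    population_label = "M1"),
                 centered = FALSE, column_means = colMeans(A)),
            class = "stacked_matrices")
}
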