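test_that("split covariances match a brute-force oracle and add up", {
  resp <- make_random_resp(C = 3, T = 4, N = 2, seed = 21)
  S <- build_matrices(resp, window_ms = c(0, 30), center = FALSE)
  cov <- split_covariances(S)
  # elementwise oracle
  arr <- unstack_matrix(S$A, 3, 4)
  m <- apply(arr, c(2, 3), mean)
  Ca <- matrix(0, 2, 2); Ci <- matrix(0, 2, 2)
  mbar <- colMeans(m)
  for (i in 1:2) for (j in 1:2) {
    for (c in 1:3) for (t in 1:4)
      Ca[i, j] <- Ca[i, j] + (arr[c, t, i] - m[t, i]) * (arr[c, t, j] - m[t, j]) / 12
    for (t in 1:4)
      Ci[i, j] <- Ci[i, j] + (m[t, i] - mbar[i]) * (m[t, j] - mbar[j]) / 4
  }
  expect_equal(cov$C_across, Ca, tolerance = 1e-12)
  expect_equal(cov$C_ind, Ci, tolerance = 1e-12)
  # the two parts add to the total covariance of column-centered data
  Ac <- sweep(S$A, 2, colMeans(S$A), "-")
  expect_lt(max(abs(cov$C_ind + cov$C_across - crossprod(Ac) / 12)), 1e-8)

  # identical conditions: no across-condition variance
  resp2 <- resp
  for (c in 2:3) resp2$rates[c, , ] <- resp2$rates[1, , ]
  cov2 <- split_covariances(build_matrices(resp2, window_ms = c(0, 30)))
  expect_lt(max(abs(cov2$C_across)), 1e-12)

  # +/- paired conditions with zero mean at every time: no invariant part
  resp3 <- make_random_resp(C = 2, T = 4, N = 2, seed = 22)
  resp3$rates[2, , ] <- -resp3$rates[1, , ]
  cov3 <- split_covariances(build_matrices(resp3, window_ms = c(0, 30)))
  expect_lt(max(abs(cov3$C_ind)), 1e-12)
})

test_that("cost terms hit their boundary cases", {
  resp <- make_random_resp(C = 4, T = 10, N = 6, seed = 23)
  S <- build_matrices(resp, window_ms = c(0, 90))
  cfg <- hdr_config(k_total = 6, k_invar = 2, k_dyn = 4)
  # full basis reconstructs perfectly
  W_full <- diag(6)
  costs <- hdr_cost(W_full, S, cfg = cfg)
  expect_equal(costs$f_rec, 0, tolerance = 1e-8)

  # an invariant subspace with zero across-condition variance scores 0
  resp2 <- make_random_resp(C = 3, T = 10, N = 4, seed = 24)
  shared <- matrix(rnorm(10), 10, 1) %*% matrix(c(1, 0, 0, 0), 1, 4)
  for (c in 1:3) resp2$rates[c, , ] <- shared + 5
  resp2$rates[, , 2:4] <- resp2$rates[, , 2:4] +
    array(rnorm(3 * 10 * 3), c(3, 10, 3))   # condition-varying elsewhere
  S2 <- build_matrices(resp2, window_ms = c(0, 90))
  W <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  cfg2 <- hdr_config(k_total = 3, k_invar = 1, k_dyn = 2)
  expect_lt(hdr_cost(W, S2, cfg = cfg2)$f_invar, 1e-12)
})

test_that("dynamics term equals an independent regression oracle", {
  resp <- make_random_resp(C = 3, T = 12, N = 5, seed = 25)
  S <- build_matrices(resp, window_ms = c(0, 110))
  cfg <- hdr_config(k_total = 4, k_invar = 2, k_dyn = 2)
  set.seed(26)
  W <- pracma::randortho(5)[1:4, ]
  costs <- hdr_cost(W, S, cfg = cfg)
  Xd <- S$A %*% t(W[3:4, , drop = FALSE])
  Xdd <- S$A_dot %*% t(W[3:4, , drop = FALSE])
  beta <- stats::lm.fit(Xd, Xdd)$coefficients   # independent oracle
  expect_equal(costs$f_dyn, -sum((Xd %*% beta)^2), tolerance = 1e-8)
})

test_that("cost depends only on the partition subspaces", {
  resp <- make_random_resp(C = 4, T = 10, N = 8, seed = 27)
  S <- build_matrices(resp, window_ms = c(0, 90))
  cfg <- hdr_config()
  set.seed(28)
  W <- pracma::randortho(8)[1:6, ]
  c0 <- hdr_cost(W, S, cfg = cfg)
  for (rep in 1:5) {
    Ri <- pracma::randortho(2)
    Rd <- pracma::randortho(4)
    W2 <- rbind(Ri %*% W[1:2, ], Rd %*% W[3:6, ])
    c1 <- hdr_cost(W2, S, cfg = cfg)
    expect_equal(c1$f_rec, c0$f_rec, tolerance = 1e-8)
    expect_equal(c1$f_invar, c0$f_invar, tolerance = 1e-8)
    expect_equal(c1$f_dyn, c0$f_dyn, tolerance = 1e-6)
  }
})

test_that("analytic gradient matches central finite differences", {
  resp <- make_random_resp(C = 4, T = 10, N = 8, seed = 29)
  S <- build_matrices(resp, window_ms = c(0, 90))
  cfg <- hdr_config()
  cov <- split_covariances(S)
  h <- 1e-6
  set.seed(30)
  for (rep in 1:10) {
    W <- pracma::randortho(8)[1:6, ]
    g <- hdr_gradient(W, S, cov, cfg)
    fd <- matrix(NA_real_, 6, 8)
    for (i in 1:6) for (j in 1:8) {
      Wp <- W; Wp[i, j] <- Wp[i, j] + h
      Wm <- W; Wm[i, j] <- Wm[i, j] - h
      fd[i, j] <- (hdr_cost(Wp, S, cov, cfg)$total -
                     hdr_cost(Wm, S, cov, cfg)$total) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("with only the reconstruction term the fit is top-K PCA", {
  for (seed in 1:3) {
    resp <- make_random_resp(C = 5, T = 10, N = 12, seed = 100 + seed)
    S <- build_matrices(resp, window_ms = c(0, 90))
    cfg <- hdr_config(lambda = c(1, 0, 0), seed = seed)
    res <- fit_hdr(S, cfg)
    V <- svd(S$A, nu = 0, nv = 6)$v
    expect_lt(max(principal_angles(t(res$basis$W), V)), 1e-3)
  }
})

test_that("a noiseless planted model is recovered essentially exactly", {
  spec <- synthetic_spec(mode = "m1", n_units = 30, noise_sd = 1e-9)
  ds <- generate_dataset(spec, seed = 5)
  S <- build_matrices(ds$resp, window_ms = c(-100, 200))
  cfg <- hdr_config(seed = 5, normalize_terms = TRUE,
                    lambda = c(1, 100, 1))
  res <- fit_hdr(S, cfg)
  ai <- principal_angles(t(res$basis$W[1:2, ]), t(ds$truth$W_invar_true))
  ad <- principal_angles(t(res$basis$W[3:6, ]), t(ds$truth$W_dyn_true))
  expect_lt(max(ai) * 180 / pi, 1)
  expect_lt(max(ad) * 180 / pi, 1)
})

test_that("the optimizer respects its structural contracts", {
  resp <- make_random_resp(C = 4, T = 10, N = 10, seed = 31)
  S <- build_matrices(resp, window_ms = c(0, 90))
  cfg <- hdr_config(seed = 2, n_restarts = 2, max_iterations = 100)
  res <- fit_hdr(S, cfg)
  # orthonormality after retraction
  expect_lt(max(abs(tcrossprod(res$basis$W) - diag(6))), 1e-8)
  # monotone non-increasing cost over accepted iterations
  expect_true(all(diff(res$cost_trace$total) <= 1e-10))
  expect_lte(res$cost$total, res$cost_trace$total[1])
  # bit-identical rerun under the same seed and config
  res2 <- fit_hdr(S, cfg)
  expect_identical(res$basis$W, res2$basis$W)
  expect_identical(res$cost_trace, res2$cost_trace)
  # restart diagnostics present
  expect_length(res$restart_angles_deg, 2)
})

test_that("captured variance respects PCA optimality", {
  resp <- make_random_resp(C = 4, T = 10, N = 8, seed = 32)
  S <- build_matrices(resp, window_ms = c(0, 90))
  # full basis captures everything
  full <- projection_basis(diag(8), 2, 6)
  expect_equal(captured_variance(full, S)$total, 100, tolerance = 1e-9)
  # no orthonormal 6-set beats the top-6 PCs
  Ac <- S$A
  pc_var <- 100 * sum(svd(Ac)$d[1:6]^2) / sum(Ac^2)
  set.seed(33)
  for (rep in 1:5) {
    W <- pracma::randortho(8)[1:6, ]
    cv <- captured_variance(projection_basis(W, 2, 4), S)
    expect_lte(cv$total, pc_var + 1e-9)
  }
})

test_that("hdr on synthetic data beats the non-leading PCs it competes with", {
  spec <- synthetic_spec(mode = "m1", n_units = 40)
  ds <- generate_dataset(spec, seed = 8)
  S <- build_matrices(ds$resp, window_ms = c(-100, 200))
  res <- fit_hdr(S, hdr_config(seed = 8, normalize_terms = TRUE))
  sv <- svd(S$A)
  pcs_2_7 <- 100 * sum(sv$d[2:7]^2) / sum(sv$d^2)
  expect_gte(res$captured$total, pcs_2_7)
})
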