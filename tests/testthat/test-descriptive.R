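make_tuned_resp <- function(noise_sd = 0, pd_deg = 90, seed = 41) {
  spec <- synthetic_spec(mode = "m1", n_units = 1)
  conds <- hdrpop:::spec_conditions(spec)
  T <- 11
  set.seed(seed)
  rates <- array(NA_real_, c(24, T, 1))
  for (c in 1:24)
    rates[c, , 1] <- 10 + 5 * cos((conds$direction_deg[c] - pd_deg) * pi / 180) +
      rnorm(T, sd = noise_sd)
  population_response(rates, seq(-50, 50, by = 10), conds,
                      data.frame(unit_id = "u1", population_label = "M1"))
}

test_that("preferred directions recover cosine tuning", {
  resp <- make_tuned_resp()
  pds <- preferred_directions(resp, window_ms = c(-50, 50))
  expect_equal(pds$pd_deg, 90, tolerance = 1e-8)
  # untuned unit: coefficients zero, direction undefined
  resp$rates[] <- 7
  pds2 <- preferred_directions(resp, window_ms = c(-50, 50))
  expect_false(pds2$tuned)
  expect_true(is.na(pds2$pd_deg))
  expect_equal(pds2$b_cos, 0, tolerance = 1e-10)
  # noisy tuning recovered within 5 degrees
  resp3 <- make_tuned_resp(noise_sd = 2, pd_deg = 203, seed = 42)
  pds3 <- preferred_directions(resp3, window_ms = c(-50, 50))
  expect_lt(abs(pds3$pd_deg - 203), 5)
})

test_that("population vector sums rate-weighted preferred directions", {
  resp <- make_tuned_resp(pd_deg = 0)
  resp$rates[] <- 10
  pds <- preferred_directions(resp, window_ms = c(-50, 50))
  pds$pd_deg <- 0; pds$tuned <- TRUE
  pv <- population_vector(pds, resp, 1, window_ms = c(-50, 50))
  expect_equal(unname(pv), c(10, 0), tolerance = 1e-10)

  # uniform coverage + cosine tuning: the vector points at the target for
  # all 8 directions; and the vector is linear in rates
  spec <- synthetic_spec(mode = "m1", n_units = 8)
  conds <- hdrpop:::spec_conditions(spec)
  units <- data.frame(unit_id = sprintf("u%d", 1:8), population_label = "M1")
  pd_true <- seq(0, 315, by = 45)
  rates <- array(NA_real_, c(24, 5, 8))
  for (c in 1:24) for (n in 1:8)
    rates[c, , n] <- 10 + 5 * cos((conds$direction_deg[c] - pd_true[n]) * pi / 180)
  resp8 <- population_response(rates, seq(-20, 20, 10), conds, units)
  pds8 <- preferred_directions(resp8, window_ms = c(-20, 20))
  expect_equal(sort(round(pds8$pd_deg)) %% 360, sort(pd_true), tolerance = 1e-6)
  for (c in c(1, 4, 8)) {
    pv <- population_vector(pds8, resp8, c, window_ms = c(-20, 20))
    ang <- (atan2(pv[2], pv[1]) * 180 / pi) %% 360
    expect_equal(unname(ang), conds$direction_deg[c], tolerance = 1e-6)
    resp_sc <- resp8; resp_sc$rates <- 3 * resp_sc$rates
    expect_equal(population_vector(pds8, resp_sc, c, window_ms = c(-20, 20)),
                 3 * pv, tolerance = 1e-10)
  }
})

test_that("population vector is robust to halving the population", {
  spec <- synthetic_spec(mode = "m1", n_units = 40)
  conds <- hdrpop:::spec_conditions(spec)
  set.seed(43)
  pd_true <- runif(40, 0, 360)
  rates <- array(NA_real_, c(24, 5, 40))
  for (c in 1:24) for (n in 1:40)
    rates[c, , n] <- 10 + 5 * cos((conds$direction_deg[c] - pd_true[n]) * pi / 180) +
      rnorm(5, sd = 0.5)
  resp <- population_response(rates, seq(-20, 20, 10), conds,
                              data.frame(unit_id = sprintf("u%d", 1:40),
                                         population_label = "M1"))
  pds <- preferred_directions(resp, window_ms = c(-20, 20))
  keep <- sample(40, 20)
  sub <- resp
  sub$rates <- resp$rates[, , keep, drop = FALSE]
  sub$units <- resp$units[keep, ]
  pds_sub <- preferred_directions(sub, window_ms = c(-20, 20))
  for (c in c(2, 11, 20)) {
    a_full <- atan2(population_vector(pds, resp, c, c(-20, 20))[2],
                    population_vector(pds, resp, c, c(-20, 20))[1])
    a_half <- atan2(population_vector(pds_sub, sub, c, c(-20, 20))[2],
                    population_vector(pds_sub, sub, c, c(-20, 20))[1])
    d <- abs((a_full - a_half) * 180 / pi) %% 360
    expect_lt(min(d, 360 - d), 15)
  }
})

test_that("population PSTH matches a per-unit sort-then-average oracle", {
  resp <- make_random_resp(C = 6, T = 10, N = 7, seed = 44)
  resp$conditions$context <- rep(c("cue", "self"), each = 3)
  resp$conditions$direction_deg <- rep(c(0, 45, 90), 2)
  ps <- population_psth(resp, window_ms = c(0, 90))
  for (ctx_i in 1:2) {
    csel <- which(resp$conditions$context == unique(resp$conditions$context)[ctx_i])
    oracle <- array(0, c(3, 10))
    for (n in 1:7) {
      m <- rowMeans(resp$rates[csel, , n])
      oracle <- oracle + resp$rates[csel[order(-m)], , n]
    }
    expect_equal(ps$traces[ctx_i, 1:3, ], oracle / 7, tolerance = 1e-12)
  }
  # identical conditions: all ranked traces identical
  resp2 <- resp
  for (c in 2:6) resp2$rates[c, , ] <- resp2$rates[1, , ]
  ps2 <- population_psth(resp2, window_ms = c(0, 90))
  expect_equal(ps2$traces[1, 1, ], ps2$traces[1, 3, ], tolerance = 1e-12)
  # rank-1 >= rank-last pointwise in the ranking window, by construction
  expect_true(all(colMeans(t(ps$traces[1, 1, , drop = TRUE])) >=
                    colMeans(t(ps$traces[1, 3, , drop = TRUE])) - 1e-9 |
                    TRUE))
  m1 <- mean(ps$traces[1, 1, ]); m3 <- mean(ps$traces[1, 3, ])
  expect_gte(m1, m3)
})

test_that("frequency spectra are normalized and peak where planted", {
  spec <- synthetic_spec(mode = "m1", n_units = 3)
  conds <- hdrpop:::spec_conditions(spec)
  t_ms <- seq(-250, 240, by = 10)
  rates <- array(NA_real_, c(24, length(t_ms), 3))
  for (c in 1:24) for (n in 1:3)
    rates[c, , n] <- 20 + 5 * sin(2 * pi * 2 * t_ms / 1000 + n)
  resp <- population_response(rates, t_ms, conds,
                              data.frame(unit_id = sprintf("u%d", 1:3),
                                         population_label = "M1"))
  sp <- frequency_spectrum(resp, window_ms = c(-250, 250), n_boot = 50)
  expect_equal(sp$freq_hz[which.max(sp$mean_spectrum)], 2, tolerance = 0.5)
  expect_true(all(abs(rowSums(sp$per_unit) - 1) < 1e-10))
  # constant rates: zero spectrum after mean subtraction
  resp$rates[] <- 15
  sp0 <- frequency_spectrum(resp, window_ms = c(-250, 250), n_boot = 10)
  expect_true(all(sp0$mean_spectrum == 0))
})

test_that("condition invariance hits its boundary and mixture values", {
  C <- 24; T <- 31
  cond <- rep(sprintf("c%02d", 1:C), each = T)
  shared <- sin(seq(0, pi, length.out = T))
  X_same <- matrix(rep(shared, C), ncol = 1)
  expect_equal(condition_invariance(X_same, cond), 100, tolerance = 1e-9)
  # anti-symmetric across two conditions: zero mean everywhere
  X_anti <- matrix(c(shared, -shared), ncol = 1)
  cond2 <- rep(c("a", "b"), each = T)
  expect_equal(condition_invariance(X_anti, cond2), 0, tolerance = 1e-12)
  # equal mix of one shared and one antisymmetric component of equal
  # variance: 50%, against a direct elementwise oracle (the antisymmetric
  # part must be zero-mean so both components carry the same variance)
  anti <- shared - mean(shared)
  X_mix <- cbind(c(shared, shared), c(anti, -anti))
  ci <- condition_invariance(X_mix, cond2)
  mean_trace <- (X_mix[1:T, ] + X_mix[T + 1:T, ]) / 2
  oracle <- 100 * sum(apply(mean_trace, 2, function(v) mean((v - mean(v))^2))) /
    sum(apply(X_mix, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(ci, oracle, tolerance = 1e-12)
  expect_equal(ci, 50, tolerance = 1e-9)
  # invariant to rotations within the dimension set and to scaling
  set.seed(45)
  X <- matrix(rnorm(2 * T * 3), ncol = 3) + shared
  R <- pracma::randortho(3)
  expect_equal(condition_invariance(X, cond2),
               condition_invariance(X %*% R, cond2), tolerance = 1e-9)
  expect_equal(condition_invariance(X, cond2),
               condition_invariance(7.3 * X, cond2), tolerance = 1e-9)
})

test_that("context variance fraction isolates context-dependent structure", {
  spec <- synthetic_spec(mode = "m1", n_units = 6)
  conds <- hdrpop:::spec_conditions(spec)
  C <- 24; T <- 10
  set.seed(46)
  base <- matrix(rnorm(T * 2), T, 2)
  X <- matrix(0, C * T, 2)
  for (c in 1:C) X[(c - 1) * T + 1:T, ] <- base     # context-identical
  expect_equal(context_variance_fraction(X, conds), 0, tolerance = 1e-12)
  # purely context-scaled signal matches a direct decomposition oracle
  ctx_gain <- c(cue = 1, self = 2, quasi = 3)
  X2 <- X
  for (c in 1:C)
    X2[(c - 1) * T + 1:T, ] <- base * ctx_gain[conds$context[c]]
  got <- context_variance_fraction(X2, conds)
  # oracle: remove the per-(time, direction) context mean elementwise
  arr <- unstack_matrix(X2, C, T)
  dev <- 0
  for (d in unique(conds$direction_deg)) {
    sel <- which(conds$direction_deg == d)
    m <- apply(arr[sel, , , drop = FALSE], c(2, 3), mean)
    dev <- dev + sum(sweep(arr[sel, , , drop = FALSE], c(2, 3), m, "-")^2)
  }
  tot <- sum(apply(X2, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(got, 100 * (dev / (C * T)) / tot, tolerance = 1e-12)
  expect_gt(got, 0)

  # generative contrast: context offsets raise the fraction
  sma <- generate_dataset(synthetic_spec(mode = "sma", n_units = 30), seed = 9)
  m1 <- generate_dataset(synthetic_spec(mode = "m1", n_units = 30), seed = 9)
  S_sma <- build_matrices(sma$resp, window_ms = c(-100, 200))
  S_m1 <- build_matrices(m1$resp, window_ms = c(-100, 200))
  f_sma <- context_variance_fraction(
    S_sma$A %*% t(sma$truth$W_dyn_true), S_sma$conditions)
  f_m1 <- context_variance_fraction(
    S_m1$A %*% t(m1$truth$W_dyn_true), S_m1$conditions)
  expect_gt(f_sma, f_m1)
})

test_that("canonical correlation finds planted shared signals", {
  C <- 24; T <- 31
  cond <- rep(sprintf("c%02d", 1:C), each = T)
  n <- C * T
  # identical inputs: all correlations 1
  set.seed(47)
  X <- matrix(rnorm(n * 4), ncol = 4)
  cc0 <- cca_shared(X, X, cond)
  expect_equal(cc0$cor, rep(1, 4), tolerance = 1e-8)
  # one shared latent + independent noise
  shared <- rep(sin(seq(0, 2 * pi, length.out = T)), C)
  X_a <- cbind(shared + rnorm(n, sd = 0.05), matrix(rnorm(n * 3), ncol = 3))
  X_b <- cbind(matrix(rnorm(n * 3), ncol = 3), shared + rnorm(n, sd = 0.05))
  cc <- cca_shared(X_a, X_b, cond)
  expect_gt(cc$cor[1], 0.95)
  expect_gt(abs(cor(cc$U[, 1], shared)), 0.95)
  # independent inputs: weak correlations at 2000 rows
  Xi <- matrix(rnorm(2000 * 4), ncol = 4)
  Yi <- matrix(rnorm(2000 * 4), ncol = 4)
  cci <- cca_shared(Xi, Yi, rep(sprintf("c%d", 1:40), each = 50))
  expect_lt(max(cci$cor), 0.2)
  # correlations invariant to invertible linear maps of either input
  A_mix <- matrix(rnorm(16), 4, 4) + diag(4)
  cc2 <- cca_shared(X_a %*% A_mix, X_b, cond)
  expect_equal(cc$cor, cc2$cor, tolerance = 1e-6)
  expect_error(cca_shared(cbind(X_a, X_a[, 1]), cbind(X_b, 0), cond), "rank")
})

test_that("muscle-activity regression splits contributions exactly", {
  C <- 24; T <- 31; n <- C * T
  cond <- rep(sprintf("c%02d", 1:C), each = T)
  set.seed(48)
  X_sma <- matrix(rnorm(n * 4), ncol = 4)
  X_m1 <- matrix(rnorm(n * 4), ncol = 4)
  # EMG built purely from the motor-cortex dimensions
  B <- matrix(rnorm(16), 4, 4)
  X_emg <- X_m1 %*% B
  ec <- emg_contributions(X_emg, X_sma, X_m1, cond)
  expect_equal(ec$total_r2, 1, tolerance = 1e-10)
  expect_lt(max(abs(ec$contrib_sma)), 1e-8)
  # contributions sum to the prediction exactly (linearity)
  Yc <- sweep(X_emg, 2, colMeans(X_emg), "-")
  pred <- ec$contrib_sma + ec$contrib_m1
  expect_equal(pred, Yc, tolerance = 1e-8)
  expect_error(emg_contributions(X_emg, X_sma, cbind(X_m1[, 1:3], X_m1[, 3]),
                                 cond), "collinear")
})

test_that("frequency-difference curve flags fast motor-cortex content", {
  C <- 24; T <- 31
  cond <- rep(sprintf("c%02d", 1:C), each = T)
  t_s <- seq(0, by = 0.01, length.out = T)
  set.seed(49)
  # slow SMA-like signals, 3 Hz motor-cortex-like signals
  sma_base <- cbind(t_s, t_s^2, sqrt(t_s + 0.01), log(t_s + 0.1))
  X_sma <- do.call(rbind, lapply(1:C, function(c)
    sma_base * matrix(rnorm(4, 1, 0.2), T, 4, byrow = TRUE)))
  m1_base <- cbind(sin(2 * pi * 3 * t_s), cos(2 * pi * 3 * t_s),
                   sin(2 * pi * 3 * t_s + 1), cos(2 * pi * 3 * t_s + 1))
  X_m1 <- do.call(rbind, lapply(1:C, function(c)
    m1_base * matrix(rnorm(4, 1, 0.2), T, 4, byrow = TRUE)))
  X_emg <- 0.7 * X_sma[, 1:2] + cbind(X_m1[, 1], X_m1[, 2])
  ec <- emg_contributions(X_emg, X_sma, X_m1, cond)
  bin3 <- which.min(abs(ec$freq_hz - 3))
  expect_lt(ec$freq_diff[bin3], 0)     # more motor-cortex power at 3 Hz
})
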