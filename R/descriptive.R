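# Standard population analyses and summary statistics: preferred directions
# and the population vector, population PSTHs, frequency spectra,
# condition invariance, context-variance fraction, CCA shared signals, and
# the EMG-versus-neural-dimensions regression.

window_time_index <- function(time_ms, window_ms) {
  sel <- which(time_ms >= window_ms[1] - 1e-9 & time_ms <= window_ms[2] + 1e-9)
  if (!length(sel)) stopf("window [%g, %g] ms selects no samples",
                          window_ms[1], window_ms[2])
  sel
}

#' Preferred directions by cosine-tuning regression
#'
#' For each unit, regresses the movement-epoch mean firing rate (per
#' condition, averaged over a window centered on movement onset) on the
#' cosine and sine of target direction across all directions and contexts.
#' The preferred direction is the angle of the fitted coefficient vector.
#'
#' @param resp a [population_response()].
#' @param window_ms averaging window, ms (default `c(-250, 250)`, clipped to
#'   the data extent).
#' @return data.frame with one row per unit: `unit_id`, `pd_deg` (in
#'   `[0, 360)`, `NA` for untuned units), `b0`, `b_cos`, `b_sin`, `tuned`.
#'   The per-condition windowed mean rates are attached as attribute
#'   `"condition_means"` (conditions x units).
#' @export
preferred_directions <- function(resp, window_ms = c(-250, 250)) {
  stopifnot(inherits(resp, "population_response"))
  window_ms <- c(max(window_ms[1], min(resp$time_ms)),
                 min(window_ms[2], max(resp$time_ms)))
  tsel <- window_time_index(resp$time_ms, window_ms)
  if (length(unique(resp$conditions$direction_deg)) < 3)
    stopf("need at least 3 distinct reach directions")
  means <- apply(resp$rates[, tsel, , drop = FALSE], c(1, 3), mean)
  th <- resp$conditions$direction_deg * pi / 180
  Z <- cbind(1, cos(th), sin(th))
  B <- qr.solve(Z, means)                      # 3 x N coefficients
  amp <- sqrt(B[2, ]^2 + B[3, ]^2)
  scale_ref <- pmax(abs(B[1, ]), 1)
  tuned <- amp > 1e-8 * scale_ref
  pd <- (atan2(B[3, ], B[2, ]) * 180 / pi) %% 360
  pd[!tuned] <- NA_real_
  out <- data.frame(unit_id = resp$units$unit_id, pd_deg = pd,
                    b0 = B[1, ], b_cos = B[2, ], b_sin = B[3, ],
                    tuned = tuned)
  attr(out, "condition_means") <- means
  out
}

#' Population vector for one condition
#'
#' The rate-weighted sum of the units' preferred-direction unit vectors:
#' `sum_n rate_n(condition) * (cos pd_n, sin pd_n)`. Untuned units (no
#' defined preferred direction) are skipped.
#'
#' @param pds a [preferred_directions()] result for the same population.
#' @param resp the [population_response()].
#' @param condition condition index or `condition_id`.
#' @param window_ms rate-averaging window (should match the one used for
#'   `pds`).
#' @return numeric length-2 vector `(x, y)`.
#' @export
population_vector <- function(pds, resp, condition,
                              window_ms = c(-250, 250)) {
  stopifnot(inherits(resp, "population_response"))
  if (nrow(pds) == 0) stopf("empty population")
  if (is.character(condition))
    condition <- match(condition, resp$conditions$condition_id)
  if (is.na(condition) || condition < 1 || condition > nrow(resp$conditions))
    stopf("unknown condition")
  window_ms <- c(max(window_ms[1], min(resp$time_ms)),
                 min(window_ms[2], max(resp$time_ms)))
  tsel <- window_time_index(resp$time_ms, window_ms)
  rates <- apply(resp$rates[condition, tsel, , drop = FALSE], 3, mean)
  keep <- pds$tuned
  ang <- pds$pd_deg[keep] * pi / 180
  c(x = sum(rates[keep] * cos(ang)), y = sum(rates[keep] * sin(ang)))
}

#' Population PSTH (ranked condition averages per context)
#'
#' Within each context, each unit's direction-conditions are ranked by mean
#' rate over a window centered on movement onset (rank 1 = most-preferred;
#' ties broken by first occurrence). The rank-r traces are then averaged
#' across units, giving one trace per rank and context.
#'
#' @param resp a [population_response()].
#' @param window_ms ranking window, ms (clipped to the data extent).
#' @return list with `traces` (array contexts x ranks x times), `contexts`,
#'   `time_ms`.
#' @export
population_psth <- function(resp, window_ms = c(-250, 250)) {
  stopifnot(inherits(resp, "population_response"))
  window_ms <- c(max(window_ms[1], min(resp$time_ms)),
                 min(window_ms[2], max(resp$time_ms)))
  tsel <- window_time_index(resp$time_ms, window_ms)
  ctxs <- unique(resp$conditions$context)
  N <- dim(resp$rates)[3]; T <- length(resp$time_ms)
  n_rank <- max(table(resp$conditions$context))
  traces <- array(NA_real_, c(length(ctxs), n_rank, T),
                  dimnames = list(ctxs, NULL, NULL))
  for (ci in seq_along(ctxs)) {
    csel <- which(resp$conditions$context == ctxs[ci])
    if (length(csel) < 2) stopf("need >= 2 conditions per context")
    acc <- array(0, c(length(csel), T))
    for (n in seq_len(N)) {
      m <- rowMeans(matrix(resp$rates[csel, tsel, n], length(csel)))
      ord <- order(-m)                        # stable: first occurrence wins
      acc <- acc + matrix(resp$rates[csel[ord], , n], length(csel))
    }
    traces[ci, seq_along(csel), ] <- acc / N
  }
  list(traces = traces, contexts = ctxs, time_ms = resp$time_ms)
}

#' Population-averaged normalized frequency spectrum
#'
#' Per unit: the magnitude spectrum of each condition's mean-subtracted rate
#' over the window, averaged over conditions and normalized to unit sum.
#' The population spectrum is the average over units, with a bootstrap
#' confidence envelope from resampling units with replacement.
#'
#' @param resp a [population_response()].
#' @param window_ms analysis window, ms (clipped to the data extent).
#' @param n_boot bootstrap draws for the confidence envelope (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @param normalization `"sum"` (default: each unit's spectrum scaled to
#'   unit sum) or `"peak"` (scaled to unit maximum).
#' @return list with `freq_hz`, `mean_spectrum`, `ci_lower`, `ci_upper`,
#'   `per_unit` (units x frequencies).
#' @export
frequency_spectrum <- function(resp, window_ms = c(-250, 250),
                               n_boot = 1000, conf = 0.95, seed = 1,
                               normalization = c("sum", "peak")) {
  stopifnot(inherits(resp, "population_response"))
  normalization <- match.arg(normalization)
  window_ms <- c(max(window_ms[1], min(resp$time_ms)),
                 min(window_ms[2], max(resp$time_ms)))
  tsel <- window_time_index(resp$time_ms, window_ms)
  if (length(tsel) < 2) stopf("window must contain at least 2 samples")
  nT <- length(tsel)
  nb <- floor(nT / 2) + 1L
  freq_hz <- (seq_len(nb) - 1) * 1000 / (nT * resp$dt_ms)
  C <- dim(resp$rates)[1]; N <- dim(resp$rates)[3]
  per_unit <- matrix(0, N, nb)
  for (n in seq_len(N)) {
    acc <- numeric(nb)
    for (c in seq_len(C)) {
      x <- resp$rates[c, tsel, n]
      acc <- acc + Mod(stats::fft(x - mean(x)))[seq_len(nb)]
    }
    tot <- if (normalization == "sum") sum(acc / C) else max(acc / C)
    per_unit[n, ] <- if (tot > 1e-300) (acc / C) / tot else 0
  }
  mean_spec <- colMeans(per_unit)
  qs <- with_seed(seed, {
    draws <- matrix(NA_real_, n_boot, nb)
    for (b in seq_len(n_boot))
      draws[b, ] <- colMeans(per_unit[sample(N, N, replace = TRUE), ,
                                      drop = FALSE])
    apply(draws, 2, stats::quantile,
          probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  })
  list(freq_hz = freq_hz, mean_spectrum = mean_spec,
       ci_lower = qs[1, ], ci_upper = qs[2, ], per_unit = per_unit)
}

#' Condition invariance of a latent signal
#'
#' The variance (over time) of the across-condition mean divided by the
#' total variance across all times and conditions, as a percentage;
#' variances are summed across dimensions before forming the ratio. A
#' signal identical across conditions scores 100%; one whose
#' across-condition mean is zero at every time scores 0%. Population
#' (divide-by-n) moments are used so the boundary cases are exact.
#'
#' @param X numeric matrix (rows = stacked condition/time samples, columns =
#'   dimensions) or vector.
#' @param condition condition label per row; every condition must have the
#'   same number of rows in the same time order.
#' @return percent, a number in `(-Inf, 100]`.
#' @export
condition_invariance <- function(X, condition) {
  X <- as.matrix(X)
  condition <- as.character(condition)
  if (length(condition) != nrow(X))
    stopf("condition must have one entry per row of X")
  groups <- split(seq_len(nrow(X)), factor(condition, unique(condition)))
  sizes <- lengths(groups)
  if (length(groups) < 2) stopf("need at least 2 conditions")
  if (length(unique(sizes)) != 1)
    stopf("all conditions must have the same number of time samples")
  T <- sizes[[1]]
  mean_trace <- Reduce(`+`, lapply(groups, function(g)
    X[g, , drop = FALSE])) / length(groups)
  num <- sum(apply(mean_trace, 2, pop_var))
  den <- sum(apply(X, 2, pop_var))
  if (den <= 0) stopf("zero total variance")
  100 * num / den
}

#' Fraction of response variance that varies with context
#'
#' For each (time, direction) cell, activity is averaged across contexts;
#' the context variance is the mean squared deviation from that average, and
#' the fraction is reported relative to the total variance of the
#' (mean-centered) signal, summed over dimensions.
#'
#' @param X numeric matrix `CT x k`, condition-major stacked rows.
#' @param conditions the condition table (`direction_deg`, `context`), one
#'   row per condition, in stacking order.
#' @return percent of total variance attributable to context.
#' @export
context_variance_fraction <- function(X, conditions) {
  X <- as.matrix(X)
  C <- nrow(conditions)
  if (nrow(X) %% C != 0) stopf("row count is not a multiple of the condition count")
  T <- nrow(X) %/% C
  if (length(unique(conditions$context)) < length(VALID_CONTEXTS))
    stopf("all contexts must be present")
  arr <- unstack_matrix(X, C, T)
  dirs <- unique(conditions$direction_deg)
  ctx_var <- 0
  for (d in dirs) {
    csel <- which(conditions$direction_deg == d)
    sub <- arr[csel, , , drop = FALSE]
    m <- apply(sub, c(2, 3), mean)              # across-context mean
    dev <- sweep(sub, c(2, 3), m, "-")
    ctx_var <- ctx_var + sum(dev^2)
  }
  ctx_var <- ctx_var / nrow(X)
  tot <- sum(apply(X, 2, pop_var))
  if (tot <= 0) stopf("zero total variance")
  100 * ctx_var / tot
}

#' Shared signals between two populations via canonical correlation
#'
#' Applies CCA to two sets of latent trajectories with identical row
#' structure (same conditions x times), returning canonical correlations
#' (descending), the canonical variables, and the condition invariance of
#' each canonical variable on each side.
#'
#' @param X_a,X_b numeric matrices with the same rows (typically the six
#'   HDR latents of two areas).
#' @param condition condition label per row (for the per-variable condition
#'   invariance).
#' @return list with `cor`, `U`, `V` (canonical variables of each side),
#'   `invariance_a`, `invariance_b` (percent per canonical variable).
#' @export
cca_shared <- function(X_a, X_b, condition) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  if (nrow(X_a) != nrow(X_b)) stopf("inputs must share row structure")
  if (qr(X_a)$rank < ncol(X_a) || qr(X_b)$rank < ncol(X_b))
    stopf("rank-deficient input to CCA")
  cc <- stats::cancor(X_a, X_b)
  U <- sweep(X_a, 2, cc$xcenter, "-") %*% cc$xcoef
  V <- sweep(X_b, 2, cc$ycenter, "-") %*% cc$ycoef
  k <- length(cc$cor)
  list(cor = cc$cor,
       U = U[, seq_len(k), drop = FALSE], V = V[, seq_len(k), drop = FALSE],
       invariance_a = vapply(seq_len(k), function(j)
         condition_invariance(U[, j], condition), numeric(1)),
       invariance_b = vapply(seq_len(k), function(j)
         condition_invariance(V[, j], condition), numeric(1)))
}

#' Regress muscle activity on neural dynamical dimensions
#'
#' Each EMG dimension is regressed (after mean-centering) simultaneously
#' against the concatenated neural dimensions from the two areas; the fit is
#' the exact sum of an SMA contribution and a motor-cortex contribution.
#' Also returns the per-frequency difference in normalized power between
#' the two contributions (positive = more SMA power), averaged over
#' conditions and EMG dimensions, with standard errors across conditions.
#'
#' @param X_emg EMG latents (`CT x k_emg`).
#' @param X_sma,X_m1 neural latents (`CT x 4` each), same row structure.
#' @param condition condition label per row (condition-major, equal-length
#'   time blocks).
#' @param dt_ms sampling step in ms (for the frequency axis).
#' @return list with `r2` (per EMG dimension), `total_r2` (average),
#'   `coefficients`, `contrib_sma`, `contrib_m1` (matrices `CT x k_emg`),
#'   `freq_hz`, `freq_diff` (mean normalized-power difference, SMA - M1),
#'   `freq_diff_se`.
#' @export
emg_contributions <- function(X_emg, X_sma, X_m1, condition, dt_ms = 10) {
  X_emg <- as.matrix(X_emg); X_sma <- as.matrix(X_sma); X_m1 <- as.matrix(X_m1)
  n <- nrow(X_emg)
  if (nrow(X_sma) != n || nrow(X_m1) != n)
    stopf("inputs must share row structure")
  Z <- cbind(X_sma, X_m1)
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  kap <- kappa(Zc, exact = TRUE)
  if (kap > 1e8)
    stopf("collinear neural dimensions (condition number %.3g)", kap)
  Yc <- sweep(X_emg, 2, colMeans(X_emg), "-")
  beta <- qr.solve(Zc, Yc)
  ks <- ncol(X_sma)
  contrib_sma <- Zc[, seq_len(ks), drop = FALSE] %*%
    beta[seq_len(ks), , drop = FALSE]
  contrib_m1 <- Zc[, ks + seq_len(ncol(X_m1)), drop = FALSE] %*%
    beta[ks + seq_len(ncol(X_m1)), , drop = FALSE]
  pred <- contrib_sma + contrib_m1
  r2 <- vapply(seq_len(ncol(Yc)), function(j)
    1 - sum((Yc[, j] - pred[, j])^2) / sum(Yc[, j]^2), numeric(1))

  condition <- as.character(condition)
  groups <- split(seq_len(n), factor(condition, unique(condition)))
  T <- length(groups[[1]])
  nb <- floor(T / 2) + 1L
  freq_hz <- (seq_len(nb) - 1) * 1000 / (T * dt_ms)
  norm_power <- function(x) {
    p <- Mod(stats::fft(x - mean(x)))[seq_len(nb)]^2
    s <- sum(p)
    if (s > 1e-300) p / s else rep(0, nb)
  }
  per_cond <- t(vapply(groups, function(g) {
    rowMeans(vapply(seq_len(ncol(Yc)), function(j)
      norm_power(contrib_sma[g, j]) - norm_power(contrib_m1[g, j]),
      numeric(nb)))
  }, numeric(nb)))
  list(r2 = r2, total_r2 = mean(r2), coefficients = beta,
       contrib_sma = contrib_sma, contrib_m1 = contrib_m1,
       freq_hz = freq_hz,
       freq_diff = colMeans(per_cond),
       freq_diff_se = apply(per_cond, 2, stats::sd) / sqrt(nrow(per_cond)))
}
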