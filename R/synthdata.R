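# Synthetic population generator with known latent ground truth. Three
# modes emulate the study's populations:
#   m1  - a dominant condition-invariant translation plus two rotational
#         planes (1.5-3 Hz) whose phase/amplitude vary with reach direction;
#   sma - the same condition-invariant signal plus smooth condition-specific
#         trajectories NOT generated by any shared linear flow field, with
#         context-dependent offsets;
#   emg - weak condition-invariant structure plus multiphasic bursts with
#         inconsistent loop orientations; rates are nonnegative.
# Rates are latents %*% W_true (+ baseline + observation noise), with a
# seeded row-orthonormal mixing matrix W_true, optionally replaced by a
# Poisson spiking path (spike draws -> 20-ms Gaussian smoothing -> trial
# average).

#' Specify a synthetic population
#'
#' Defaults mirror the study conditions: 24 conditions (8 reach directions x
#' 3 contexts), a -100..200 ms movement-aligned epoch at 10-ms resolution,
#' rotational planes at 2.5 and 1.5 Hz, and a dominant condition-invariant
#' sigmoidal translation.
#'
#' @param mode `"m1"`, `"sma"` or `"emg"` (see module description).
#' @param n_units number of observed units N.
#' @param window_ms simulated epoch, ms relative to movement onset.
#' @param dt_ms sampling step in ms.
#' @param n_directions number of reach directions (evenly spaced).
#' @param planes list of rotational planes, each
#'   `list(freq_hz, amp, pref_deg, phase_offset)`: frequency in Hz, amplitude
#'   in (pre-normalization) spikes/s, direction of maximal amplitude, and a
#'   fixed phase offset (radians). Used in `"m1"` mode.
#' @param ci condition-invariant signal: `list(onset_ms, tau_ms, amps)` for
#'   two sigmoidal components (amps in spikes/s; second component rises
#'   later and more slowly).
#' @param context_offset amplitude (spikes/s) of constant per-context
#'   offsets applied to the condition-specific latents (SMA-like signature;
#'   default 4 in `"sma"` mode, 0 otherwise).
#' @param gp_amp,gp_length_ms amplitude and temporal length-scale of the
#'   smoothed-random-walk condition-specific latents (`"sma"` mode).
#' @param noise_sd observation noise standard deviation, spikes/s.
#' @param baseline_range range of per-unit constant baseline rates.
#' @param trials_per_condition if non-`NULL`, observe rates through the
#'   Poisson spiking path with this many trials per condition.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mode = c("m1", "sma", "emg"),
                           n_units = 140,
                           window_ms = c(-100, 200), dt_ms = 10,
                           n_directions = 8,
                           planes = list(
                             list(freq_hz = 2.5, amp = 8, pref_deg = 0,
                                  phase_offset = 0),
                             list(freq_hz = 1.5, amp = 6, pref_deg = 90,
                                  phase_offset = pi / 3)),
                           ci = list(onset_ms = -60, tau_ms = 120,
                                     amps = c(46, 36)),
                           context_offset = NULL,
                           gp_amp = 8, gp_length_ms = 100,
                           noise_sd = 0.5,
                           baseline_range = c(5, 20),
                           trials_per_condition = NULL) {
  mode <- match.arg(mode)
  if (is.null(context_offset)) context_offset <- if (mode == "sma") 4 else 0
  for (p in planes) if (p$freq_hz <= 0) stopf("plane frequencies must be > 0")
  structure(list(mode = mode, n_units = n_units, window_ms = window_ms,
                 dt_ms = dt_ms, n_directions = n_directions,
                 contexts = VALID_CONTEXTS, planes = planes, ci = ci,
                 context_offset = context_offset, gp_amp = gp_amp,
                 gp_length_ms = gp_length_ms, noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 trials_per_condition = trials_per_condition),
            class = "synthetic_spec")
}

spec_times <- function(spec) seq(spec$window_ms[1], spec$window_ms[2], by = spec$dt_ms)

spec_conditions <- function(spec) {
  dirs <- seq(0, 360 - 360 / spec$n_directions, by = 360 / spec$n_directions)
  data.frame(
    condition_id = paste(rep(spec$contexts, each = spec$n_directions),
                         sprintf("%03d", rep(dirs, times = length(spec$contexts))),
                         sep = "_"),
    direction_deg = rep(dirs, times = length(spec$contexts)),
    context = rep(spec$contexts, each = spec$n_directions))
}

sigmoid <- function(t, onset, tau) 1 / (1 + exp(-(t - onset) / tau))

# Finite-difference derivative matching build_matrices(): central interior,
# one-sided edges, per-step units.
fd_derivative <- function(x) {
  T <- length(x)
  d <- numeric(T)
  d[2:(T - 1)] <- (x[3:T] - x[1:(T - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[T] <- x[T] - x[T - 1]
  d
}

#' Generate latent trajectories with ground truth
#'
#' Builds the latent tensor (conditions x times x latents) for the given
#' mode. The first two latents are condition-invariant; the remaining four
#' are the condition-specific (dynamical in `"m1"` mode) latents. In `"m1"`
#' mode the rotational latents are an exact discrete rollout
#' `x[t+1] = x[t] (I + D_true)`, so the stored per-step derivatives satisfy
#' `x_dot = x D_true` at machine precision.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (only `"sma"`/`"emg"` condition-specific latents
#'   consume randomness).
#' @return list with `latents` (`C x T x 6`), `dlatents` (per-step
#'   derivatives, same shape) and `truth` (mode, indices of the invariant
#'   and dynamical latents, `D_true` and plane frequencies where defined).
#' @export
generate_latents <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  times <- spec_times(spec)
  conds <- spec_conditions(spec)
  C <- nrow(conds); T <- length(times)
  K <- 6L
  lat <- array(0, c(C, T, K))
  dlat <- array(0, c(C, T, K))

  # condition-invariant components (deterministic, identical across modes
  # up to the emg-mode attenuation)
  ci_scale <- if (spec$mode == "emg") 0.25 else 1
  ci1 <- ci_scale * spec$ci$amps[1] *
    sigmoid(times, spec$ci$onset_ms, spec$ci$tau_ms)
  # second component: a faster secondary shift shortly after movement onset,
  # temporally distinct from both the dominant slow shift and the rotations
  # so the generative partition is identifiable
  ci2 <- ci_scale * spec$ci$amps[2] *
    sigmoid(times, spec$ci$onset_ms + 80, spec$ci$tau_ms / 4)
  for (c in seq_len(C)) {
    lat[c, , 1] <- ci1; lat[c, , 2] <- ci2
    dlat[c, , 1] <- fd_derivative(ci1); dlat[c, , 2] <- fd_derivative(ci2)
  }

  truth <- list(mode = spec$mode, ci_idx = 1:2, dyn_idx = 3:6,
                times = times, conditions = conds)

  if (spec$mode == "m1") {
    D_true <- matrix(0, 4, 4)
    for (p in 1:2) {
      omega <- 2 * pi * spec$planes[[p]]$freq_hz * spec$dt_ms / 1000
      idx <- (p - 1) * 2 + 1:2
      D_true[idx, idx] <- matrix(c(0, omega, -omega, 0), 2, 2)
    }
    step_map <- diag(4) + D_true
    for (c in seq_len(C)) {
      th <- conds$direction_deg[c] * pi / 180
      x <- numeric(4)
      for (p in 1:2) {
        pl <- spec$planes[[p]]
        a <- pl$amp * (1 + 0.5 * cos(th - pl$pref_deg * pi / 180))
        ph <- th + pl$phase_offset
        x[(p - 1) * 2 + 1:2] <- a * c(cos(ph), sin(ph))
      }
      for (t in seq_len(T)) {
        lat[c, t, 3:6] <- x
        dlat[c, t, 3:6] <- x %*% D_true
        x <- as.numeric(x %*% step_map)
      }
    }
    truth$D_true <- D_true
    truth$freqs_hz <- vapply(spec$planes, `[[`, numeric(1), "freq_hz")
  } else if (spec$mode == "sma") {
    with_seed(derive_seed(seed, 11), {
      ell <- spec$gp_length_ms / spec$dt_ms
      kern <- stats::dnorm(seq(-ceiling(3 * ell), ceiling(3 * ell)), sd = ell)
      kern <- kern / sqrt(sum(kern^2))   # keep unit marginal variance
      for (c in seq_len(C)) for (k in 3:6) {
        z <- stats::rnorm(T + 2 * length(kern))
        sm <- stats::convolve(z, rev(kern), type = "filter")
        sm <- sm[seq_len(T) + floor((length(sm) - T) / 2)]
        lat[c, , k] <- spec$gp_amp * sm
      }
      # constant per-context offsets in the condition-specific dimensions
      ctx_i <- match(conds$context, spec$contexts)
      for (c in seq_len(C)) {
        off <- spec$context_offset * (ctx_i[c] - 2)
        lat[c, , 3] <- lat[c, , 3] + off
        lat[c, , 4] <- lat[c, , 4] - off / 2
      }
      for (c in seq_len(C)) for (k in 3:6)
        dlat[c, , k] <- fd_derivative(lat[c, , k])
    })
  } else { # emg
    with_seed(derive_seed(seed, 12), {
      for (c in seq_len(C)) {
        th <- conds$direction_deg[c] * pi / 180
        for (k in 3:6) {
          burst <- numeric(T)
          for (j in 1:2) {
            center <- stats::runif(1, 0, 150)
            width <- stats::runif(1, 25, 60)
            a <- spec$gp_amp * (0.5 + 0.5 * cos(th - (k - 3) * pi / 2)) *
              stats::runif(1, 0.5, 1.5)
            burst <- burst + a * exp(-(times - center)^2 / (2 * width^2))
          }
          lat[c, , k] <- burst
          dlat[c, , k] <- fd_derivative(burst)
        }
      }
    })
  }
  list(latents = lat, dlatents = dlat, truth = truth)
}

#' Generate a synthetic population response
#'
#' Observes the latents of [generate_latents()] through a seeded random
#' row-orthonormal mixing matrix `W_true`, adds per-unit baselines and
#' Gaussian rate noise (or, optionally, passes the noiseless rates through
#' an inhomogeneous-Poisson spiking path with 20-ms Gaussian smoothing and
#' trial averaging).
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the generator is bit-reproducible from
#'   `(spec, seed)`.
#' @return list with `resp` (a [population_response()]) and `truth`
#'   (ground-truth record: `W_true`, `W_invar_true`, `W_dyn_true`, latents,
#'   per-step derivatives, and in `"m1"` mode `D_true` and the plane
#'   frequencies; `clipped_fraction` for `"emg"` mode).
#' @export
generate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gl <- generate_latents(spec, seed)
  times <- spec_times(spec)
  conds <- spec_conditions(spec)
  C <- nrow(conds); T <- length(times); N <- spec$n_units
  if (N < 6) stopf("n_units must be at least the number of latents (6)")
  W_true <- with_seed(derive_seed(seed, 21), random_orthonormal_rows(6, N))
  baseline <- with_seed(derive_seed(seed, 22),
                        stats::runif(N, spec$baseline_range[1],
                                     spec$baseline_range[2]))
  signal <- array(0, c(C, T, N))
  flat <- stack_tensor(gl$latents) %*% W_true      # CT x N
  for (c in seq_len(C))
    signal[c, , ] <- flat[(c - 1) * T + seq_len(T), ]
  noiseless <- sweep(signal, 3, baseline, "+")
  label <- if (spec$mode == "emg") "EMG" else if (spec$mode == "sma") "SMA" else "M1"
  clipped <- 0
  if (label == "EMG") {
    clipped <- mean(noiseless < 0)
    noiseless[noiseless < 0] <- 0
  }
  if (is.null(spec$trials_per_condition)) {
    rates <- noiseless + with_seed(derive_seed(seed, 23),
                                   array(stats::rnorm(C * T * N, sd = spec$noise_sd),
                                         c(C, T, N)))
    if (label == "EMG") rates[rates < 0] <- 0
  } else {
    rates <- with_seed(derive_seed(seed, 24),
                       poisson_observe(noiseless, times, spec$dt_ms,
                                       spec$trials_per_condition))
  }
  units <- data.frame(unit_id = sprintf("u%03d", seq_len(N)),
                      population_label = label)
  resp <- population_response(rates, times, conds, units, dt_ms = spec$dt_ms)
  truth <- gl$truth
  truth$W_true <- W_true
  truth$W_invar_true <- W_true[1:2, , drop = FALSE]
  truth$W_dyn_true <- W_true[3:6, , drop = FALSE]
  truth$latents <- gl$latents
  truth$dlatents <- gl$dlatents
  truth$baseline <- baseline
  truth$clipped_fraction <- clipped
  list(resp = resp, truth = truth)
}

# Observe noiseless rates (spikes/s, clipped at 0) through per-trial
# inhomogeneous Poisson spiking at 1-ms resolution, followed by 20-ms
# Gaussian smoothing and trial averaging. The spike window is padded by
# 3 sigma on both sides (edge-value rate extrapolation) to avoid smoothing
# truncation at the epoch edges.
poisson_observe <- function(noiseless, times, dt_ms, n_trials, sigma_ms = 20) {
  d <- dim(noiseless)
  pad <- 3 * sigma_ms
  fine <- seq(times[1] - pad, times[length(times)] + pad, by = 1)
  rates <- array(NA_real_, d)
  for (c in seq_len(d[1])) for (n in seq_len(d[3])) {
    lam <- stats::approx(times, pmax(noiseless[c, , n], 0), xout = fine,
                         rule = 2)$y / 1000     # spikes per 1-ms bin
    counts <- matrix(stats::rpois(length(fine) * n_trials, lam),
                     nrow = length(fine))
    trials <- lapply(seq_len(n_trials),
                     function(r) rep(fine, counts[, r]))
    rates[c, , n] <- smooth_to_rate(trials, times, sigma_ms)
  }
  rates
}

#' Write a synthetic dataset plus its ground truth to disk
#'
#' Emits the rate-table/sidecar format of [write_population()] plus a
#' `ground_truth.json` holding the true subspaces, plane frequencies and
#' latent component variances.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_population(ds$resp, file.path(dir, "rates.csv"))
  tr <- ds$truth
  gt <- list(mode = tr$mode,
             W_invar_true = tr$W_invar_true,
             W_dyn_true = tr$W_dyn_true,
             freqs_hz = tr$freqs_hz,
             latent_variances = apply(tr$latents, 3,
                                      function(m) pop_var(as.numeric(m))),
             clipped_fraction = tr$clipped_fraction)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
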