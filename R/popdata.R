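# Data model, file I/O and preprocessing for trial-averaged population
# responses: rate tensors, soft-normalization, matrix stacking and time
# differentiation.

VALID_CONTEXTS <- c("cue", "self", "quasi")
VALID_POPULATIONS <- c("SMA", "M1", "EMG")

#' Construct a population response object
#'
#' The common currency of all analyses: a trial-averaged firing-rate tensor
#' (conditions x times x units) together with per-condition and per-unit
#' metadata. Conditions are reach direction x behavioral context; units carry
#' a population label (SMA, M1 or EMG).
#'
#' @param rates numeric array `C x T x N`, firing rates in spikes/s.
#' @param time_ms integer-valued vector of length `T`, milliseconds relative
#'   to movement onset, uniformly spaced.
#' @param conditions data.frame with columns `condition_id`, `direction_deg`
#'   (multiples of 45 in `[0, 315]`) and `context` (one of `"cue"`, `"self"`,
#'   `"quasi"`), one row per condition.
#' @param units data.frame with columns `unit_id` and `population_label`
#'   (one of `"SMA"`, `"M1"`, `"EMG"`), one row per unit.
#' @param dt_ms time step in ms (must match the spacing of `time_ms`).
#' @return an object of class `population_response`.
#' @export
population_response <- function(rates, time_ms, conditions, units, dt_ms = 10) {
  rates <- unname(rates)
  if (length(dim(rates)) != 3L)
    stopf("rates must be a 3-d array (conditions x times x units)")
  if (!all(is.finite(rates)))
    stopf("rates must all be finite")
  steps <- diff(time_ms)
  if (length(time_ms) != dim(rates)[2])
    stopf("time_ms length (%d) != time dimension (%d)", length(time_ms), dim(rates)[2])
  if (length(time_ms) > 1 &&
      (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9))
    stopf("time_ms must be strictly increasing with a constant step")
  if (length(time_ms) > 1 && abs(steps[1] - dt_ms) > 1e-9)
    stopf("dt_ms (%g) does not match time_ms spacing (%g)", dt_ms, steps[1])
  conditions <- as.data.frame(conditions)
  units <- as.data.frame(units)
  if (nrow(conditions) != dim(rates)[1])
    stopf("conditions rows (%d) != condition dimension (%d)", nrow(conditions), dim(rates)[1])
  if (nrow(units) != dim(rates)[3])
    stopf("units rows (%d) != unit dimension (%d)", nrow(units), dim(rates)[3])
  bad <- setdiff(unique(conditions$context), VALID_CONTEXTS)
  if (length(bad))
    stopf("unknown context label: %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(units$population_label), VALID_POPULATIONS)
  if (length(bad))
    stopf("unknown population label: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(conditions$condition_id))
    stopf("duplicate condition_id")
  if (anyDuplicated(units$unit_id))
    stopf("duplicate unit_id")
  emg <- units$population_label == "EMG"
  if (any(emg) && any(rates[, , emg, drop = FALSE] < 0))
    stopf("EMG rates must be nonnegative")
  structure(
    list(rates = rates, time_ms = as.numeric(time_ms),
         conditions = conditions, units = units, dt_ms = dt_ms,
         normalization = NULL),
    class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("population_response: %d conditions x %d times x %d units\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time: %g..%g ms (dt = %g ms), populations: %s\n",
              min(x$time_ms), max(x$time_ms), x$dt_ms,
              paste(unique(x$units$population_label), collapse = ", ")))
  if (!is.null(x$normalization))
    cat(sprintf("  soft-normalized (offset = %g spikes/s)\n",
                x$normalization$offset))
  invisible(x)
}

#' Read a population response from a rate table plus JSON sidecar
#'
#' The rate table is UTF-8 delimited text with header
#' `condition_id,direction_deg,context,time_ms,unit_id,rate`, one row per
#' (condition, time, unit) cell. The sidecar (same path with a `.json`
#' extension) records `dt_ms`, unit population labels and the context set.
#'
#' @param path path to the rate table (`.csv`); the sidecar is looked up at
#'   the same path with extension `.json`.
#' @return a validated [population_response()].
#' @export
load_population <- function(path) {
  if (!file.exists(path)) stopf("rate table not found: %s", path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) stopf("metadata sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "direction_deg", "context", "time_ms", "unit_id", "rate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("rate table missing columns: %s", paste(miss, collapse = ", "))

  cond_ids <- unique(tab$condition_id)   # first-appearance order
  unit_ids <- meta$units$unit_id %||% sort(unique(tab$unit_id))
  times <- sort(unique(tab$time_ms))
  C <- length(cond_ids); T <- length(times); N <- length(unit_ids)
  if (length(times) > 1) {
    steps <- diff(times)
    if (max(abs(steps - steps[1])) > 1e-9)
      stopf("non-uniform time grid in rate table")
  }
  key <- paste(tab$condition_id, tab$time_ms, tab$unit_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stopf("duplicate cell for key (condition,time,unit) = (%s)",
          gsub("\r", ",", dup))
  }
  if (nrow(tab) != C * T * N) {
    full <- expand.grid(condition_id = cond_ids, time_ms = times,
                        unit_id = unit_ids, stringsAsFactors = FALSE)
    fkey <- paste(full$condition_id, full$time_ms, full$unit_id, sep = "\r")
    missing_key <- setdiff(fkey, key)[1]
    stopf("missing cell for key (condition,time,unit) = (%s)",
          gsub("\r", ",", missing_key))
  }
  ci <- match(tab$condition_id, cond_ids)
  ti <- match(tab$time_ms, times)
  ui <- match(tab$unit_id, unit_ids)
  rates <- array(NA_real_, c(C, T, N))
  rates[cbind(ci, ti, ui)] <- tab$rate

  first <- !duplicated(tab$condition_id)
  conditions <- data.frame(condition_id = tab$condition_id[first],
                           direction_deg = tab$direction_deg[first],
                           context = tab$context[first])
  conditions <- conditions[match(cond_ids, conditions$condition_id), ]
  rownames(conditions) <- NULL
  units <- data.frame(unit_id = unit_ids,
                      population_label = meta$units$population_label[
                        match(unit_ids, meta$units$unit_id)])
  dt <- meta$dt_ms %||% (if (T > 1) diff(times)[1] else 10)
  population_response(rates, times, conditions, units, dt_ms = dt)
}

#' Write a population response to a rate table plus JSON sidecar
#'
#' Emits bit-identical files for identical inputs: rows are ordered by
#' condition, then time, then unit.
#'
#' @param resp a [population_response()].
#' @param path output path for the rate table; the sidecar is written at the
#'   same path with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_population <- function(resp, path) {
  C <- nrow(resp$conditions); T <- length(resp$time_ms); N <- nrow(resp$units)
  grid <- expand.grid(unit = seq_len(N), time = seq_len(T), cond = seq_len(C))
  # expand.grid varies its first factor fastest; reorder to condition-major
  tab <- data.frame(
    condition_id = resp$conditions$condition_id[grid$cond],
    direction_deg = resp$conditions$direction_deg[grid$cond],
    context = resp$conditions$context[grid$cond],
    time_ms = resp$time_ms[grid$time],
    unit_id = resp$units$unit_id[grid$unit],
    rate = resp$rates[cbind(grid$cond, grid$time, grid$unit)])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(dt_ms = resp$dt_ms,
               movement_onset_convention = "time_ms=0",
               units = resp$units,
               contexts = VALID_CONTEXTS)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Estimate a trial-averaged firing rate from spike times
#'
#' Each spike contributes a Gaussian kernel of unit area (one spike), scaled
#' to spikes/s; the result is averaged across trials. This is the standard
#' kernel-smoothed PSTH with a 20-ms Gaussian by default.
#'
#' @param spike_times list with one numeric vector of spike times (ms) per
#'   trial; a trial with no spikes is an empty vector.
#' @param grid time grid (ms) at which to evaluate the rate; must be uniform.
#' @param sigma_ms kernel standard deviation in ms (default 20).
#' @return numeric vector of rates (spikes/s), one per grid point.
#' @export
smooth_to_rate <- function(spike_times, grid, sigma_ms = 20) {
  if (!is.list(spike_times) || length(spike_times) == 0L)
    stopf("spike_times must be a non-empty list of per-trial spike vectors")
  if (sigma_ms <= 0) stopf("sigma_ms must be > 0")
  if (length(grid) > 1) {
    steps <- diff(grid)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9)
      stopf("grid must be uniform and increasing")
  }
  per_trial <- vapply(spike_times, function(st) {
    if (length(st) == 0L) return(rep(0, length(grid)))
    # dnorm is per-ms; x1000 converts spike density to spikes/s
    colSums(1000 * stats::dnorm(outer(st, grid, "-"), sd = sigma_ms))
  }, numeric(length(grid)))
  rowMeans(matrix(per_trial, nrow = length(grid)))
}

#' Read per-trial spike times for one unit
#'
#' Lines of `trial_id,spike_time_ms`; returns a list of spike-time vectors,
#' one per trial (in order of first appearance of each trial_id).
#'
#' @param path path to the spike file.
#' @return list of numeric vectors.
#' @export
read_spike_times <- function(path) {
  if (!file.exists(path)) stopf("spike file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(tab$spike_time_ms, factor(tab$trial_id, levels = unique(tab$trial_id)))
}

#' Soft-normalize unit firing rates
#'
#' Divides each unit's rates by (firing-rate range + offset), where the range
#' is the max minus min across all conditions and times in the analysis
#' epoch. With the default 5 spikes/s offset, high-rate units end up with
#' roughly unity range so that variance-seeking projections do not simply
#' track the loudest units. The per-unit factors are stored for inversion.
#'
#' @param resp a [population_response()].
#' @param offset nonnegative offset in spikes/s (default 5).
#' @param window_ms optional `c(start, end)` in ms; if given, ranges are
#'   computed only within this epoch (rates everywhere are still divided).
#' @return the normalized `population_response`, with `$normalization`
#'   recording per-unit factors and the offset.
#' @export
soft_normalize <- function(resp, offset = 5, window_ms = NULL) {
  stopifnot(inherits(resp, "population_response"))
  if (offset < 0) stopf("offset must be >= 0")
  tsel <- if (is.null(window_ms)) seq_along(resp$time_ms) else
    which(resp$time_ms >= window_ms[1] & resp$time_ms <= window_ms[2])
  if (!length(tsel)) stopf("window_ms selects no time samples")
  N <- dim(resp$rates)[3]
  factors <- vapply(seq_len(N), function(n) {
    r <- resp$rates[, tsel, n]
    diff(range(r)) + offset
  }, numeric(1))
  out <- resp
  out$rates <- sweep(resp$rates, 3, factors, "/")
  out$normalization <- list(offset = offset, factors = factors,
                            window_ms = window_ms)
  out
}

#' Undo soft normalization using the stored factors
#' @param resp a soft-normalized [population_response()].
#' @return the `population_response` on the original spikes/s scale.
#' @export
unnormalize <- function(resp) {
  if (is.null(resp$normalization)) stopf("response is not soft-normalized")
  out <- resp
  out$rates <- sweep(resp$rates, 3, resp$normalization$factors, "*")
  out$normalization <- NULL
  out
}

#' Stack a population response into analysis matrices
#'
#' Builds the `CT x N` data matrix `A` (condition-major stacking: row for
#' condition c, time t is `(c - 1) * T + t`) and its time derivative `A_dot`
#' in units of rate change per time step, using central differences at
#' interior samples and one-sided first differences at the window edges (no
#' rows are dropped).
#'
#' @param resp a [population_response()] (typically soft-normalized).
#' @param window_ms `c(start, end)` in ms relative to movement onset; must
#'   contain at least 3 time samples.
#' @param center if `TRUE` (default), each column of `A` has its mean over
#'   all rows removed (static per-unit offsets carry no temporal or
#'   condition information; derivatives are unaffected).
#' @param derivative one of `"central"` (default) or `"forward"`; boundary
#'   rows always use one-sided differences.
#' @return an object of class `stacked_matrices` with elements `A`, `A_dot`,
#'   `condition` (row -> condition index), `time_ms` (row -> time),
#'   `window_ms`, `dt_ms`, `C`, `T`, `N`, `conditions`, `units`,
#'   `column_means`.
#' @export
build_matrices <- function(resp, window_ms = c(0, 200), center = TRUE,
                           derivative = c("central", "forward")) {
  stopifnot(inherits(resp, "population_response"))
  derivative <- match.arg(derivative)
  tsel <- which(resp$time_ms >= window_ms[1] - 1e-9 &
                resp$time_ms <= window_ms[2] + 1e-9)
  if (!length(tsel)) stopf("window [%g, %g] ms is outside the data extent",
                           window_ms[1], window_ms[2])
  if (length(tsel) < 3) stopf("window must contain at least 3 time samples")
  C <- dim(resp$rates)[1]; T <- length(tsel); N <- dim(resp$rates)[3]
  A <- matrix(NA_real_, C * T, N)
  A_dot <- matrix(NA_real_, C * T, N)
  for (c in seq_len(C)) {
    block <- matrix(resp$rates[c, tsel, ], T, N)
    rows <- (c - 1L) * T + seq_len(T)
    A[rows, ] <- block
    d <- matrix(NA_real_, T, N)
    if (derivative == "central") {
      d[2:(T - 1), ] <- (block[3:T, , drop = FALSE] -
                           block[1:(T - 2), , drop = FALSE]) / 2
    } else {
      d[2:(T - 1), ] <- block[3:T, , drop = FALSE] -
        block[2:(T - 1), , drop = FALSE]
    }
    d[1, ] <- block[2, ] - block[1, ]
    d[T, ] <- block[T, ] - block[T - 1, ]
    A_dot[rows, ] <- d
  }
  column_means <- colMeans(A)
  if (center) A <- sweep(A, 2, column_means, "-")
  structure(
    list(A = A, A_dot = A_dot,
         condition = rep(seq_len(C), each = T),
         time_ms = rep(resp$time_ms[tsel], times = C),
         window_ms = window_ms, dt_ms = resp$dt_ms,
         C = C, T = T, N = N,
         conditions = resp$conditions, units = resp$units,
         centered = center, column_means = column_means),
    class = "stacked_matrices")
}

#' @export
print.stacked_matrices <- function(x, ...) {
  cat(sprintf("stacked_matrices: A is %d x %d (C = %d, T = %d), window [%g, %g] ms\n",
              nrow(x$A), ncol(x$A), x$C, x$T, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Unstack a CT x k matrix into a C x T x k array
#' @param M matrix with `C * T` rows, condition-major.
#' @param C,T numbers of conditions and time samples.
#' @return array `C x T x k`.
#' @export
unstack_matrix <- function(M, C, T) {
  M <- as.matrix(M)
  if (nrow(M) != C * T) stopf("row count %d != C*T = %d", nrow(M), C * T)
  out <- array(NA_real_, c(C, T, ncol(M)))
  for (c in seq_len(C))
    out[c, , ] <- M[(c - 1L) * T + seq_len(T), , drop = FALSE]
  out
}

#' Stack a C x T x k array into a CT x k matrix (condition-major)
#' @param arr array `C x T x k`.
#' @return matrix `CT x k`.
#' @export
stack_tensor <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2L) { arr <- array(arr, c(d, 1L)); d <- dim(arr) }
  out <- matrix(NA_real_, d[1] * d[2], d[3])
  for (c in seq_len(d[1]))
    out[(c - 1L) * d[2] + seq_len(d[2]), ] <- matrix(arr[c, , ], d[2], d[3])
  out
}
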