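# End-to-end orchestration: preprocess -> HDR -> dynamics -> descriptive
# analyses -> bootstraps, with a JSON report. The command-line interface in
# inst/cli/hdrpop.R is a thin wrapper over run_pipeline().

#' Assemble a pipeline configuration
#'
#' @param input path to a rate table (see [load_population()]), or `NULL`
#'   when `simulate` is given.
#' @param simulate `NULL`, or a list with `mode` (and optionally `n_units`,
#'   `noise_sd`, ...) forwarded to [synthetic_spec()].
#' @param analyses character vector of stages to run, a subset of
#'   `c("hdr", "dynamics", "jpca", "spectrum", "invariance")`.
#' @param windows named list of analysis windows in ms: `hdr` (projection
#'   fitting and condition invariance), `dynamics` (dynamical fits),
#'   `spectrum`.
#' @param hdr list of overrides for [hdr_config()].
#' @param soft_norm_offset soft-normalization offset, spikes/s.
#' @param n_bootstrap bootstrap repetitions for the PCA-LDS spectrum stage.
#' @param seed master seed recorded in every output.
#' @param output_dir directory for the report bundle (`NULL` = no files).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       analyses = c("hdr", "dynamics", "jpca",
                                    "spectrum", "invariance"),
                       windows = list(hdr = c(-100, 200),
                                      dynamics = c(0, 200),
                                      spectrum = c(-250, 250)),
                       hdr = list(), soft_norm_offset = 5,
                       n_bootstrap = 100, seed = 1, output_dir = NULL) {
  if (is.null(input) && is.null(simulate))
    stopf("either input or simulate must be given")
  if (!is.null(input) && !file.exists(input))
    stopf("input file not found: %s", input)
  structure(list(input = input, simulate = simulate, analyses = analyses,
                 windows = windows, hdr = hdr,
                 soft_norm_offset = soft_norm_offset,
                 n_bootstrap = n_bootstrap, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Loads (or simulates) a population, soft-normalizes it, fits HDR, fits
#' unconstrained / symmetric / skew / best-skew dynamics on the dynamical
#' dimensions, and runs the requested descriptive analyses. Writes
#' `report.json` (plus serialized intermediates) into
#' `cfg$output_dir` when set.
#'
#' @param cfg a [run_config()].
#' @return the report, a named list; every numeric output is traceable to a
#'   module operation whose parameters (windows, seeds) are recorded
#'   alongside.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  report <- list(seed = cfg$seed, windows = cfg$windows, stages = list())
  stage_time <- function(since) round(proc.time()[["elapsed"]] - since, 3)

  ts <- proc.time()[["elapsed"]]
  if (!is.null(cfg$input)) {
    resp <- load_population(cfg$input)
    report$input <- cfg$input
  } else {
    sim_args <- cfg$simulate
    spec <- do.call(synthetic_spec, sim_args[names(sim_args) != "seed"])
    ds <- generate_dataset(spec, seed = sim_args$seed %||% cfg$seed)
    resp <- ds$resp
    report$simulate <- sim_args
  }
  norm <- soft_normalize(resp, offset = cfg$soft_norm_offset)
  report$stages$preprocess <- list(
    n_conditions = nrow(resp$conditions), n_units = nrow(resp$units),
    dt_ms = resp$dt_ms, soft_norm_offset = cfg$soft_norm_offset,
    seconds = stage_time(ts))

  S_hdr <- build_matrices(norm, window_ms = cfg$windows$hdr)
  hdr_res <- NULL
  if ("hdr" %in% cfg$analyses) {
    ts <- proc.time()[["elapsed"]]
    hcfg <- do.call(hdr_config, c(cfg$hdr, list(seed = cfg$seed)))
    hdr_res <- fit_hdr(S_hdr, hcfg)
    report$stages$hdr <- list(
      cost = hdr_res$cost, converged = hdr_res$converged,
      n_iterations = hdr_res$n_iterations,
      captured_variance = hdr_res$captured,
      restart_angles_deg = hdr_res$restart_angles_deg,
      window_ms = cfg$windows$hdr, seed = cfg$seed,
      seconds = stage_time(ts))
  }

  if ("dynamics" %in% cfg$analyses) {
    if (is.null(hdr_res)) stopf("the dynamics stage requires the hdr stage")
    ts <- proc.time()[["elapsed"]]
    rows <- which(hdr_res$latents$time_ms >= cfg$windows$dynamics[1] &
                    hdr_res$latents$time_ms <= cfg$windows$dynamics[2])
    Xd <- hdr_res$latents$X_dyn[rows, , drop = FALSE]
    Xdd <- hdr_res$latents$X_dot_dyn[rows, , drop = FALSE]
    fit <- fit_linear_dynamics(Xd, Xdd, dt_ms = S_hdr$dt_ms)
    parts <- decompose_dynamics(fit, Xd, Xdd)
    best <- fit_best_skew(Xd, Xdd, dt_ms = S_hdr$dt_ms)
    report$stages$dynamics <- list(
      r2_unconstrained = fit$r2, r2_sym = parts$sym$r2,
      r2_skew = parts$skew$r2, r2_best_skew = best$r2,
      frequencies_hz = rotational_frequencies(best),
      window_ms = cfg$windows$dynamics, r2_baseline = fit$r2_baseline,
      seconds = stage_time(ts))
  }

  if ("invariance" %in% cfg$analyses) {
    if (is.null(hdr_res)) stopf("the invariance stage requires the hdr stage")
    ts <- proc.time()[["elapsed"]]
    report$stages$invariance <- list(
      condition_invariance_pct = condition_invariance(
        hdr_res$latents$X_invar, hdr_res$latents$condition),
      context_variance_pct = context_variance_fraction(
        hdr_res$latents$X_dyn, S_hdr$conditions),
      window_ms = cfg$windows$hdr, seconds = stage_time(ts))
  }

  if ("jpca" %in% cfg$analyses) {
    ts <- proc.time()[["elapsed"]]
    S_dyn <- build_matrices(norm, window_ms = cfg$windows$dynamics)
    jp <- run_jpca(S_dyn)
    spect <- pca_lds_spectrum(resp, window_ms = cfg$windows$dynamics,
                              n_reps = cfg$n_bootstrap, seed = cfg$seed)
    report$stages$jpca <- list(
      r2_best_skew = jp$r2, frequencies_hz = jp$frequencies_hz,
      pca_lds_r2 = c(mean = spect$r2_mean, sem = spect$r2_sem),
      pca_lds_max_im = c(mean = spect$max_im_mean, sem = spect$max_im_sem),
      n_bootstrap = cfg$n_bootstrap, window_ms = cfg$windows$dynamics,
      seed = cfg$seed, seconds = stage_time(ts))
  }

  if ("spectrum" %in% cfg$analyses) {
    ts <- proc.time()[["elapsed"]]
    sp <- frequency_spectrum(norm, window_ms = cfg$windows$spectrum,
                             n_boot = cfg$n_bootstrap, seed = cfg$seed)
    report$stages$spectrum <- list(
      freq_hz = sp$freq_hz, mean_spectrum = sp$mean_spectrum,
      ci_lower = sp$ci_lower, ci_upper = sp$ci_upper,
      n_boot = cfg$n_bootstrap, window_ms = cfg$windows$spectrum,
      seed = cfg$seed, seconds = stage_time(ts))
  }

  report$total_seconds <- stage_time(t0)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(hdr_res))
      write_hdr_result(hdr_res, file.path(cfg$output_dir, "hdr"))
  }
  invisible(report)
}
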