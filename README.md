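# hdrpop

Hypothesis-guided dimensionality reduction (HDR) and dynamical-systems
analyses for trial-averaged neural population recordings.

The package is for researchers comparing population *dynamics* across
cortical areas (for example supplementary motor area versus motor cortex)
and muscles during reaching tasks. Single-unit statistics in such areas can
look almost interchangeable; the differences appear at the population
level, in whether the state trajectory contains (a) a large
condition-invariant translation around movement onset and (b) orthogonal
dimensions whose evolution follows a linear — and, in motor cortex,
strongly rotational, 1.5–3 Hz — flow field. `hdrpop` estimates exactly that
structure and quantifies it.

## The method

Trial-averaged rates (soft-normalized: each unit divided by its
firing-rate range + 5 spikes/s) are stacked into a `CT × N` matrix `A` with
per-step derivatives `Ȧ`. Latents are `X = A Wᵀ` through a row-orthonormal
`K × N` projection `W = [W_invar; W_dyn]` (default 2 + 4 = 6 dimensions)
found by minimizing a tripartite cost on the Stiefel manifold:

    f(W) = ‖A − A WᵀW‖²_F                                   (reconstruction, = PCA)
         + tr(W_invar C_across W_invarᵀ) / tr(W_invar C_ind W_invarᵀ)   (condition invariance)
         − ‖X_dyn X_dyn⁺ Ẋ_dyn‖²_F                          (linear-dynamics fit)

`C_ind` is the covariance of the cross-condition mean trace, `C_across`
the covariance of the residuals around it. Minimization is projected
gradient descent with exact analytic gradients, Barzilai–Borwein steps,
Armijo backtracking and QR retraction, from a PCA-seeded plus random
restarts.

The dynamical latents are then scored by unconstrained linear dynamics
`Ẋ ≈ X D` (least squares), by the symmetric/skew-symmetric parts of `D`,
and by the best purely rotational system `D*_skew = argmin ‖Ẋ − X D‖_F`
subject to `D = −Dᵀ` (exact normal equations in the skew basis). Rotational
frequencies come from the imaginary parts of the eigenvalues:
`f = |Im λ| / (2π Δt)` — an imaginary component of 0.144 per 10-ms step is
2.3 Hz. Surrounding analyses include condition-invariance and
context-variance statistics, jPCA and PCA + LDS eigenvalue-spectrum
baselines, CCA shared-signal analysis, EMG-versus-neural regression with
per-area contributions, population vectors, population PSTHs, frequency
spectra, and three bootstrap procedures (condition redraw, conservative
dimension redraw, neuron redraw).

Because the study's recordings are not redistributable, the package ships
a synthetic population generator with known ground truth (motor-cortex-like,
SMA-like, and muscle-like modes) that serves as the test bed for every
estimator.

## Worked example

```r
library(hdrpop)

spec <- synthetic_spec(mode = "m1", n_units = 60)   # 24 conditions, -100..200 ms
ds   <- generate_dataset(spec, seed = 1)

S   <- build_matrices(ds$resp, window_ms = c(-100, 200))
res <- fit_hdr(S, hdr_config(seed = 1, normalize_terms = TRUE))
res
#> hdr_result: K = 6 (2 invariant + 4 dynamical), N = 60 units
#>   cost -0.164287 after 127 iterations (converged), best of 3 restarts
#>   variance captured: invariant 57.9%, dynamical 38.8%, total 96.6%
#>   max cross-restart principal angle: 0.01 deg

rows <- which(res$latents$time_ms >= 0)              # movement epoch
Xd   <- res$latents$X_dyn[rows, ]
Xdd  <- res$latents$X_dot_dyn[rows, ]
fit_linear_dynamics(Xd, Xdd)
#> dynamics_fit (unconstrained): k = 4, R^2 = 0.836 (mean baseline)
#>   rotational frequencies (Hz): 2.43, 1.52
fit_best_skew(Xd, Xdd)
#> dynamics_fit (best_skew): k = 4, R^2 = 0.830 (mean baseline)
#>   rotational frequencies (Hz): 2.45, 1.48

condition_invariance(res$latents$X_invar, res$latents$condition)
#> [1] 99.8
```

Read this as: the six recovered dimensions capture 96.6% of the population
variance; the two invariant dimensions carry a signal that is 99.8%
identical across the 24 conditions; the four dynamical dimensions are well
fit by linear dynamics (R² = 0.84) that are almost purely rotational
(best-skew R² = 0.83) at 2.45 and 1.48 Hz — recovering the generator's
planted 2.5 / 1.5 Hz planes. An SMA-like dataset run through the same
pipeline gives a low unconstrained R² with a much lower skew share, the
qualitative signature that separates the two areas.

A thin command-line wrapper is installed at `inst/cli/hdrpop.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hdrpop.R", package="hdrpop"))')" \
    simulate --mode m1 --seed 1 --output-dir out/
Rscript "$(Rscript -e 'cat(system.file("cli/hdrpop.R", package="hdrpop"))')" \
    analyze --input out/rates.csv --hdr --dynamics --invariance --output-dir out/
```

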