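---
title: "Hypothesis-guided dimensionality reduction for neural population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypothesis-guided dimensionality reduction for neural population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrpop)
```

## The scientific problem

Motor-related cortical areas produce trial-averaged firing-rate patterns
whose population-level structure is hypothesized to contain two distinct
kinds of signal during reaching: a *condition-invariant* translation of the
population state around movement onset (nearly identical regardless of reach
direction or behavioral context), and *dynamical* structure in orthogonal
dimensions, where the state evolves under an approximately linear —
and, in motor cortex, strongly rotational — flow field at 1.5–3 Hz.
`hdrpop` implements an estimation framework for this hypothesis and the
descriptive and inferential analyses that surround it.

## The model

Trial-averaged rates are arranged as a matrix $A$ of size $CT \times N$
($C$ conditions, $T$ time samples, $N$ units, condition-major stacking),
with per-step time derivatives $\dot A$ (central differences in the
interior, one-sided at the window edges, so no rows are dropped). Latent
variables are a linear readout $X = A W^\top$ through a $K \times N$
row-orthonormal projection $W = [W_{\mathrm{invar}}; W_{\mathrm{dyn}}]$,
partitioned into $k_{\mathrm{invar}}$ condition-invariant and
$k_{\mathrm{dyn}}$ dynamical dimensions (defaults $2 + 4 = 6$).

$W$ minimizes a tripartite cost over the Stiefel manifold:

$$
f(W) = \lambda_{\mathrm{rec}}\, \lVert A - A W^\top W \rVert_F^2
 + \lambda_{\mathrm{invar}}\,
   \frac{\operatorname{tr}(W_{\mathrm{invar}} C_{\mathrm{across}} W_{\mathrm{invar}}^\top)}
        {\operatorname{tr}(W_{\mathrm{invar}} C_{\mathrm{ind}} W_{\mathrm{invar}}^\top)}
 - \lambda_{\mathrm{dyn}}\,
   \lVert X_{\mathrm{dyn}} X_{\mathrm{dyn}}^{+} \dot X_{\mathrm{dyn}} \rVert_F^2 .
$$

The first term is the PCA reconstruction cost. In the second,
$C_{\mathrm{ind}}$ is the covariance (over time) of the cross-condition mean
trace and $C_{\mathrm{across}}$ the covariance of the residuals around that
mean; the ratio is small when the invariant latents vary with time but not
condition. The third term is the negative of the derivative variance
captured by the best unconstrained linear dynamical fit
$\dot X_{\mathrm{dyn}} \approx X_{\mathrm{dyn}} D$ with
$D = X_{\mathrm{dyn}}^{+} \dot X_{\mathrm{dyn}}$. Both covariance parts use
population (divide-by-$n$) scaling, under which they sum exactly to the
total covariance of the column-centered data.

Downstream, the dynamical latents are scored by unconstrained, symmetric,
skew-symmetric, and best-fit purely rotational linear dynamics. The
skew-constrained problem
$\min_D \lVert \dot X - X D\rVert_F \ \text{s.t.}\ D = -D^\top$
is linear in the $k(k-1)/2$ free parameters and solved exactly by normal
equations in the elementary skew basis; in 2-D this reduces to the closed
form $\omega = \sum(x_1 \dot x_2 - x_2 \dot x_1) / \sum(x_1^2 + x_2^2)$.
Eigenvalues are in per-time-step units; rotational frequencies are
$f = |\mathrm{Im}\,\lambda| / (2\pi\, \Delta t)$ with $\Delta t$ in seconds.
With $\Delta t = 10$ ms, an imaginary component of 0.144 per step is 2.3 Hz.

## Optimization

`fit_hdr()` performs projected gradient descent on the Stiefel manifold:
the exact Euclidean gradient of every term (including the dynamics term's
gradient through the pseudoinverse) is projected onto the tangent space at
$W$, a Barzilai–Borwein step length is proposed, safeguarded by Armijo
backtracking, and the iterate is retracted by QR re-orthonormalization with
sign correction. Accepted steps never increase the cost, and row
orthonormality is maintained to $10^{-8}$ or better. Gradient correctness is
defined operationally — agreement with central finite differences to a
relative error below $10^{-4}$ at random ambient points — and enforced by
the test suite.

Convergence is declared when the cost change over 10 iterations falls below
$10^{-10}$ absolutely or $10^{-8}$ relatively (or the line search can make
no further progress at numerical precision); `max_iterations` defaults to
500. Restart 1 is seeded from the top-$K$ principal components with the
invariant rows pre-aligned to the leading eigenvectors of
$C_{\mathrm{ind}}$; the remaining restarts (3 by default) are random
orthonormal, and the best final cost wins. Principal angles between the
restarts' spans are reported as a stability diagnostic; on well-structured
data the restarts typically agree to within a degree.

Returned dimensions are put in a canonical order, which is free because
every cost term depends only on the two partition subspaces: invariant
dimensions by captured variance, dynamical dimensions grouped into
rotational planes (from the best-skew fit's conjugate eigenvector pairs)
ordered by frequency, each plane oriented so rotation is counter-clockwise
in plotted coordinates.

## Scale of the cost terms

The three terms have heterogeneous units: the reconstruction and dynamics
terms are sums of squares on the data scale, while the invariance term is a
dimensionless ratio. On soft-normalized data (each unit divided by its
firing-rate range + 5 spikes/s, the standard preprocessing applied by
`soft_normalize()` and the pipeline), unit weights behave sensibly. On data
whose overall scale is large, the absolute-scale dynamics term can dominate
the ratio-scale invariance term and absorb condition-invariant signal whose
derivative is even partially predictable from the latent state. The
`normalize_terms` option divides the reconstruction term by the total data
variance and the dynamics term by the total derivative variance, making the
weights scale-free; it is off by default (matching the plain three-term
sum) and switched on in the package's own parameter-recovery experiments,
where the generative amplitudes are on the spikes/s scale. Robustness to
down-weighting the invariance term by a factor of ten is part of the test
suite's expectations for well-separated data.

## What the synthetic generator emulates

`synthetic_spec()` / `generate_dataset()` manufacture populations with
known ground truth, in three modes sharing one observation model: six
latent time courses mixed into $N$ units through a seeded random
row-orthonormal matrix, plus per-unit baselines (uniform 5–20 spikes/s) and
i.i.d. Gaussian rate noise (default sd 0.5 spikes/s), or optionally an
inhomogeneous-Poisson spiking path (1-ms bins, 20-ms Gaussian smoothing,
trial averaging) applied to the noiseless rates.

* **m1 mode** — two condition-invariant components plus two rotational
  planes (defaults 2.5 and 1.5 Hz) whose initial phase follows reach
  direction and whose amplitude follows a cosine rule around a preferred
  direction; contexts share phases. The rotational latents are an exact
  Euler rollout $x_{t+1} = x_t(I + D_{\mathrm{true}})$, so the stored
  derivatives satisfy $\dot x = x D_{\mathrm{true}}$ at machine precision
  and the noiseless fit attains $R^2 = 1$.
* **sma mode** — the same condition-invariant components, but the
  condition-specific latents are independent Gaussian-process-smoothed
  random walks per condition (length scale 100 ms) — explicitly *not*
  generated by any shared flow field — plus constant per-context offsets
  (default 4 spikes/s) in the condition-specific dimensions.
* **emg mode** — attenuated condition-invariant structure plus multiphasic
  direction-tuned bursts with randomized centers and widths (inconsistent
  loop orientations); rates are clipped at zero and the clipped fraction is
  reported.

The condition-invariant signal is a dominant slow sigmoidal shift (onset
−60 ms, time constant 120 ms, 46 spikes/s) plus a faster secondary shift
just after movement onset (30-ms time constant, 36 spikes/s). Three
properties of these shapes are deliberate and matter for identifiability:
the shift carries variance comparable to the leading rotational plane (the
condition-invariant dimensions should rival the top two PCs); it is slow
relative to the rotations, so its derivative power does not dominate the
dynamics term; and the two components' derivative time courses are nearly
unpredictable from the span of the latent states themselves. When the last
condition fails — for example, two CI shapes whose difference resembles one
of their derivatives — the printed cost genuinely prefers to place the
predictable part of the CI derivative in the dynamical dimensions, and no
optimizer can (or should) undo that: the generator would then be
unidentifiable as a validation bed. The near-optimum is extremely flat in
the partition angle (cost differences of order $10^{-10}$ across several
degrees), so exact noiseless recovery is demonstrated under a strongly
hypothesis-weighted configuration ($\lambda_{\mathrm{invar}} = 100$,
normalized terms), while the moderate-noise recovery experiment uses unit
weights with normalized terms and achieves principal angles below 10°.

Features of real recordings the generator does not emulate: temporally
correlated (smoothing-induced) noise in the Gaussian path, heterogeneous
per-unit noise, latent dimensionality beyond six, non-stationary
frequencies, or trial-to-trial behavioral covariates. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not performance guarantees on real data.

## Descriptive and inferential conventions

* **Condition invariance** — variance (over time) of the across-condition
  mean divided by total variance over all times and conditions, as a
  percentage, variances summed across dimensions before the ratio is
  formed; population moments make the identical-across-conditions case
  exactly 100%.
* **Context variance fraction** — for every (time, direction) cell the mean
  across the three contexts is removed; the fraction is the mean squared
  deviation over the total variance of the mean-centered signal. This
  explicit decomposition is this package's definition and is recorded in
  output metadata.
* **Frequency spectra** — per unit, magnitude spectra of each condition's
  mean-subtracted trace are averaged over conditions and normalized to unit
  sum (`"peak"` normalization is available); the population average carries
  a percentile confidence envelope from resampling units.
* **$R^2$ baseline** — residuals are measured against the column means of
  $\dot X$ by default (`r2_baseline = "zero"` is available); negative
  values for a skew part simply mean its predictions are worse than that
  baseline. The choice is recorded in every fit object.
* **jPCA baseline** — cross-condition mean removal, projection onto the top
  six PCs, then the best-skew fit; the mean removal makes the result
  exactly invariant to any additive condition-invariant signal. The
  PCA-based variant fits an unconstrained system and reports eigenvalue
  spectra over 100 unit-resampling repetitions (degenerate resamples are
  redrawn and counted, keeping the repetition count fixed).
* **Bootstraps** — the condition redraw resamples the condition multiset
  (shared by both areas per draw); the p-value is the fraction of draws in
  which the effect was not observed, reported as the bound $1/n$ rather
  than zero after a clean sweep. The conservative dimension redraw pools
  the two areas' four dynamical dimensions, draws two four-dimensional
  pseudo-areas (independently; a disjoint variant exists), and compares the
  observed statistic difference against the null of such differences —
  two-sided on the absolute difference by default (so a zero observed
  difference yields $p = 1$), with a signed one-sided option; sidedness is
  recorded in the result.
* **Population vector / PSTH** — preferred directions come from regressing
  windowed mean rates on the cosine and sine of target direction across all
  24 conditions; untuned units are flagged and excluded from the vector
  sum. PSTH ranking ties break by first occurrence.

## Numerical choices and degenerate inputs

Columns of $A$ are mean-centered by default in `build_matrices()` (a static
per-unit offset carries no temporal or condition information; derivatives
are unaffected; the option is exposed). A degenerate invariant subspace
(zero condition-independent variance) makes the invariance ratio infinite:
it is reported as `Inf` with a warning rather than an error. Rank-deficient
dynamical latents are an error naming the deficient columns; a
zero-variance derivative matrix is an error because $R^2$ is undefined.
`NaN` in the cost aborts optimization; mere non-convergence within the
iteration budget flags the result instead.

## Problem sizes

The test suite and examples run at the package's reference sizes: 24
conditions (8 directions × 3 contexts), 31 samples (−100 to +200 ms at
10 ms), and populations of 20–96 units (60 for the parameter-recovery
experiments, mirroring a modest electrode yield); bootstrap calibrations
use a few hundred draws. These sizes make the full suite run in well under
a minute while leaving every statistical contrast comfortably clear of its
threshold.

## Known limitations

The cost's partition between invariant and dynamical subspaces is decided
by competition between a ratio-scale and an absolute-scale term; its
finite-noise optimum can tilt the weakest invariant direction a few degrees
toward structured noise (the ratio's denominator rewards directions whose
sample cross-condition mean is large). The package reports restart
diagnostics and captured variance so such tilts are visible, but does not
attempt to correct them. Only one partition into two blocks is supported
(no automatic selection of $K$), fits are single-matrix linear dynamical
systems (no inputs, no switching), and per-trial state-space analyses are
out of scope.
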