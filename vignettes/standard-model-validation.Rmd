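---
title: "Validating Standard Model parameters with axon-level ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating Standard Model parameters with axon-level ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonsm)
```

## The model and its two arms

White-matter diffusion MRI at moderate b-values is well described by the
Standard Model (SM): a voxel is a collection of identical fiber fascicles with
orientation density P(n̂), each fascicle responding with a kernel of
non-exchanging Gaussian compartments — a zero-radius "stick" of diffusivity
`Da` inside axons, an axially symmetric extra-axonal tensor `(De∥, De⊥)`, and
optionally isotropic free water. The signal is the spherical convolution of
P(n̂) with the kernel, which in the real even spherical-harmonic basis
factorizes per degree, `slm = plm Kl(b, ξ)`; everything this package does
hangs off that identity.

The validation question is whether the kernel parameters and the FOD summary
statistics that SM estimators report actually track the anatomy. The package
answers it on synthetic anatomy, where ground truth is exact, by comparing
two computational arms sample by sample:

* the **morphometry arm** measures the generated axon skeletons directly:
  dispersion angle `θ = cos⁻¹√⟨cos²θi⟩` (length-weighted over tangent
  segments), the tangent FOD and its invariants `pl`, the myelin-excluded
  volume fraction `f`, axial tortuosity `Λ∥ = ⟨Ā/A(z)⟩`, undulation
  dispersion `⟨cos²θu⟩`, and the predicted intra-axonal diffusivity
  `D̃a = Σ wk (D0/Λ∥,k)⟨cos²θu⟩k` (volume weights, `D0 = 2 μm²/ms` at room
  temperature);
* the **dMRI arm** simulates the protocol (3 shells at b = 2, 3, 4 ms/μm²
  with 43 directions each plus 3 b0; δ = 6 ms, Δ = 11.5 ms as metadata) and
  runs the four estimators.

## What the generator emulates — and what it does not

`generate_population()` produces ordered 3d centerlines with per-point
cross-sectional areas and a myelin annulus, mimicking what automated
segmentation of 3d electron microscopy yields after skeletonization. The
knobs are the FOD model (Watson, the exponential-decay family, or a delta),
one transverse sinusoid per axon for undulation (random phase and azimuth),
a sinusoidal area modulation for beading — chosen because it admits the
closed form `Λ∥ = 1/√(1−a²)` used as an oracle — a Gaussian diameter
distribution, and a g-ratio (default 0.7) for the myelin annulus. Axons are
generated 24 μm long by default and clipped to a 20 μm box so that the 10 μm
length filter used by the morphometry keeps the large majority of them.

Real tissue differs in ways the generator deliberately ignores: axons
exchange caliber irregularly rather than sinusoidally, populations contain
unmyelinated axons and glia, axons physically exclude one another (the
generator allows overlap, so the nominal `f` is a sum of per-axon volumes),
and injury produces focal rather than stationary beading. Passing tests
therefore demonstrate the *computational* correctness of the pipeline and the
internal consistency of the model chain, not biological fidelity of any
particular parameter value.

Default study conditions: Watson κ = 16 (≈ 15° dispersion), undulation
amplitude 0.3 μm at 8 μm wavelength, beading amplitude 0.2 at 6 μm
wavelength, inner diameter 0.8 ± 0.15 μm. Where the source protocol fixes a
value (b-values, direction counts, δ/Δ, `D0 = Dw = 2 μm²/ms`, the ex vivo
NODDI diffusivity 0.6 μm²/ms, the 2 μm²/ms diffusivity bound, invariants to
l = 6 for parameter mapping) those values are the defaults; remaining
generator defaults are plausible rodent-white-matter scales and are not
tuned.

## Conventions and restored radicals

Several published forms of these quantities drop radicals in typesetting; the
package fixes the conventions by forcing the defining limits:

* `θ = cos⁻¹√⟨cos²θi⟩` (an aligned population must give θ = 0);
* invariant normalization `Nl = √(4π(2l+1))`, so that `pl = |⟨Pl(cosθ)⟩| ≤ 1`
  for axially symmetric FODs and a delta FOD has `pl = 1` (`Pl(1) = 1`);
* diffusion length `L = √(2Dt)`, Gaussian smoothing σ = L/2 ≈ 3.39 μm at
  t = Δ = 11.5 ms, D = 2 μm²/ms;
* equivalent diameter `2r = 2√(A/π)`.

The SH basis is real, orthonormal in dΩ, Condon–Shortley phase, even degrees
only (antipodal symmetry), coefficients ordered l ascending and m from −l to
l; `p00 = √(4π)` so the isotropic term of any synthesis is 1. The kernel
projections use `Kl = ∫₀¹ K(x) Pl(x) dx`; with these choices `sl = pl·Kl`
holds exactly on noiseless band-limited data, which the test suite checks to
10⁻⁴ — that identity, not any external convention table, is the correctness
gate. `Kl` can be negative (the stick kernel decreases with x²), so
identities involving the non-negative `sl` use `|Kl|`.

## The exponential-decay FOD family

The family with invariants exactly `pl = C λ^l` has the closed form

    P(t) = (1 − C) + (C/2)(1 − λ²)[(1 − 2λt + λ²)^(−3/2) + (1 + 2λt + λ²)^(−3/2)],

the potential on the unit sphere of two point sources at ±λ n̂0. The
implementation is gated on the convention-free quadrature identity
`⟨Pl⟩ = C λ^l` (10⁻⁶ over a (C, λ) grid, l ≤ 16). Because `C` enters
linearly, non-negativity reduces to `C ≤ 1/(1 − min_t g(t))` with `g` the
two-source kernel; the minimum sits at the equator, giving the analytic
boundary used as a cross-check of the numerical domain scan. The Watson and
Poisson-kernel FODs serve as references: at matched `p2` their higher
invariants deviate from any `C λ^l` law by well over 5% (κ = 4), which is the
property that discriminates the family from them.

## Numerical choices

* **Sphere discretization**: subdivided icosahedron; level 4 (5120 face bins)
  for histograms, exact per-face solid angles, antipodal symmetrization by
  averaging opposite bins. Face-centroid quadrature leaves ~10⁻⁴-level ripple
  in SH projections at l ≤ 8; oracle tests that need better use level 5 or 1d
  Gauss–Legendre quadrature (order 96–256) for axially symmetric densities.
* **Skeleton smoothing**: Gaussian kernel along arc length with reflecting
  (point-symmetric) boundary extension, which leaves straight centerlines
  exactly invariant; 1 μm is trimmed from each end first; axons shorter than
  2 μm after trimming are rejected with a message.
* **Main directions**: per axon, the length-weighted mean tangent; per
  population, the leading eigenvector of the length-weighted tangent
  outer-product sum. Tangent averages are length-weighted throughout so
  results are invariant to resampling of the centerline step.
* **FOD histogram weighting**: tangents are weighted by segment length
  (a flag disables it); whether counts or lengths are intended in the
  source method is ambiguous, and length-weighting is the
  discretization-invariant choice.
* **Estimator optimizations**: NODDI and SMT are Gaussian maximum-likelihood
  fits (`nlminb`) with multi-start grids (NODDI over κ ∈ {0.5, 2, 8, 32});
  NODDI fits the per-shell rotational invariants rather than raw directional
  signals — equivalent information for a single Watson bundle and no bundle
  direction to estimate. Watson invariants are spline-interpolated over
  log κ inside the objective (tabulated from 256-point quadrature).
* **WMTI**: kurtosis maximum located on a 256-direction set and refined by
  Nelder–Mead; the intra/extra tensors are the quadratic forms fitted to the
  per-direction branch formulas, intra on the minus branch so `Da ≤ De∥`.
  On noiseless dispersed data the perpendicular kurtosis equals the maximum,
  so the intra-axonal perpendicular eigenvalues vanish and WMTI saturates at
  `p2 = 1`; this is a property of the closed-form estimator itself, visible
  here because the synthetic data are noiseless.
* **SMI**: the training prior is uniform `f ∈ [0.05, 0.95]`,
  `Da, De∥ ∈ [0.5, 2]`, `De⊥ ∈ [0.05, 1.5]` μm²/ms, `fw = 0`, FOD invariants
  `pl = λ^l` with `λ ∈ [0, 0.95]`; 5·10⁴ draws; features are the 12 per-shell
  invariants (l ≤ 6), standardized, expanded to all monomials of total degree
  ≤ 3 (455 terms), solved by one ridge-stabilized least squares for all
  targets. Noise, when requested, is propagated onto the invariants in the
  fiber frame with per-coefficient standard deviation `σ√(4π/N_dir)`. The
  published estimator's exact prior and regression details are not public;
  these are this package's own documented stand-ins.
* **FOD recovery from a kernel**: `plm = Σb Kl slm / (Σb Kl² + ε²)` with
  ε = 10⁻⁴, omitting degrees whose `|Kl|` is negligible on every shell.
* **Statistics**: Pearson p-values from the t distribution with N−2 degrees
  of freedom, confidence intervals from the Fisher transform with variance
  1/(N−3) (both per the standard `corrcoef` conventions); BH-FDR is the
  step-up rule written out (and cross-checked against `p.adjust` in tests);
  Lin's concordance uses population (1/N) moments, Pearson sample moments.
  Permutation p-values and the 0.05 threshold on both p and q are available
  for the robustness variants.

## Problem sizes

Routine runs use a few hundred axons per population, icosphere level 3–4,
SMI training at 1–5·10⁴ draws, and a handful of samples per pipeline run;
these sizes give Monte-Carlo error comfortably inside every stated tolerance
while keeping a full suite run in minutes on one core. The demo pipeline
(`run_pipeline()`) chains 6–8 samples across a severity gradient (axon loss,
beading, dispersion increase — the injury phenotype) and feeds the paired
tables to `specificity_report()`.

## Known limitations

* Axon overlap is not excluded, so `f` is nominal; at the default densities
  the error is small but `f` close to 1 is unphysical.
* The severity gradient in the demo pipeline varies several properties
  together, so off-diagonal correlations in its report are genuine
  collinearity, not estimator failures; independent-variation designs (as in
  the specificity tests) are needed to probe specificity proper.
* WMTI's `p2` saturates at 1 on noiseless synthetic data (see above), so its
  dispersion column degenerates in the demo pipeline report.
* Rician likelihoods are not implemented; fits assume Gaussian residuals
  (appropriate for complex-denoised data). Time-dependent diffusion,
  exchange, and non-PGSE encodings are out of scope.
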