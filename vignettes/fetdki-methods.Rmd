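---
title: "Methods: combined FET PET and diffusion kurtosis analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined FET PET and diffusion kurtosis analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetdki)
```

## The problem and the pipeline

After resection and chemoradiation, a growing contrast-enhancing lesion in a
glioblastoma patient may be true tumor progression (TPR) or a
treatment-related change (TRC, e.g. pseudoprogression or radiation
necrosis). The two demand opposite management, and structural MRI alone
separates them poorly. `fetdki` implements a combined-modality pipeline:
amino-acid PET with O-(2-[18F]-fluoroethyl)-L-tyrosine (FET) identifies
metabolically active tissue, and diffusion kurtosis imaging (DKI) probes the
microstructure of exactly that tissue. The stages are:

1. **DKI fitting** — estimate the diffusion tensor $D$ and kurtosis tensor
   $W$ per voxel from multi-shell diffusion MRI (b = 0, 1000, 2500 s/mm²,
   30 directions), after Rician noise-bias correction, and derive the six
   metric maps MD/RD/AD (μm²/ms) and MK/RK/AK (unitless).
2. **PET analytics** — from the dynamic FET study (16 frames over 50 min):
   the 20–40 min summed image, tumor-to-brain ratios (TBRmean by 2D
   auto-contour at TBR ≥ 1.6, TBRmax from a 1.6 cm circular ROI at the
   uptake maximum), and the lesion time–activity curve (TAC) with its
   time-to-peak (TTP) and 20–50 min slope (SUV/h).
3. **PET-guided ROI** — the lesion is the 26-connected component of
   {TBR ≥ 1.6} containing a seed, segmented on the PET summed image.
4. **Histogram features** — within that 3D ROI, each metric map is
   truncated to a plausible range, histogrammed, and summarized by its mean
   and centiles, giving 18 DT/KT variables per patient.
5. **Statistics and classification** — Mann–Whitney group comparison with
   Bonferroni control, ROC analysis with Youden-optimal cutoffs, DeLong AUC
   comparison, logistic biomarker combination, and the composite
   **FET–DKI index** $= 4.7\,\mathrm{TBR}_{max} + 39.2\,\mathrm{MK\,C90}$,
   calling TPR when the index exceeds 41.

Because no patient images are distributed, the package ships two synthetic
generators — image-level digital phantoms and a feature-level cohort
simulator — that make every stage testable end to end.

## The kurtosis signal model

For a unit gradient direction $n$ and b-value $b$ (internally in ms/μm², so
that $b = 1000\,$s/mm² becomes 1.0 and diffusivities come out in μm²/ms):

$$\ln S(b, n) = \ln S_0 - b\, n^\top D\, n +
  \frac{b^2}{6}\, \mathrm{MD}^2 \sum_{ijkl} n_i n_j n_k n_l W_{ijkl}.$$

The model is linearized with the standard reparameterization $V =
\mathrm{MD}^2 W$, making the 22-parameter vector $(\ln S_0, D_{6}, V_{15})$
linear in the log-signal; the two-shell, 30-direction protocol gives a
design matrix of full rank 22. Fitting proceeds in two stages:

* **WLS initialization** on the log signal with weights $S^2$ (the usual
  variance-stabilizing choice). When the noise level $\sigma$ is known, the
  log signal receives the second-order delta-method debiasing term
  $+\sigma^2/(2S^2)$ for measurements with local SNR ≥ 3 (below that the
  expansion is invalid and the term is dropped). This removes the log-noise
  asymmetry bias of the linear estimator, which otherwise depresses MK by
  ~0.02 at b0-SNR 50 with this protocol.
* **NLLS refinement** (`method = "nlls"`, the default) by
  Levenberg–Marquardt on the exponentiated model with an analytic Jacobian,
  relative tolerance 1e-8, at most 100 iterations.

Constraints are applied as a post-hoc projection rather than constrained
optimization: $D$ is projected to the positive-semidefinite cone by
eigenvalue clipping at zero, and the directional (apparent) kurtosis is
clipped to [0, 3] when metrics are computed — simple, reproducible, and
consistent with the downstream histogram truncation.

### Estimator behavior at low shell SNR

At b = 2500 s/mm² a lesion with MD ≈ 1.3 μm²/ms retains only ~11% of its
b0 signal, so a b0-SNR of 25 means shell SNR near 3. We characterized both
estimators there with seeded simulations: the bias-corrected WLS is nearly
unbiased for MK (~1–3% lesion-median bias at b0-SNR 25), whereas the
magnitude-domain NLLS refinement acquires a ≈ −9% MK bias (square-root
concavity of the corrected amplitudes plus selection among near-floor
measurements). At moderate-to-high SNR the NLLS is unbiased and has the
lower variance. NLLS stays the volume default; the bias-sensitive property
tests (bias-correction improvement, Gaussian limit, SNR-25 recovery) assert
on the WLS path, where the Rician mechanism acts cleanly.

### Rician handling

Background noise σ is estimated by the maximum-likelihood Rayleigh fit to
signal-free magnitude voxels, $\hat\sigma = \sqrt{\overline{M^2}/2}$. The
power-images correction replaces each magnitude by
$\sqrt{\max(M^2 - 2\sigma^2, 0)}$ — unbiased in the squared domain because
$\mathbb{E}[M^2] = A^2 + 2\sigma^2$ exactly. Measurements floored to zero
are dropped from that voxel's fit; a voxel is excluded outright only when
more than 25% of its measurements floor. (Whole-voxel exclusion at the
first floored measurement would discard ~80% of lesion voxels at b0-SNR 25
and bias the survivors upward.)

### Kurtosis metrics by spherical quadrature

The apparent kurtosis $K(n) = \mathrm{MD}^2\, W(n) / (n^\top D n)^2$ is a
smooth rational function on the sphere. MK is its spherical mean, evaluated
on a fixed Gauss–Legendre × trapezoid product rule with 32 polar × 64
azimuthal nodes (2048 points): for these integrands the rule converges
spectrally, so the quadrature error (~1e-8 even for extreme tensors) is far
below the 1e-3 Monte-Carlo validation tolerance, and the metric is
rotation invariant to numerical precision. AK is $K$ along the principal
eigenvector of $D$; RK averages $K$ over 64 equally spaced perpendicular
directions (the trapezoid rule on a circle is spectrally accurate for the
smooth in-plane integrand). These fixed deterministic designs keep every
map bit-reproducible.

## PET conventions

* The summed image is the duration-weighted mean of frames overlapping the
  20–40 min window; partial frames contribute proportionally to overlap.
* TBR quantities divide by the mean SUV of a user-supplied healthy-brain
  reference mask (the phantom generates a contralateral one). All TBR
  quantities, masks and TTP are invariant to global intensity rescaling;
  the TAC slope scales linearly. SUV computation from dose and weight is
  out of scope — inputs are assumed already in SUV.
* **TBRmax**: the source convention is ambiguous about whether the 1.6 cm
  circle contributes its mean or its maximum; the circle mean is the
  default (under the max reading the circle would have no effect), with
  `stat = "max"` exposed. When the uptake maximum is a plateau, the circle
  anchors on the voxel nearest the plateau centroid (deterministic).
* Sphere and circle membership is by voxel-center inclusion (a 1.6 cm
  sphere on a 2 mm grid contains 257 voxel centers, ~2.06 ml);
  3D connectivity is 26-neighbor, 2D auto-contour connectivity 8-neighbor,
  and the auto-contour lives in the single axial slice containing the
  global TBR maximum.
* TTP is the mid-time of the first frame attaining the TAC maximum (ties
  to the earliest frame); the late slope is the OLS slope of SUV against
  frame mid-times in 20–50 min, ×60 to give SUV/h.

## Histogram analysis

Voxel values outside 0.5–3.5 μm²/ms (diffusivity maps) or 0.4–1.2
(kurtosis maps) are discarded (closed intervals, counts reported).
Relative-frequency histograms are normalized by the in-range voxel count,
so they sum to 1 for any ROI volume, and smoothed with a centered moving
average spanning 0.14 μm²/ms (DT) or 0.04 (KT). Only the smoothing windows
are prescribed by the protocol; the bin width is chosen as window/7 so the
average spans exactly 7 bins, and is exposed in `histogram_spec()`.

Means and centiles (C5/C10 for diffusivities, C90/C95 for kurtoses — 18
variables in all) are computed on the **raw truncated voxel values** with
the type-7 linear-interpolation quantile convention, not on the smoothed
histogram: smoothed-histogram quantiles depend on the bin width, voxel
quantiles do not. The smoothed histogram is retained for display
(`autoplot()`). Normalization to contralateral white matter is deliberately
omitted.

## Statistics

* **Mann–Whitney U** uses midrank ties; for $n_1+n_2 \le 12$ the two-sided
  p comes from exact enumeration of all group assignments (valid under
  ties), otherwise from the normal approximation with tie and continuity
  correction via `stats::wilcox.test`.
* **Bonferroni families**: α/18 for the DT/KT histogram variables and α/4
  for the PET parameters; p-values between the corrected threshold and α
  are reported as "significant prior to correction".
* **ROC**: empirical AUC with ties counted ½ (verified against the
  $U/(n_1 n_2)$ identity and a brute-force pairwise oracle). The optimal
  cutoff maximizes Youden's J over ">" criteria, ties resolved toward
  higher specificity. The AUC-vs-0.5 p-value uses the DeLong variance; the
  95% CI uses exact (Clopper–Pearson) binomial bounds on the placement
  proportion. Markers oriented the wrong way (diffusivities, lower in TPR)
  are auto-flipped and the orientation reported.
* **DeLong comparison** of paired markers via placement-value covariances;
  cross-checked against pROC in the test suite.
* **Logistic models** are IRLS fits (`glm`, tolerance 1e-8, ≤100
  iterations); complete/quasi-separation is detected and flagged, never
  silently reported; accuracy is evaluated at predicted probability 0.5.
* **FET–DKI index**: $4.7 \cdot \mathrm{TBR}_{max} + 39.2 \cdot
  \mathrm{MK\,C90}$, strictly greater than 41 calls TPR. The source text
  swaps the coefficient–variable pairing in one sentence; the equation's
  assignment is implemented, as only it is consistent with the published
  cutoff at the feature scales involved (the group-median worked examples
  give 46.1 for TPR and 35.7 for TRC).

## Synthetic data

### Image-level phantoms

Each virtual patient is an ellipsoidal "brain" of white matter inside a
48×48×32 grid of 2 mm voxels (air outside provides the background for σ
estimation), with a spherical lesion (default radius 8 mm). White matter
has tensor eigenvalues (1.7, 0.4, 0.4) μm²/ms along the x-axis and an
isotropic kurtosis tensor scaled so its spherical-mean kurtosis equals the
configured target (0.9); the lesion is isotropic with MD and MK drawn from
the group-calibrated marginal distributions (clamped to the model-valid
range). DWI noise is Rician (magnitude of complex Gaussian), default
σ = S0/25; PET noise is Gaussian per frame (σ = 0.02 SUV).

The PET lesion follows a TAC built so that three contracts hold exactly in
the noiseless case: the duration-weighted 20–40 min mean equals
TBR·background; the OLS slope over the late-phase mid-times equals the
target slope; and the maximum falls on the frame whose mid-time equals the
target TTP. For the calibrated group medians (e.g. TTP 27.5 min with a
positive late slope) no monotone late phase can satisfy all three, so the
peak is imposed as a perturbation of the late-phase line orthogonal to the
intercept, slope, and 20–40 min-mean functionals. A mild center-bright
radial profile (±5%, mean 1 over the lesion) anchors the uptake maximum at
the lesion center, as in real lesions, without moving the TBR calibration.

### Feature-level cohorts

Each of the 22 features gets a marginal distribution matched exactly to a
target median and quartile pair — a shifted log-normal in the direction of
the quartile skew (reflected for left skew), a normal family when the
quartiles are symmetric or degenerate, and always a normal family for the
TAC slope (which may be negative). Printed quartile pairs arriving in
reversed order are sanitized by sorting. Features couple through a Gaussian
copula. Within one metric's {mean, C-low, C-high} triplet the default
correlation is 0.98: these are summaries of the same voxel histogram and
hence near-comonotone — anything much weaker makes per-patient centile
ordering violations common, and the sort-based repair then visibly biases
the medians of adjacent centiles. Between metrics of the same tensor family
the default is 0.4, and 0.3 between MK C90 and TBRmax; patient-level
correlations are not published, so these are package choices, fully exposed
in `default_correlation_spec()`. Per patient, the rare residual ordering
violations are repaired by sorting the triplet.

### What the generators do and do not emulate

They reproduce: the acquisition geometry, the noise families, per-feature
group medians and IQRs (to < 1% at n = 10 000/group), per-patient centile
ordering, and the direction of every published group effect (kurtosis
features higher in TPR, diffusivities lower, TBRmax higher). They do not
reproduce: anatomically realistic brains, intralesional heterogeneity
beyond a hard sphere, motion/eddy artifacts, or — importantly — the joint
distribution of MK C90 and TBRmax beyond one correlation coefficient. A
consequence the test suite documents honestly: on large simulated cohorts
the in-sample logistic combination of MK C90 and TBRmax tracks, but does
not strictly dominate, the best single marker, whereas in the real cohort
the combination was decisively better. Quartile-calibrated marginals plus
a flat copula cannot encode the cross-modality complementarity that drives
that result, so passing or failing that one check says more about the
generator than about the statistics stage; it is left asserted (and red)
rather than weakened.

## Problem sizes and numerical choices

The test suite runs phantoms on 20×20×14 grids with 5 mm lesions
(56 lesion voxels), volume fits restricted to the lesion or ROI, cohort
calibration at 10 000 patients/group, Monte-Carlo kurtosis oracles at 10⁶
directions, and 50 seeded replicates for the family-wise-error study —
sizes chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo error far below every asserted tolerance. All
randomness flows from explicit seeds; equal seed and configuration gives
bit-identical volumes, tables and pipeline artifacts. Degenerate inputs are
defined rather than accidental: pure-S0 voxels are flagged (MD ~ 0 makes W
unidentifiable), empty masks yield empty maps with a warning, all-zero
backgrounds are an error, and exact index ties resolve to the earliest
frame / higher specificity / nearest-centroid rules stated above.

## Known limitations

* Eddy/motion correction, gradient reorientation and co-registration are
  out of scope; inputs are contractually on a common grid.
* The NLLS estimator's negative MK bias at shell SNR ≲ 3 is inherent to
  magnitude-domain fitting after square-root bias correction; use
  `method = "wls"` when the high shell is that noisy.
* The cohort simulator's copula is a placeholder where the literature is
  silent (see above); conclusions about multivariate model ranking on
  simulated cohorts should not be read as claims about patients.
* Exact numerical equality with the closed-source tools commonly used for
  these processing steps (ExploreDTI, PMOD, MedCalc) is not claimed; their
  constraint and weighting internals are unpublished.
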