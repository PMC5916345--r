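---
title: "Methods: reference-tissue kinetics and synthetic validation for striatal dopamine PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-tissue kinetics and synthetic validation for striatal dopamine PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatakit)
```

This vignette documents the models implemented in `striatakit`, the numerical
choices behind them, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The measurement model

Dynamic PET yields a time-activity curve (TAC) per region or voxel: the
activity concentration averaged over each acquisition frame. Two protocols
are built in: a 90-min, 25-frame schedule (5×1, 3×2, 3×3, 14×5 min) for the
irreversibly trapped synthesis tracer, and a 60-min, 19-frame schedule
(5×1, 3×2, 3×3, 8×5 min) for the reversible D2/3 ligand. Frame values are
treated as frame-duration averages of the underlying continuous
concentration, not midpoint samples; midpoints serve only as fit abscissae.

Neither analysis uses arterial blood. Both are *reference-tissue* methods:
a region with negligible specific binding (posterior cerebellar gray;
occipital cortex as the configurable alternative) serves as input. The
synthetic plasma input (`plasma_input()`) therefore only has to produce
realistic reference TACs; it is a tri-exponential bolus (Feng-type) with
conventional default parameters, and the reference region is a one-tissue
compartment with defaults $K_1' = 0.1$ mL/min/g, $k_2' = 0.1$ min⁻¹ —
plausible cerebellar values. No downstream estimate depends on these
choices, because every estimator is scale-invariant and conditions only on
the reference TAC itself.

## Patlak graphical analysis

For an irreversibly trapped tracer, the transformed coordinates
$y = C_t/C_r$ and $x = (\int_0^t C_r)/C_r$ become linear after a
pseudo-equilibrium time $t^*$; ordinary least squares over frames with
midpoint $\ge t^*$ (default 25 min, i.e. the 25–90 min window) yields the
net influx rate $K_i$ (slope, scaled to the reference distribution volume)
and an intercept related to the distribution volume ratio. The running
integral is a trapezoid over frame midpoints with the origin $(0,0)$
prepended.

The generator's `graphical_exact` mode builds tissue TACs from the *same*
discrete quadrature: $C_t = K_i X + V C_r$ with $X$ the fitter's own
abscissa integral. Such curves are Patlak-linear to machine precision, so
slope recovery is exact for any $t^*$ — this separates quadrature error
from model error in tests. The `compartmental` mode instead integrates the
two-tissue irreversible system driven by the reference curve and is only
asymptotically linear; its late-window slope approaches $K_1k_3/(k_2+k_3)$
and is checked against an independent ODE solution.

## Basis-function SRTM

The simplified reference tissue model's operational equation is

$$C_t(t) = R_1 C_r(t) + (k_2 - R_1 k_{2a})\, C_r \otimes e^{-k_{2a} t},
\qquad k_{2a} = \frac{k_2}{1 + BP_{ND}}.$$

The basis-function fit scans a grid of $\theta_3 = k_{2a}$ values, solving a
two-parameter weighted linear problem per basis and keeping the RSS
minimiser. Defaults, with rationale:

* **Grid**: 128 log-spaced values in $[0.006, 0.6]$ min⁻¹, bounds chosen to
  bracket plausible apparent efflux rates for reversible D2/3 ligands.
* **Refinement**: after the grid search, a bounded golden-section search
  between the winning node's neighbours refines $\theta_3$ continuously
  (`refine = TRUE` by default). The grid alone has ~3.7% spacing, which
  floors the attainable $BP_{ND}$ accuracy for off-grid truth; refinement
  removes that floor at the cost of a few extra basis evaluations.
  `refine = FALSE` gives the pure grid estimator, which is what the
  exhaustive brute-force oracle test compares.
* **Weights**: uniform by default; `"frame_duration"` weighting available.
* **Ties**: exact RSS ties resolve to the smallest $\theta_3$ — the
  smoother solution, chosen so that larger $BP_{ND}$ is never privileged by
  a tie-break.

$BP_{ND} = k_2/\theta_3 - 1$ is reported together with $R_1$ and $k_2$;
in receptor terms $BP_{ND} = f_{ND} B_{avail}/K_D$ (`bpnd_from_receptors()`,
with the D2/3 antagonist's $K_D \approx 1.2$ nM as the default).

## One continuous representation everywhere

All continuous-time operations live on a 0.1-min internal grid. Convolution
with $e^{-\theta t}$ uses an exact exponential integrator for
piecewise-linear signals, so discretisation error reduces entirely to the
piecewise-linear representation of the input. A frame-level TAC is made
continuous by a piecewise-linear curve with nodes at frame *boundaries*,
starting at $(0,0)$, with node values solved so that the frame-duration
average over each frame reproduces the frame datum exactly.

This choice has two consequences worth stating. First, forward simulation
(`simulate_srtm_tac()`) and fitting (`srtm_fit()`) share the representation,
so the fit's model space contains simulated truth exactly and noiseless
recovery is limited only by the optimiser — the package's recovery tests
would otherwise conflate representation mismatch with estimator bias.
Second, the boundary-node recursion can overshoot on sharply varying early
frames (the node solve has an alternating character); for the smooth
reference curves used here the effect is negligible, but the reconstruction
is a modelling convention, not a claim about the true intra-frame shape.
The reference simulator itself integrates the analytic plasma model on a
finer 0.01-min grid, since the bolus peak is sharp; it is verified against
stiff ODE integration to well under 0.1% per frame.

## Noise and the release statistic

Observed TACs receive zero-mean Gaussian noise with per-frame SD
$s\sqrt{\max(C,0)/\Delta t}$ — the standard frame-weighted approximation
(variance proportional to counts, inversely to frame duration). The cohort
default is $s = 0.05$, a low-noise regime: no published noise magnitude
accompanies the regional TACs this design emulates, so the scale was chosen
once such that single-subject kinetic estimates are precise to a few
percent, which is the regime in which cohort-level recovery of the printed
population values is a meaningful check. Release is computed per subject as
$100(BP_{placebo} - BP_{drug})/BP_{placebo}$ and then averaged — the mean
of per-subject ratios, which differs from the ratio of group means (9.13%
vs 8.78% at the default whole-striatum population values).

## The cohort generator

`simulate_cohort()` draws per-subject truth and forward-simulates every TAC:

* Per ROI (whole striatum, dorsal caudate, dorsal putamen, ventral
  striatum), the triple (Ki, baseline $BP_{ND}$, release fraction) is drawn
  from a correlated trivariate normal with the package's default
  population table (whole striatum: $0.015 \pm 0.002$ min⁻¹,
  $2.19 \pm 0.18$, $8.78 \pm 4.23\%$) and a default Ki–$BP_{ND}$
  correlation of 0.46, release uncorrelated with either.
* The release fraction is truncated to $[0, 0.9)$ by redrawing the whole
  triple, which keeps post-drug $BP_{ND} = BP_{placebo}(1-f)$ positive;
  truncation shifts the realised mean release slightly above the nominal
  normal mean (by about 0.2 percentage points at the default parameters),
  and the generator's moment tests check against the analytic
  truncated-normal mean.
* Body weight follows the fixed-dose context: 30 mg oral dose at
  $0.46 \pm 0.08$ mg/kg, so weight $= 30/(\text{mg/kg})$.
* Draws are independent across ROIs. The whole-striatum row is simulated
  directly as its own ROI rather than as a volume-weighted composite of the
  subregions: the package's population table carries a printed
  whole-striatum row, and simulating it directly is the only way to
  calibrate the generator to it exactly. (With voxel data, a
  whole-striatum mask would instead come from `intersect_masks()` over
  group t-maps.)
* All randomness happens inside one seeded RNG scope, so a fixed spec is
  bit-reproducible.

What the generator does *not* emulate: radioactive decay, attenuation and
scatter, scanner geometry and reconstruction, head motion, inter-subject
anatomical variability and spatial normalisation, metabolite kinetics, and
drug pharmacokinetics (the post-drug scan differs from placebo only through
the reduced true $BP_{ND}$). Passing recovery tests therefore demonstrate
estimator correctness under the stated statistical model, not robustness to
those physical confounds.

## Imaging operations

* **Smoothing** (`smooth_map()`): separable Gaussian with per-axis
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ in mm. The 1-D kernel weights
  are *bin-integrated* Gaussian masses rather than point samples, so
  blurring a voxelized piecewise-constant image reproduces the continuous
  Gaussian blur at voxel centers exactly — phantom tests then have
  closed-form erf oracles. Missing voxels are excluded by renormalisation
  (smoothed indicator in the denominator), which also handles the volume
  boundary; `NA` voxels stay `NA`.
* **Missing-value sentinel** is `NA` throughout, excluded from ROI means,
  smoothing normalisation and t-maps.
* **Group t-maps**: one-sample against zero or paired, $df = n-1$;
  zero-variance voxels become `NA`. The paired map is by construction
  identical to the one-sample map of difference images.
* **Cluster thresholding**: two-tailed cluster-forming p by default (the
  sidedness of the emulated group tests is not fixed by convention;
  one-tailed is available), connectivity defaults to 6 (face adjacency,
  the most conservative of 6/18/26, all supported). Peak ties resolve to
  the lowest linear index.
* **Extent calibration** (`cluster_extent_mc()`): smoothed Gaussian
  white-noise volumes, standardised within the search mask, thresholded,
  maximum component size recorded per iteration; returns the smallest $k$
  with $P(\max \ge k) \le \alpha$. The conventional $k = 55$ default in
  `cluster_config()` is a configuration value, not a claim that this null
  reproduces any particular scanner's calibration.
* **Posterior cerebellum rule**: among coronal slices containing the
  cerebellum label, the most anterior `round(fraction × n)` slices are
  cleared (round-half-up, so exactly one quarter when the count is
  divisible by 4), limiting spill-in from midbrain dopaminergic nuclei.

## GTM partial volume correction

`gtm_matrix()` computes $\omega_{ij}$, the mean over region $i$'s voxels of
the PSF-smoothed indicator of region $j$; `gtm_correct()` solves
$\omega\,c = o$. The background (label 0) is always included as an explicit
region so each row is a partition of observed signal and sums to 1 —
leaving background unmodeled would bias every corrected mean. The PSF is
isotropic Gaussian, default FWHM 4 mm (matching typical reconstruction
smoothing; configurable, as the effective scanner PSF is usually unknown).
The correction is rejected when the matrix condition number exceeds 1e8.
On piecewise-constant phantoms, correction after forward blurring recovers
the truth to solver precision.

## Statistics layer

* **Correlations**: point estimates from the standard product-moment or
  rank formulas, p-values from the t transform with $df = n-2$, CIs from
  1000 seeded paired bootstrap resamples, percentile by default (BCa by
  option). Degenerate resamples (zero variance) are dropped from the CI.
* **Partial correlation**: residual-based (each variable regressed on the
  covariates with intercept), p with $df = n - 2 - k$ — the standard
  residual-df convention.
* **Normality gating**: Shapiro–Wilk at $\alpha = 0.05$ decides
  Pearson vs Spearman per pair; the body-weight-corrected release
  correlation uses the same gate on the partial method.
* **Paired tests** report Cohen's $d_z = \bar d/s_d = t/\sqrt{n}$; the
  identity `dz_from_t()` recovers effect sizes from printed t values.
  (Printed tables that pair $t = 0.27$, $n = 40$ with $d_z = 0.00$ are
  inconsistent with this identity, which gives 0.04; the package treats the
  identity as definitional.)
* **Power**: Fisher-z approximation,
  $\Phi(|\operatorname{atanh}\rho|\sqrt{n-3} - z_{crit})$ plus the opposite
  tail. This is not the exact bivariate-normal routine of dedicated power
  software; at $n = 40$, two-tailed $\alpha = 0.05$, power 0.80 corresponds
  to $\rho \approx 0.43$ under this formula (a commonly quoted
  $\rho = 0.32$ for the same design is not reproducible under it — the
  approximation is documented rather than tuned).
* **ICC**: the inter-rater variant is ICC(2,1) — two-way random effects,
  absolute agreement, single measure — computed from the ANOVA mean
  squares; absolute agreement is the right notion for comparing raters'
  region values on a common scale.
* **Missing data**: strictly refused by every operation; callers drop
  subjects listwise first.

## Pipeline

`run_study()` chains the stages (simulate → fit → reports) with a
stage-labeled failure diagnostic, a master seed propagated to every
bootstrap, and per-ROI reports: mean ± SD of the four measures; three
correlations per ROI (Ki vs baseline $BP_{ND}$; baseline vs post-drug
$BP_{ND}$; Ki vs release, weight-corrected) with Bonferroni flags using a
three-comparison family for the subregions and no correction for the
primary whole-striatum row; and per-ROI regressions of post-drug $BP_{ND}$
on Ki, baseline $BP_{ND}$ and region volume (volume omitted for the
whole-striatum ROI, which is a fixed group-level mask). The interface is
the exported functions plus this vignette and `scripts/acceptance.R`; no
shell CLI is shipped, as the natural entry points for R users are
`study_config()`/`run_study()` themselves.

`sanity_check_reference()` mirrors the reference-stability control:
quantify the cerebellar region as a *target* against the occipital
alternative reference on both challenge scans and test scan-1 vs scan-2
$BP_{ND}$ with a paired t; a significant change would invalidate the
cerebellar reference. On noiseless cohorts with no injected change the
degenerate all-zero difference is reported as $t = 0$ rather than 0/0.

## Problem sizes and test design

The test suite runs entirely on synthetic data built at test time: cohort
moment checks use $10^4$ truth-only draws; end-to-end recovery uses
40-subject cohorts (20 replicate cohorts for release recovery, 50 for
correlation recovery); Monte-Carlo extent calibration uses 120 iterations
on small masks; the type-I-error check uses 2000 null replicates at
$n = 40$. These sizes make the standard errors of the checked quantities
comfortably smaller than the asserted tolerances. Oracles are independent
of the code paths they check: stiff ODE integration (deSolve) for the
simulators, an $O(n^2)$ direct-quadrature brute-force scan for the SRTM
minimiser, closed-form erf expressions for Gaussian blurring and the GTM,
normal-equation and ANOVA algebra for regression and ICC, and a
from-scratch re-simulation for the cluster-extent null.

## Known limitations

* No decay, scatter, attenuation, motion or registration modelling; all
  volumes must share a grid (no affine resampling).
* The Patlak scaling convention is the reference-input slope; absolute
  $K_i$ against an arterial input is out of scope.
* SRTM assumes a valid reference (no specific binding, shared
  non-displaceable volume); violations bias $BP_{ND}$ in ways the
  generator does not emulate.
* The GTM assumes within-region homogeneity; voxelwise PVC methods are not
  implemented.
* Bootstrap CIs are percentile by default and can undercover near
  $|r| \to 1$.
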