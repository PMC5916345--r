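# striatakit

Reference-tissue kinetic modelling and cohort statistics for multi-tracer
striatal dopamine PET, with a synthetic data generator that makes every stage
of the analysis verifiable by parameter recovery — no scan data required.

## The problem

Three complementary PET measurements characterise striatal dopamine function
within a person:

* **Dopamine synthesis capacity** — an irreversibly trapped tracer (a
  substrate of aromatic amino acid decarboxylase, 90-min dynamic scan) is
  quantified by Patlak graphical analysis with a reference-tissue input. The
  tissue and reference time-activity curves (TACs) are transformed to

  y(t) = C_t(t)/C_r(t),   x(t) = ∫₀ᵗ C_r dτ / C_r(t),

  which becomes linear once trapping dominates (t ≥ t\*, default 25 min);
  the slope is the net influx rate **Ki** (1/min), scaled to the reference
  distribution volume. In compartmental terms Ki = k₂k₃/(k₂+k₃).

* **D2/3 receptor availability** — a reversible antagonist (60-min dynamic
  scan) is quantified by the basis-function simplified reference tissue
  model (SRTM). For each candidate apparent efflux rate θ₃ = k₂ₐ the basis
  B(t) = C_r ⊗ e^(−θ₃t) is built and C_t ≈ θ₁C_r + θ₂B is solved by
  weighted linear least squares; the best θ₃ gives R₁ = θ₁,
  k₂ = θ₂ + θ₁θ₃, and the non-displaceable binding potential
  **BP_ND = k₂/θ₃ − 1 = f_ND·B_avail/K_D**.

* **Dopamine release** — a drug challenge (oral methylphenidate blocking
  the dopamine transporter) raises synaptic dopamine, which competes with
  the radioligand; release is indexed by the percent change
  **100·(BP_placebo − BP_drug)/BP_placebo** between paired scans.

Around this kinetic core the package provides voxelwise parametric maps,
Gaussian smoothing, group t-maps with cluster-extent thresholding (including
Monte-Carlo extent calibration), reference-region construction (posterior
cerebellar mask), Dice/ICC reliability metrics, Rousset geometric-transfer-
matrix (GTM) partial volume correction, and the statistics layer used in
cohort studies of these measures: Pearson/Spearman correlations with
1000-sample bootstrap CIs, Shapiro-Wilk gating, body-weight partial
correlation, paired t-tests with Cohen's dz, multiple regression, Bonferroni
flags, and correlation power.

Because real multi-tracer cohorts are rarely shareable, the
`synthetic` layer simulates the whole study: frame schedules, a
tri-exponential bolus input, one-tissue reference kinetics, irreversible and
SRTM tissue TACs, frame-weighted noise, correlated 40-subject cohorts, and
PSF-blurred labeled phantoms. Every estimator in the package is tested by
recovering the generator's known truth.

## Worked example

```r
library(striatakit)

## dopamine synthesis capacity: Patlak on a 25-frame / 90-min protocol
ref    <- simulate_reference_tac(schedule = frame_schedule("FMT"))
tissue <- simulate_irreversible_tac(ref, Ki = 0.015, V = 0.5)
patlak_fit(tissue, ref, t_star = 25)
#> Reference-tissue Patlak fit
#>   Ki        = 0.015 1/min
#>   intercept = 0.5
#>   r^2 = 1.0000 over 13 frames (t* = 25 min)

## receptor binding and release: SRTM on a 19-frame / 60-min protocol
ref_rac <- simulate_reference_tac(schedule = frame_schedule("RAC"))
placebo <- simulate_srtm_tac(ref_rac, R1 = 1, k2 = 0.3, BPnd = 2.19)
drug    <- simulate_srtm_tac(ref_rac, R1 = 1, k2 = 0.3, BPnd = 1.99)
fp <- srtm_fit(placebo, ref_rac)
fp
#> Basis-function SRTM fit
#>   R1     = 1
#>   k2     = 0.3 1/min
#>   theta3 = 0.09404 1/min
#>   BPnd   = 2.19
#>   RSS    = 0
percent_change(fp$BPnd, srtm_fit(drug, ref_rac)$BPnd)
#> [1] 9.13...
```

The fitted `Ki` and intercept equal the generating truth because a
graphical-exact TAC is Patlak-linear by construction; the SRTM fit recovers
`BPnd = 2.19` because the forward model and the basis functions share the
same continuous representation of the reference curve. The 9.13% release is
the ratio of these two group means — note it differs from the mean of
per-subject ratios, which is how cohort release is reported.

A full simulated study (cohort draw, all kinetic fits, both report tables):

```r
cfg <- study_config(cohort_spec(n_subjects = 40, seed = 1),
                    n_boot = 1000, seed = 1)
res <- run_study(cfg)
res$table1   # per-ROI mean +/- SD of Ki, BPnd placebo/drug, % release
res$table2   # per-ROI correlations with bootstrap CIs and Bonferroni flags
```

With seed 1 this prints, e.g., whole-striatum `Ki 0.0153+/-0.0019`,
`BP 2.21+/-0.17 -> 2.03+/-0.20`, `release 7.99+/-4.84 %`, and a
whole-striatum Ki-vs-baseline-BP_ND Pearson `r = +0.48 (+0.21, +0.66)` —
estimator output, scattering around the generator's population values
(Ki 0.015, BP 2.19 → 2.00 on average, release 8.78%, r 0.46).

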