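---
title: "Methods: IVIM and extended-Tofts simulation, fitting, and staging statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IVIM and extended-Tofts simulation, fitting, and staging statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimdce)
```

# What this package computes

`ivimdce` implements a complete quantitative-MRI staging analysis for
nasopharyngeal carcinoma (NPC) — or any two-group tumor cohort — as a
tested, reusable pipeline:

1. **Synthetic data**: digital phantoms, noisy diffusion-weighted (DWI)
   and dynamic contrast-enhanced (DCE) acquisitions, and multi-subject
   cohorts with controlled group differences and cross-parameter
   correlations.
2. **IVIM fitting**: voxel-wise segmented bi-exponential fitting of the
   intravoxel-incoherent-motion model, giving the true diffusion
   coefficient `D`, the perfusion fraction `f`, and the pseudodiffusion
   coefficient `D*`.
3. **DCE fitting**: variable-flip-angle T1 mapping, spoiled-gradient-echo
   signal-to-concentration conversion, and voxel-wise extended-Tofts
   pharmacokinetic fitting, giving `Ktrans`, `kep = Ktrans/ve`, `ve`, `vp`.
4. **ROI summaries**: ROI means over valid voxels, segmentation tumor
   volume, Cohen's kappa for repeat measurements.
5. **Cohort statistics**: Shapiro–Wilk, pooled Student's t-tests, ROC
   analysis with Youden cut-offs and likelihood ratios, DeLong paired AUC
   comparison, forward stepwise logistic regression, and Spearman
   correlation with Bonferroni correction.

Patient images for the reference NPC cohort are not publicly available,
so every stage is exercised end-to-end on synthetic data whose group
distributions reproduce the published subject-level summaries. The tests
establish properties of the *methods* (round-trip identities, oracle
agreement, calibration); they cannot certify performance on real
patient data.

# Signal models

## IVIM forward model

The voxel signal at diffusion weighting $b$ follows

$$S(b) = S_0\left[(1-f)\,e^{-bD} + f\,e^{-b(D+D^*)}\right],$$

with $D$ the true molecular diffusion coefficient (mm²/s), $f$ the
perfusion fraction of the microvascular compartment, and $D^*$ the
pseudodiffusion coefficient of capillary blood ($D^* \gg D$). The
default acquisition uses 13 b-values
(0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000 s/mm²) at
3 T, with three orthogonal diffusion directions averaged before fitting.

## Segmented IVIM fit

Fitting follows the classic two-stage scheme:

* **Stage 1** (`fit_high_b_mono`): ordinary least squares of
  $\ln S$ on $b$ restricted to $b > 200$ s/mm² (strictly greater, so
  b = 300, 500, 1000 with the default scheme), where the perfusion
  compartment has decayed below numerical noise; $D = -$slope.
* **Stage 2** (`fit_perfusion`): bounded Levenberg–Marquardt least
  squares over *all* b-values for $(f, D^*, S_0)$ with $D$ held fixed.
  Bounds $f \in [0,1]$, $D^* \in [D, 1.0]$ mm²/s; warm start
  $f_0 = 1 - \exp(\text{intercept})/S(0)$ clipped to $[0.01, 0.5]$ and
  $D^*_0 = 10 D$. Whether $D$ should be refined jointly in stage 2 is a
  genuinely open design choice; the classic fixed-$D$ variant is the
  default because stage 2 is conventionally described as producing only
  $(f, D^*)$, and a joint refinement is available via `refine_D = TRUE`
  (both recover the truth in the noiseless limit, which is tested).

Voxel validity is the conjunction of: b = 0 signal at least
$k\sigma$ above the background noise level (default $k = 5$; the
protocol description demands only "safely above background", so $k$ is
exposed), positive signals at the log-fit b-values, $D > 0$,
convergence, and — important in practice — *not* converging onto the
$D^*$ or $f$ upper bound. Bound convergence means the perfusion
compartment is unidentifiable in that voxel; at b = 0 SNR 50 about
0.3–3% of voxels (more at low $f$) produce runaway $D^*$ estimates that
would otherwise corrupt ROI means.

## Spoiled-gradient-echo and T1 mapping

The DCE acquisition is a 3D spoiled (fast-field) gradient echo:

$$S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$

Two flip angles are acquired (5° pre-contrast, 15° dynamic; TR 4.8 ms).
`vfa_t1` linearizes $S/\sin\alpha = E_1 \cdot S/\tan\alpha +
M_0(1-E_1)$ and solves the two-point system exactly; the slope must lie
in $(0,1)$ for a physical T1, otherwise the voxel is flagged. Note that
*equal* signals at the two angles are perfectly consistent with a T1
(about 435 ms at these settings); the genuinely impossible inputs are
signal ratios outside $(\tan 2.5°/\tan 7.5°,\ \sin 15°/\sin 5°)$.

The dynamic series is converted per time point by inverting the same
equation with the baseline-derived $M_0$ (the only self-consistent
reading of a two-flip-angle protocol — there is no angle sweep per
dynamic to refit), and concentration follows the linear relaxivity
relation

$$C_t(t) = \frac{1/T_1(t) - 1/T_{10}}{r_1},$$

with $r_1 = 3.5\ \mathrm{s^{-1} mM^{-1}}$ (Gd-DOTA at 3 T; the protocol
does not state it, so it is configurable). Because $T_{10}$ comes from
the baseline mean, baseline concentration is zero by construction. Time
points whose signal implies $E_1 \notin (0,1)$ are marked invalid; a
voxel with more than 20% invalid points is excluded.

## Extended-Tofts model

$$C_t(t) = v_p\,C_p(t) + K^{trans}\int_0^t C_p(\tau)\,
  e^{-k_{ep}(t-\tau)}\,d\tau, \qquad k_{ep} = K^{trans}/v_e.$$

`Ktrans` and `kep` are stored in 1/min (the reporting convention) and
converted to 1/s internally at the time-grid boundary. The convolution
uses trapezoidal quadrature on a uniform grid upsampled 10× (the
9.2 s dynamic interval is coarse relative to bolus dynamics); on the
upsampled grid the exponential kernel admits the exact recursion
$I_i = E\,I_{i-1} + \tfrac{h}{2}(C_{p,i} + E\,C_{p,i-1})$ with
$E = e^{-k_{ep}h}$, which the tests verify against boxcar and
mono-exponential closed forms to 0.1%.

`fit_extended_tofts` runs bounded Levenberg–Marquardt for
$(K^{trans}, v_e, v_p)$ with bounds $[0,5]$/min, $[10^{-3},1]$,
$[0,0.5]$ and deterministic start $(0.3, 0.3, 0.05)$; `kep` is always
reported as the derived ratio (the identity $k_{ep} v_e = K^{trans}$ is
tested to $10^{-6}$ relative). All-zero concentration curves are
excluded as unphysiological rather than fitted.

# The synthetic cohort

## What the generator emulates

`cohort_spec()` defaults to 29 low-stage (AJCC I+II) and 46 high-stage
(III+IV) subjects. Per-subject ROI-mean parameters are drawn from the
published group summary distributions (`npc_group_params()`): lower
`D`, `f`, `D*`, `Ktrans`, `vp` and *higher* `ve` in the high-stage
group. Stage labels within a group follow the reference cohort mix
(7:22 for I:II, 29:17 for III:IV). Each subject gets an ellipsoidal
"tumor" embedded in background tissue on an 8 × 8 × 4 grid
(~32 ROI voxels, ~342 mm³ at 1.8 × 1.8 × 3.3 mm voxels) with
log-normal within-tumor heterogeneity (CV 10%), so the voxel filters
have real work to do.

Two deliberate deviations from a literal reading of the published
summary table:

* **kep is derived, never drawn.** The model fixes
  $k_{ep} = K^{trans}/v_e$, so its group distribution cannot be set
  independently; the published kep row is internally inconsistent with
  the Ktrans and ve rows of the same table under this identity, and the
  derived values are used throughout (their group direction still
  matches, because both effects point the same way).
* **ve and vp are fractions.** The published "%" unit labels are
  incompatible with the printed magnitudes (e.g. a plasma fraction of
  0.0757 *percent* would be biologically absurd next to ve ≈ 0.6); the
  values are plainly fractions and are treated as such.

Truncation to physical ranges after the Gaussian draw uses
physiological bounds for this tissue: `f` in [0.04, 0.6] (vascularized
tumor has nonzero perfusion), `ve` in [0.2, 0.95], `vp` in
[0.002, 0.3] with `ve + vp ≤ 0.97`, `D*` at least 10 `D`. Floors near
zero would manufacture subjects with unphysiological parameter
combinations (e.g. kep of tens per minute from a near-zero `ve`) that
no patient in the reference cohort exhibits.

## Correlation induction

The analysis studies the correlation between IVIM perfusion-related
parameters (`f`, `D*`) and DCE parameters. The generator induces a
target Spearman correlation `cross_correlation` via a Gaussian copula
with *equicorrelation* among {`f`, `D*`, `Ktrans`, `ve`, `vp`} at
Pearson $r = 2\sin(\pi\rho_s/6)$, so the rank correlation is controlled
directly. A block structure with all six cross pairs at 0.5 and zero
elsewhere is not positive definite, so the single-latent-factor
equicorrelation is the feasible structure closest to the intent;
feasibility is checked and violations are reported naming the first
offending pair. `D` stays independent. Note two consequences verified
by the tests: pooling the two stage groups adds a small positive
marginal correlation on top of the within-group value (the groups'
means differ in the same directions), and correlations *with the
derived kep* are not directly controlled — the ratio of two positively
correlated quantities can correlate either way.

## Noise models

* **DWI**: Rician (magnitude of complex Gaussian noise), the standard
  model for magnitude diffusion data; `n_averages = 3` independent
  acquisitions are simulated and averaged, mirroring the
  three-direction averaging of the protocol, so the quoted
  `noise_sigma` is per acquisition and b = 0 SNR means
  $S_0/\sigma$. Background voxels show the Rayleigh floor
  $\sigma\sqrt{\pi/2}$ (tested by Monte Carlo).
* **DCE**: additive Gaussian. Enhanced spoiled-GRE signals are
  high-SNR, where the Gaussian approximation is accurate and keeps the
  signal inversion unbiased. Because the spoiled-GRE baseline signal is
  only ~3% of $M_0$, the cohort generator by default sets the DCE noise
  so the *baseline dynamic* SNR matches the DWI b = 0 SNR ("SNR-matched"),
  rather than reusing the DWI sigma verbatim, which would drown the
  dynamics.

## Arterial input function

The measured patient AIF of the reference analysis is unavailable, and
its signal-to-concentration handling (vertebral-artery signal,
hematocrit) is undescribed — this is deliberately sidestepped, not
guessed: the simulator generates a Parker-style *population* bolus
directly as plasma concentration (two Gaussians plus a
sigmoid-modulated exponential, literature coefficients, amplitude
linear in dose) shifted to arrive at the 8th dynamic, and the same
curve is used for fitting. A hematocrit parameter (0.42) exists only
for users converting their own arterial signals. The smooth analytic
form makes the convolution testable against closed forms.

The dynamic interval is not stated by the protocol beyond "65 dynamics
in about 10 minutes"; `dt = 9.2` s is the consistent default and is
configurable.

# Statistical layer choices

* **t-test**: pooled-variance Student form (that is what "Student's
  t-test" names); Welch by flag. A summary-statistic variant implements
  the identical pooled closed form, and the tests verify raw-data and
  summary-statistic paths agree to machine precision.
* **ROC cut-off**: "best diagnostic accuracy" does not pin down a
  criterion; the default is Youden's J (the standard behind published
  sensitivity/specificity pairs), with a maximum-accuracy alternative;
  ties break toward higher specificity. The sweep is exhaustive over
  midpoints, so the oracle test can compare against brute force
  directly. Sensitivity/specificity CIs are Clopper–Pearson; likelihood
  ratio CIs use the log method.
* **AUC comparison**: DeLong's paired placement-value test (the method
  is unnamed in the reference analysis; DeLong is the standard
  rank-based choice), cross-checked against an independent reference
  implementation in the tests.
* **Stepwise logistic regression**: forward selection by
  likelihood-ratio test at p < 0.05 with backward pruning at p > 0.10
  (protocol unstated; these are the conventional SPSS-style defaults
  and are configurable). Features are standardized; exact duplicate
  columns are dropped; perfect separation is flagged and coefficients
  reported from a Firth-penalized (Jeffreys-prior) refit.
* **Bonferroni m**: always the number of correlation tests actually
  run (8 for the 2 × 4 IVIM-perfusion × DCE grid), never hard-coded.
* **Kappa**: the reference analysis reports Cohen's kappa for
  *continuous* measurements without stating a binning rule; the default
  here dichotomizes at the pooled median and the rule is exposed
  (`binning`, `breaks`). This is an interpretation, and the published
  kappa values cannot be reproduced without the raw data.

# Problem sizes and reproducibility

All randomness flows from explicit seeds; identical seeds give
bit-identical phantoms, series, cohorts, and pipeline reports
(checksummed in the run manifest). Sub-seeds for per-subject and
per-stage streams are derived deterministically from the global seed.

The test suite exercises: noiseless round trips on 1000-voxel phantoms
(recovery to 0.1% for IVIM and 1% for Tofts parameters); brute-force
grid-search oracles for both nonlinear fits; exhaustive-search and
Mann–Whitney identities for the ROC; recovery at b = 0 SNR 50 over
1000 voxels (median errors ~4% `D`, ~6% `f`, ~16% `D*`, ~3%
`Ktrans`/`ve`/`vp`, with `D*` always the least stable — the expected
SNR ordering); 5000-replicate type-I-error calibration of the t-test;
200-replicate selection rates for the stepwise regression; and
three independently seeded 75-subject cohorts fitted end-to-end at the
reduced 8 × 8 × 4 resolution. Cohort replication matters for the
direction-pattern check: with the published group SDs, the
standardized group difference for `D*` is only ~0.17, so a *single*
29 + 46 cohort flips its `D*` sign with appreciable probability by
ordinary sampling noise; the check therefore pools three replicates,
which is a Monte-Carlo variance reduction for a property of the
generative means, not a change of conditions.

# Known limitations

* Anatomy is an ellipsoid in a box: no partial volume, motion,
  ghosting, B1 inhomogeneity, or coil effects; co-registration is out
  of scope (synthetic data are generated registered; an identity
  transform is where a registration hook would sit).
* The AIF is a population curve, not a patient measurement; absolute
  DCE parameter accuracy on real data depends on the patient AIF.
* The published per-patient tables cannot be reproduced (no deposited
  data); the package reproduces the *qualitative* group structure and
  validates the machinery.
* The pooled t applied to the published `D` row summaries gives
  t ≈ 2.27 (p ≈ 0.026), not the p < 0.001 printed for every parameter;
  the source of that discrepancy (a different test, pairing, or a
  typo) cannot be resolved from the text and is documented rather than
  reconciled.
* Fitted `D*` remains upward-biased at low `f` even after bound
  flagging; ROI medians are robust but ROI means inherit some bias —
  mirrored in the wide `D*` spreads of published NPC cohorts.
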