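# ivimdce

Quantitative MRI staging analysis for nasopharyngeal carcinoma (NPC) as
a tested, reusable R pipeline: voxel-wise **intravoxel incoherent
motion (IVIM)** diffusion/perfusion fitting, **extended-Tofts**
dynamic-contrast-enhanced (DCE) pharmacokinetic fitting with
variable-flip-angle T1 mapping, and the cohort-level statistics used to
compare low-stage (AJCC I+II) against high-stage (III+IV) disease —
t-tests, ROC cut-offs with likelihood ratios, DeLong AUC comparison,
stepwise logistic regression, and Bonferroni-corrected Spearman
correlation between the IVIM perfusion-related and DCE parameters.

Patient images for the reference cohort are not publicly available, so
the package ships a first-class synthetic-data module: digital phantoms
and 75-subject cohorts whose group distributions follow the published
subject-level summaries, acquired through the full forward models
(bi-exponential IVIM signal with Rician noise; spoiled-gradient-echo
DCE driven by a Parker-style population arterial input function). Every
downstream stage is validated end-to-end against this ground truth.

It is written for imaging scientists who want a transparent, fully
scriptable reference implementation of this analysis chain, and for
methodologists who need a digital-reference-object harness for IVIM /
extended-Tofts estimators.

## Models

IVIM bi-exponential signal decay over 13 b-values (0–1000 s/mm²):

    S(b)/S0 = (1 − f)·exp(−b·D) + f·exp(−b·(D + D*))

fitted with the segmented approach: log-linear `D` on b > 200 s/mm²,
then bounded Levenberg–Marquardt for `(f, D*)` over all b-values, with
SNR and identifiability filters per voxel.

Extended-Tofts tissue concentration against the plasma input `Cp`:

    Ct(t) = vp·Cp(t) + Ktrans · ∫ Cp(τ)·exp(−kep·(t − τ)) dτ,
    kep = Ktrans / ve

preceded by two-point variable-flip-angle T1 mapping (5°/15°, TR
4.8 ms) and linear-relaxivity signal-to-concentration conversion.

## Worked example

```r
library(ivimdce)

# one synthetic subject: phantom -> acquisitions -> fitted maps
ph  <- generate_phantom(shape = c(10, 10, 10), cv = 0.1, seed = 1)
dwi <- simulate_dwi(ph, noise_sigma = 20, seed = 2)   # b=0 SNR 50
iv  <- fit_ivim_map(dwi, ph$roi_mask, noise_sigma = 20)
roi_mean(iv$D_map, ph$roi_mask, iv$valid_mask)

# whole study: simulate cohort, fit every subject, staging statistics
res <- run_pipeline(default_config(seed = 42), verbose = FALSE)
print(res$report)
```

The report for the default study (29 low + 46 high subjects, induced
cross-correlation 0.5, reduced 8×8×4 grids) prints, among other things:

```
Group comparison (pooled Student's t):
 parameter     mean_low    mean_high          t df        p
         D 0.0008151846 0.0006850938  2.670794 73 9.32e-03
    Ktrans 0.6457916441 0.5058010652  5.737007 73 2.05e-07
        ve 0.4898612445 0.7336309254 -4.040409 73 1.31e-04
        ...

ROC (AUC, optimal cut-off, sens, spec):
  Ktrans  AUC=0.828 cut=0.5406 sens=71.7% spec=89.7% LR+=6.93 LR-=0.32
  ...

IVIM x DCE Spearman correlations (Bonferroni m = 8):
     mean_f mean_Ktrans  0.506   2.88e-05  TRUE
```

Reading: every fitted group mean moves in the direction of the
reference cohort (lower `D`, `f`, `D*`, `Ktrans`, `kep`, `vp`, higher
`ve` in high-stage disease), `Ktrans` is the strongest single
discriminator, and the induced correlation between the IVIM perfusion
fraction and `Ktrans` is recovered and survives Bonferroni correction.

## Analysis workflow

The study itself is organized as numbered driver scripts over the
package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + ground truth
Rscript analysis/02_fit_parameter_maps.R  # voxel-wise IVIM + Tofts fits
Rscript analysis/03_cohort_statistics.R   # staging statistics report
Rscript analysis/04_figures.R             # ROC curves, scatter plots
```

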