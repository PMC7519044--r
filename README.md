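# gaitwomac

Gait-cycle feature analysis and estimation of WOMAC knee-osteoarthritis
severity.

## What this package is for

Clinical gait analysis produces kinematic and kinetic waveforms (joint
angles, moments, powers over the normalized 0–100 % gait cycle) that carry
objective information about knee osteoarthritis (KOA), but their volume and
complexity keep them out of routine clinical use. Patient-reported outcomes
— above all the WOMAC index, 24 items scored 0–4 for a total of 0–96 —
grade KOA severity cheaply but subjectively, and are unusable for patients
who cannot answer reliably. `gaitwomac` is for biomechanics and
clinical-research groups who want to bridge the two: it turns gait-lab
waveforms into a large, named feature set, identifies the features that
separate WOMAC severity classes, and builds regression models that estimate
a patient's WOMAC total from gait alone.

## The method in brief

1. **Severity binning.** With items answered 0–4, the midpoint response
   levels 1.5 and 2.5 mark the mild/moderate and moderate/severe
   transitions; multiplied by the 24 items they give cut points 36 and 60
   on the total (below 36 mild, 36–60 moderate, above 60 severe). Subscales
   are binned by the same rule with their own item counts.
2. **Feature extraction.** Each right-leg waveform is normalized to 101
   cycle points and segmented at toe-off (60 %) into stance/swing and the
   seven Perry sub-phases. A registry of 1060 features is computed per
   subject: windowed summary statistics (SD, variance, RMS, crest factor
   `max|x|/rms`, non-excess kurtosis `m4/m2²`, range, …), signed areas under
   the curve, phase extrema, periodogram area (= variance, by Parseval) and
   99 %-occupied bandwidth, the autocorrelation lower bound
   `min_k r(k)`, the bimodal-histogram mid-reference level, and the dynamic
   time warping distance between stance and swing shapes.
3. **Selection.** Per feature, a one-way ANOVA across the three severity
   groups at α = 0.0001, then all three pairwise Student t-tests at the
   Bonferroni-corrected α = 0.00003; features significant in every
   comparison are the *key features*. The same two gates re-run with classes
   from each WOMAC subscale give the subscale associations.
4. **Estimation.** Classes are balanced by random under-sampling of the
   largest groups to n = 231 (140/182/53 → 89/89/53), split 70/30, and the
   WOMAC total is regressed on the key features by ordinary least squares
   and by a 500-tree random forest; models report hold-out RMSE (WOMAC
   points) and Pearson r.

Because the motivating clinical cohort is private, the package includes a
synthetic-cohort generator (`generate_cohort()`) in which a single latent
severity drives both the WOMAC records (group means/SDs 18.9 (11.9),
48.5 (6.8), 71.7 (10.3)) and severity-dependent waveform effects in the
published directions (knee varus angle grows with severity, knee flexion
amplitude and walking speed shrink, …). `planted_truth()` exposes the
ground-truth feature set of any configuration so selection and estimation
can be validated end to end.

## Worked example

```r
library(gaitwomac)

cfg <- pipeline_config(cohort = cohort_config(seed = 42))
res <- run_pipeline(cfg, "out")
head(select_key_features(res$selection), 3)
```

The run logs every stage:

```
[simulate] seed 42: generating 140/182/53 cohort
[cohort] 375 subjects
[extract] 1060 features x 375 subjects (full registry)
[classes] mild/moderate/severe = 139/189/47
[select] 991 passed ANOVA (alpha 0.0001), 939 key features (alpha 3e-05)
[subscales] significant features: pain 918, stiffness 911, physical function 935
[balance] down-sampled 375 -> 231 (92/92/47)
[split] train 162 / test 69
[models] using top 50 of 939 key features (by ANOVA p)
[linear] hold-out RMSE 5.76, r 0.969 (in-sample RMSE 4.70, r 0.976)
[random_forest] hold-out RMSE 5.31, r 0.973
```

Reading the output: 375 simulated subjects are classified from their WOMAC
totals (139 mild / 189 moderate / 47 severe at this seed); 939 of 1060
features survive both selection gates — far more than a clinical cohort
would yield, because the generator's within-group variability is
deliberately cleaner than real gait data (see the methods vignette); the
hold-out RMSE of ~5.8 WOMAC points and r ≈ 0.97 sit just below the
configuration's analytic ceiling `attainable_r(cohort_config())` ≈ 0.975,
which is what a correct implementation should achieve on this generator.
The top key features at this seed are knee-varus-angle statistics
(`knee_varus_angle.max_minus_min`, `knee_varus_angle.dtw_stance_swing`, …),
matching the planted severity effects. Artefacts written to `out/`:
`features.csv`, `registry.csv`, `selection.csv`, `subscales.json`,
`model_linear.json`, `model_random_forest.json`, `predictions.csv`,
`summary.log`.

On real data, replace the simulation with CSVs
(`read_cohort(waveforms, spatiotemporal, womac)`; long-format waveform
rows `subject_id, parameter, cycle_pct, value`). A thin command-line driver
with `simulate` / `extract` / `select` / `fit` / `run-all` subcommands is
installed at `inst/scripts/gaitwomac-cli.R`. The published real-data
accuracies (RMSE 16.10/17.38, r 0.722/0.741) required the private hospital
cohort and are qualitative reference points only.

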