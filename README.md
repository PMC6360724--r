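# turnoutfoot

Three-dimensional multi-segment foot kinematics of ballet turnout, as a
tested, reusable R pipeline.

## The problem

Turnout — maximal external rotation of the lower limb — is fundamental to
classical ballet. Dancers with limited hip external rotation compensate
below the hip: the whole foot abducts, the hindfoot everts, the midtarsal
joint unlocks and the medial longitudinal arch can lower, and the hallux
may deviate laterally at the first metatarsophalangeal joint (MTPJ).
Quantifying these strategies needs a dance-specific multi-segment foot
model: rigid marker clusters per segment, virtual anatomical landmarks
reconstructed by the Calibrated Anatomical System Technique (CAST),
functional joint calibration, and joint-coordinate-system (JCS) angles.

This package is for biomechanists and dance-science researchers who want
that measurement chain end to end, with a forward-kinematic synthetic
marker generator providing ground truth for every stage, so each claim the
pipeline makes is covered by a recovery test.

## The model in brief

Per segment *s* with technical cluster markers, the pose in frame *t* is
the least-squares rigid transform (R_s(t), d_s(t)) from the natural-stance
cluster geometry (SVD solution, det +1). An anatomical point *p* digitised
in stance is carried as local coordinates R_s^T (p - d_s) and reconstructed
in every frame (CAST). Functional calibration solves, over stacked frames,

    R_p(t) c_p - R_c(t) c_c = d_c(t) - d_p(t)

for the hip centre fixed in both segments (SCoRE, least squares) and takes
the smallest right singular vector of the same system as the knee flexion
axis (SARA). Joint angles are intrinsic Cardan decompositions of
R_parent^T R_child in the flexion / inversion-eversion / axial-rotation
sequence; the first-MTPJ angle is the signed angle between MT1->HAL and the
anterior metatarsal axis MTB1->MT1, projected onto the metatarsal
transverse plane. Demi-plié events are per-cycle pelvis-height minima in
sauté trials (the three most consistent consecutive cycles are averaged);
navicular drop is the loss of navicular height relative to natural stance.
Cohort inference uses repeated-measures ANOVA with the Greenhouse-Geisser
epsilon (tr S)^2 / ((k-1) tr S^2) on the double-centred condition
covariance, Bonferroni-adjusted paired comparisons, stepwise regression
(entry p <= 0.05, removal p > 0.10) and Pearson correlations.

Sign conventions are side-aware: eversion, abduction and external rotation
are positive for either limb. Frontal-plane angles are referenced to the
natural-stance calibration posture; transverse-plane angles, the MTPJ
angle and navicular height are absolute (see the methods vignette,
`vignettes/turnoutfoot-methods.Rmd`).

## Worked example

Simulate one dancer (250 Hz markers, 0.5 mm noise, ten sautés at 95 bpm)
and run the full pipeline — calibration, filtering, frames, angles, events,
measures:

```r
library(turnoutfoot)
cfg <- synth_config(seed = 7, noise_sd = 0.5)
subject <- generate_subject(cfg)
res <- run_subject(subject$trials, subject = 1)
print(res)
#> <subject_result> subject 1 | 24 condition values; 10 sautes detected
print(res$events)
#> <event_set> 10 minima; selected cycles 2,3,4 at frames 237,395,553
```

The recovered per-condition values (degrees; navicular drop in mm):

```
           variable   natural functional forced saute
  hindfoot_eversion -0.000178       4.40   6.04 14.95
  midfoot_abduction  2.885480       5.65   6.55  7.81
 forefoot_abduction  7.052277       7.81   8.43  8.18
     foot_abduction  9.846771      28.13  35.72 30.14
     mtpj_abduction 10.674592      11.82  13.38 12.68
  navicular_drop_mm  0.000000       1.63   1.96 12.90
```

Reading this like a clinical report: the dancer everts the hindfoot about
4.4 degrees more in functional turnout than in natural stance and nearly
15 degrees at the demi-plié of a sauté; the arch drops 12.9 mm during
sautés but barely moves in the static turnout positions; the MTPJ angle
stays in the `normal` hallux-valgus class (< 15 degrees) throughout, and

```r
classify_navicular(12.90)
#> stable
```

puts the sauté arch behaviour at the top of the `stable` band (7-13 mm).
These numbers echo the generator's prescribed condition offsets, which is
the point: the pipeline recovers known truth from raw noisy markers.

## The analysis workflow

The study-level analysis lives in numbered drivers under `analysis/`,
each a thin narrative over the package functions, writing tables under
`results/`:

1. `01_simulate_cohort.R` — draw an 18-dancer cohort (generative truth).
2. `02_process_kinematics.R` — full marker-level pipeline per subject.
3. `03_summarise_conditions.R` — condition summary, deltas, classifications.
4. `04_statistics.R` — RM-ANOVA (Greenhouse-Geisser, Bonferroni), stepwise
   regression of foot abduction, knee-rotation correlations.

Run them in order from the repository root with `Rscript`.

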