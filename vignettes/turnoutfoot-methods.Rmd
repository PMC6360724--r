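---
title: "Methods: a dance-specific multi-segment foot model for turnout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dance-specific multi-segment foot model for turnout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnoutfoot)
```

## What the pipeline computes

Ballet turnout is the maximal external rotation of the lower limb. Dancers
with limited hip external rotation compensate distally: the foot abducts,
the hindfoot everts, the midtarsal joint unlocks, and the medial
longitudinal arch can lower. This package implements the full measurement
chain used to quantify those compensations with a marker-based
multi-segment foot model:

1. **Marker IO** — trials are frames x markers x XYZ blocks in millimetres
   at 250 Hz, read and written in a documented tab-separated format with an
   explicit gap flag per marker-frame.
2. **Filtering** — dynamic (sauté) trials are low-pass filtered with a
   zero-lag Butterworth filter, default 26 Hz; a Winter-style residual
   analysis is available to choose the cutoff from the data.
3. **Rigid-body estimation** — each segment carries a technical marker
   cluster; its pose per frame is the least-squares (SVD) rigid transform
   from the cluster's natural-stance geometry, with the standard
   reflection guard.
4. **CAST** — anatomical points digitised in the natural-stance calibration
   trial (malleoli `LMAL`/`MMAL`, heel offset `CALe`, first metatarsal head
   `MT1`, knee joint centre from the lunge) are stored in their segment's
   technical frame and reconstructed in every frame of every trial.
5. **Functional calibration** — the hip centre is the symmetrical
   centre-of-rotation estimate (SCoRE) from the circumduction trial and the
   knee flexion axis the symmetrical axis estimate (SARA) from the squats,
   both solved as one linear least-squares system over the stacked
   per-frame pose equations.
6. **Anatomical frames and angles** — joint-coordinate-system Cardan angles
   for hindfoot-relative-to-tibia (frontal plane: eversion),
   midfoot-relative-to-hindfoot, forefoot-relative-to-midfoot, whole-foot
   relative-to-tibia and thigh-shank (transverse plane: abduction /
   external rotation), plus a bespoke first-MTPJ transverse-plane angle and
   navicular height.
7. **Events and measures** — demi-plié instants are the per-cycle minima of
   pelvis height during sautés; the three consecutive sautés with the most
   consistent excursions are selected, and each variable is averaged over
   those three demi-pliés. Navicular drop is referenced to natural stance;
   hallux-valgus severity and arch-stability classes follow the published
   interval schemes.
8. **Statistics** — one-way repeated-measures ANOVA with Greenhouse-Geisser
   correction and Bonferroni pairwise comparisons, stepwise multiple linear
   regression, and Pearson correlations, all implemented from their
   defining formulas and cross-checked against independent oracles in the
   test suite.

## Segment frames: recipes and the stance-reference convention

The published multi-segment protocols defer the segment-axis recipes to
their source model descriptions, so this package declares explicit,
testable recipes and isolates them in one construction function
(`build_frames()`):

* Every moving segment's **vertical axis** is the lab vertical snapshotted
  in the natural-stance calibration trial and carried by the segment's
  technical frame (CAST). All frames are therefore exactly level in the
  calibration posture.
* **Anterior axes** come from marker geometry: tibia from the malleoli and
  the knee joint centre, hindfoot from `CAL` toward the mid-point of
  `SUS`/`HDL`, midfoot from the dorsal `MFM` marker, forefoot from
  `MT2`-`FFM`, whole foot from `CALe` toward `FTML` (the `MT1`-`MT5`
  mid-point). The first-metatarsal frame instead keeps its anterior axis
  exact along `MTB1` to `MT1` (the `X_MET` direction), so its "vertical" is
  the metatarsal transverse-plane normal, tilted by the declination angle.
* The **mediolateral axis** always points to the subject's left; clinical
  signs (eversion, abduction, external rotation positive) are applied per
  side, so left and right feet report identical signed values for the same
  physiological motion (verified by a mirror test).

A consequence of the stance-snapshotted verticals is a mixed reference
convention, stated here explicitly because it affects interpretation:
**frontal-plane angles (hindfoot eversion) are measured relative to the
natural-stance posture**, while transverse-plane angles are absolute
heading differences and the MTPJ angle and navicular height are fully
marker-defined. Condition *differences*, the ANOVA, the regression and the
correlation structure are invariant to the per-variable constant this
introduces; only the natural-stance column of a summary table reads near
zero for frontal angles rather than a small absolute posture value. We
chose this over an ad-hoc absolute vertical per segment because it is
exactly reproducible from the calibration trial, requires no unprinted
anatomical constants, and zeroes soft-tissue-free synthetic neutral stances
to machine precision — which is what makes the end-to-end recovery tests
sharp.

Projection-based transverse angles have a known geometric property: when a
large frontal-plane rotation acts simultaneously, the horizontal heading of
an anterior axis with a vertical slope shifts by approximately
(slope x sin(tilt)). The recovery tests therefore prescribe one waveform at
a time when asserting exactness (noise-free RMS below 0.01 degrees), and
the cohort emulation accepts the sub-degree cross-talk as part of what a
projection angle measures.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `filter cutoff` | 26 | Hz | study processing choice, from residual analysis |
| `filter order` | 4 (2 per pass) | — | dominant biomechanics convention; no dual-pass cutoff correction |
| padding | max(12, 6 x rate/cutoff) | samples | odd reflection; the IIR start-up transient decays over ~rate/cutoff samples, so a fixed 3 x order pad leaves visible edge error at low cutoffs |
| `tempo_bpm` | 95 | beats/min | sauté tempo; one sauté per beat |
| `min_cycle_s` | 0.4 x beat period | s | minimum separation between demi-plié minima |
| `min_relative_depth` | 0.25 | — | minima with excursion below this fraction of the deepest cycle are noise dips, not sautés |
| Cardan sequence | `yxz` | — | flexion, then inversion/eversion, then axial rotation; configurable per joint |
| CI multiplier | 1.96 | — | normal-quantile 95% CI; SE uses the sample SD |
| `noise_sd` | 0.5 | mm | synthetic marker noise, inside the system's stated sub-millimetre accuracy |

Classification schemes are total step functions with every printed endpoint
pinned by a test. The hallux-valgus scheme leaves the open interval
(20, 21) degrees unassigned in its printed form; values there map to
`mild`. The arch-stability "7 to 13 mm" band is treated as closed on both
ends.

## The synthetic generator

`generate_trial()` forward-kinematically poses a pelvis-thigh-shank-foot
chain with articulated hindfoot, midfoot, forefoot, first-metatarsal and
hallux segments. The shank is the kinematic root: intra-foot joint
rotations compose distally and the thigh and pelvis hang proximally through
the inverse knee and hip rotations, so a prescribed joint angle *is* the
relative segment rotation the pipeline must recover. Design choices worth
knowing:

* **Arch lowering** is a world-vertical translation of the midfoot subtree,
  so the prescribed navicular drop equals the noise-free height change of
  the `NAV` marker exactly, independent of simultaneous rotations.
* **MTPJ rotations** are prescribed about the metatarsal frame's own
  transverse-plane normal — the axis the angle is measured about — not the
  lab vertical.
* Marker noise is i.i.d. Gaussian per coordinate. A low-frequency
  sinusoidal soft-tissue-artifact hook exists (`sta_amplitude_mm`) but is
  off by default: nothing in the emulated protocol calibrates it.
* The default geometry is a plausible adult lower limb (documented
  coordinates in `synth_geometry()`); it is declared test geometry, not an
  anthropometric claim. Cluster sizes and lever arms are realistic enough
  that 0.5 mm marker noise propagates to roughly 0.3-0.45 degrees RMS in
  the filtered angle streams.

`generate_cohort()` draws per-subject condition values around the published
cohort means. Each variable carries a postural **trait** (all conditions)
and a turnout **gain** (turnout conditions only); foot abduction and the
seated knee external-rotation measurements are coupled to the
hindfoot-eversion gain. This is the mechanism the study describes — dancers
with limited knee/hip external rotation compensate through pronation — and
it is also what survives the stance-referenced measurement convention: a
trait common to all conditions cancels from a stance-referenced angle,
a turnout gain does not. Within-subject SDs were sized once, analytically,
from the scale of the published F statistics (about 3 degrees for hindfoot
eversion, 1.1-1.4 degrees for the other foot angles, 3 mm for navicular
drop), with a smaller value in the highly reproducible natural stance; the
regression and correlation couplings were sized analytically for an R^2
near 0.55 and r near -0.6. Means for whole-foot abduction and the seated
measurements are not printed in the study and were set once to
field-plausible turnout magnitudes (8/25/32/25 degrees across conditions;
40/45 degrees seated). None of these constants were adjusted afterwards.

What the generator does **not** emulate: soft-tissue artifact (by
default), marker occlusion and relabelling, force data, dynamically
consistent jump kinetics (the sauté modulates segment poses and pelvis
height kinematically), and anthropometric variation between subjects
(geometry is shared; only joint angles vary). Passing recovery tests
therefore demonstrate the correctness of the estimation chain on rigid,
well-labelled data — not robustness to every artifact of a real capture
volume.

## Numerical choices

* Pose estimation uses the SVD solution with the smallest-singular-direction
  flip when the determinant is negative; reference clouds that are
  collinear to 1 part in 10^9 are rejected.
* SCoRE/SARA solve one stacked linear system. A single collapsed singular
  direction (a perfect hinge) leaves a one-parameter family of centres;
  SCoRE returns the minimum-norm member, which lies on the axis. More than
  one collapsed direction (pure translation) is a conditioning error. SARA
  warns when the two smallest singular values are comparable (ball-like
  motion). Axis sign is fixed deterministically (largest-magnitude
  parent-frame component positive; the knee axis is then re-oriented toward
  the subject's left at calibration).
* Cardan decomposition clamps the middle-angle sine into [-1, 1] and flags
  gimbal proximity beyond 85 degrees.
* Demi-plié plateau ties resolve to the earliest frame; candidate minima are
  accepted lowest-first under the separation constraint.
* Stepwise regression enters the smallest partial-F p-value at or below
  0.05 and removes the largest above 0.10 after each entry (the defaults of
  the statistics package named by the study), terminating when neither rule
  fires; with both thresholds at 1 it reproduces full-model OLS to 1e-10.
* Greenhouse-Geisser epsilon is computed from the double-centred condition
  covariance and clamped into [1/(k-1), 1].

## Problem sizes

The test suite and the acceptance script use: 10-cycle sautés at 95 bpm and
250 Hz (1579 frames), static trials of 60-100 frames, 400-frame
squat/circumduction calibrations, 500-frame functional-joint simulations,
cohorts of 18 subjects, 2000-replicate null simulations for the ANOVA size
check, and 100-1000-case property sweeps for the geometry kernels. These
sizes make every published effect scale reproducible while keeping a full
run in minutes on one CPU.

## Known limitations

* The exact segment-axis recipes of the source foot-model family are not
  printed in the study; the recipes here are declared equivalents, and all
  angle semantics are defined by them.
* The knee transverse-plane angle uses a declared frame recipe (KJC, hip
  SCoRE centre, SARA flexion axis); the study does not print how the SARA
  axis enters its angle definition.
* Gaps are rejected, not repaired: the study states no gap-filling
  procedure, and silent interpolation would bias event-level extraction.
* C3D input is not supported in this build; the canonical tab-separated
  format is the single on-disk representation.
* Retrospective power calculations are out of scope; the printed power
  values depend on unstated software settings.
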