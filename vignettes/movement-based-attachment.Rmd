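---
title: "Movement-based attachment classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based attachment classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attachkin)
```

## The measurement problem

Doll-play story-stem instruments classify a child's attachment pattern
from how they complete mildly stressful vignettes with a child-doll and
a mummy-doll. The coding is four-way — B (secure), A (insecure
avoidant), C (insecure ambivalent), D (insecure disorganised) — with
two binary collapses used in practice: secure vs insecure (B | A,C,D)
and organised vs disorganised (B,A,C | D). Manual coding requires
extensively trained raters; computerised delivery with video capture
opens the door to automatic rating.

The behavioural hypothesis behind automatic rating is that secure play
shows smooth, fairly rapid movement that reduces the distance between
the dolls (proximity seeking), while insecure play shows weaker or more
erratic approach, wider separations, or one doll being favoured. Since
the dolls are held in the hands, the kinematics of the two wrists —
tracked by an off-the-shelf pose estimator — carry the signal.

## The pipeline

### Features

From each frame's wrist keypoints we compute six families, all
normalised to the image so they are resolution-independent:

| family          | definition                              | unit    |
|-----------------|------------------------------------------|---------|
| position        | (x/width, y/height) per hand             | unitless|
| inter-hand distance | Euclidean distance of the normalised wrist positions | unitless |
| speed           | backward difference ‖pₜ − pₜ₋₁‖·fps, 0 at t = 0 | 1/s |
| acceleration    | \|speedₜ − speedₜ₋₁\|·fps, 0 at t = 0, 1  | 1/s²    |
| 1-D trajectory  | x/width per hand                         | unitless|
| presence        | per-frame detection flag; windowed proportion | unitless |

Speed and acceleration are scalar physical measurements (magnitudes),
computed by backward finite differences with zero padding at the
boundary. Normalising both axes by the image dimensions keeps every
feature image-relative, matching the 1-D trajectory convention
(placement with respect to the image width).

Missing hands (confidence below the 0.1 threshold; confidence exactly 0
always) follow a *hold-last* policy for the kinematic channels: the hand
keeps its last seen position, so detector dropouts do not fabricate
speed spikes; the per-frame presence flags and the windowed presence
proportions carry the dropout information instead. An undefined
inter-hand distance (a hand absent) holds the last defined value with a
companion validity flag, so the classifier sees both the value and its
reliability. Leading missing runs are back-filled from the first
observation; a never-seen hand sits at image centre with presence 0.

### Windows

Feature sequences are segmented into non-overlapping 128-frame windows
— about 4.25 s at 30 fps, the classifier's input unit. A session of T
frames yields ⌊T/128⌋ windows; the trailing remainder is discarded.
The frame rate is configurable (stored per sequence) with default 30
fps, the value at which 128 frames match the ~4.25 s window convention.
Windows inherit the child's label (secure = B; insecure = A, C, D):
there is no window-level ground truth.

### Classifiers

Two backends share one interface:

* **Recurrent (reference).** A single-layer LSTM (default hidden size
  8) over the 14-channel frame sequence; hidden states are mean-pooled
  over time and fed to a logistic head. Training minimises
  class-weighted binary cross-entropy with full-batch Adam (default 60
  epochs, step 0.05). Inputs are standardised per channel with training
  means/SDs stored in the model. Initial weights are uniform
  ±1/√fan-in with the forget-gate bias at +1 (the standard trick that
  preserves memory early in training); all randomness comes from the R
  RNG, so a fixed seed makes training bit-reproducible. The
  backpropagation-through-time gradients are verified against central
  finite differences in the test suite.
* **Summary-logistic (baseline).** Logistic regression (`stats::glm`)
  on 19 per-window summary statistics (means/SDs of distance, speed,
  acceleration and trajectory channels, mean vertical positions,
  distance-validity rate and the two presence proportions). Fully
  deterministic and fast; the test suite leans on it.

Class weighting defaults to inverse frequency ("balanced") because
community samples run roughly 70/30 secure/insecure. Models embed
their feature schema and refuse to predict across schema mismatches.

### Majority vote

A child's rating is the modal hard label over their windows, using at
most 500 windows in temporal order (configurable, `Inf` allowed). The
cap bounds each child's influence on the decision. Exact ties resolve
to *insecure*: as a screening decision, the cost of missing an insecure
child exceeds the cost of a false alarm. The reported `vote_fraction`
is the fraction of used windows voting for the assigned label and
therefore always lies in [0.5, 1].

### Evaluation

Leave-One-Child-Out: one fold per child, trained on all other
children's windows, tested on the held-out child. This is the correct
protocol when windows from one child are strongly dependent — any
random window split would leak child identity into training. Fold k
retrains with seed `spec$seed + k`, making the whole protocol
reproducible. Metrics use *insecure* as the positive class (with a
majority-secure population and the screening orientation, precision
below recall is the expected regime) and are reported at both child
level and window level, since the two levels generally differ.
Degenerate folds whose training set holds a single class (possible only
in minimal designs such as two children) predict the training-class
prior, with a warning — the only model such a fold supports.

`compute_metrics` reports ratios with zero denominators as `NaN` with a
warning, never silently 0.

### Agreement statistics

Percent agreement (100·trace/N), discordance (N − trace) and Cohen's
κ = (p₀ − pₑ)/(1 − pₑ) with pₑ = Σᵢ rᵢcᵢ/N², over any square
cross-tabulation; ABCD matrices use the fixed category order
(B, A, C, D) so printed tables transcribe directly, and collapse by
block summation. Values are kept at full precision internally; the
display layer rounds percentages to integers and κ to two decimals,
matching how such results are conventionally printed. Note one
consequence: an observed agreement of 86.9% *rounds* to 87 even where a
source may print 86 by truncation — we do not adopt truncation.
κ is undefined (`NaN`, with a warning) when pₑ = 1.

## The synthetic cohort generator

Because child videos cannot be shared, the package ships a seeded
simulator whose output exercises every downstream stage in the pose
format the reader consumes.

Each hand is a point mass under critically damped spring–damper
dynamics (natural frequency 6 rad/s) toward a piecewise-constant
target; targets are resampled at Poisson "play events" (`event_rate`
per minute). Half of the events are *approach events*: for 2 s both
targets contract exponentially toward a shared point at
`approach_rate` (1/s) — the proximity-seeking signature. Acceleration
noise (`jerk_sd`, units/s²) makes movement erratic; observation noise
(`noise_sd`) models pose-estimation jitter; positions reflect off the
image bounds; each hand drops out per frame with its own probability.
The non-wrist joints are emitted as a static plausible upper-body
layout at confidence 0.9 so files are schema-complete.

The class presets encode the behavioural hypothesis, chosen once as
plausible doll-play kinematics:

* secure: approach 3/s, 10 events/min, jerk 0.08, dropout 2%/2%,
  rest separation 0.3;
* insecure (union preset): approach 0.4/s, 25 events/min, jerk 0.5,
  dropout 5%/18%, rest separation 0.6; A/C/D sublabel variants derive
  from it (A: wider separation 0.75 and right-hand dropout 35%;
  C: more frequent switching; D: highest jerk and switching), so the
  binary task consumes the union while the four-way labels exercise the
  agreement module.

Cohorts assign `round(n·secure_fraction)` children to B and split the
rest A/C/D in equal thirds (remainder to C). Child i simulates with
seed `seed + i`; the generator saves and restores the caller's RNG
state, so output is a pure function of (spec, seed).

Default problem sizes: 40 children, 896 frames each (7 windows of 128
at 30 fps ≈ 30 s per child). These sizes give every child a meaningful
majority vote while keeping a full LOCO of the recurrent backend to a
few minutes on one CPU; the graded-separation analyses interpolate the
insecure preset toward the secure one at factors 0.15, 0.5 and 1, a
spread wide enough that median accuracies over five seeds order
stably.

**What passing tests show — and do not.** The simulator produces
class-conditional differences in all six feature families (each checked
marginally at generator level), smooth differentiable trajectories, and
realistic dropout. It does *not* model story-stem narrative structure,
crisis timing, camera framing changes, pose-estimator failure modes
that correlate with behaviour, or the label noise of human raters. A
pipeline that separates the synthetic classes demonstrates that the
implementation extracts and uses the intended kinematic signal; it says
nothing about accuracy on real children, where effect sizes are far
smaller and labels are imperfect. Conversely the null check (identical
class parameters ⇒ chance-level accuracy inside the 95% binomial
interval) shows the protocol does not manufacture signal — the LOCO
design has no child-level leakage by construction, and the test suite
asserts the fold partitions directly.

## Numerical and design notes

* Backward differences with zero padding mean the first frame has speed
  0 and the first two frames acceleration 0; a static input yields
  exactly zero speed and acceleration (no floating-point drift), which
  the tests assert as equalities.
* Distance, speed and acceleration are translation-invariant by
  construction (they depend only on coordinate differences); position
  and trajectory are not — both properties are tested.
* The 500-window cap is read as a cap on *windows* (segments), the unit
  the vote aggregates; `Inf` is allowed for unbounded sessions.
* The logistic backend can be restricted to a named subset of summary
  features (`summary_features`); restricting it to the inter-hand
  distance family alone still classifies the synthetic fixture above
  chance, confirming the proximity signal is not funnelled through a
  single engineered channel elsewhere.
* Sessions shorter than 2 frames, windows from empty feature tables,
  single-class training sets, mixed-child vote inputs and schema
  mismatches are all hard errors; a child contributing zero complete
  windows is excluded from cohort assembly with a warning.
* Warm-up vignettes (non-scored story stems) are not trimmed by
  default; callers can pre-trim sequences before feature extraction.

## Limitations

Automatic four-way (ABCD) or organised/disorganised classification is
out of scope — the binary secure/insecure decision is the validated
target at realistic sample sizes. Depth (3-D inter-doll distance) is
not consumed even though depth-capable cameras exist for this setting;
the published feature set is 2-D. The recurrent architecture (depth,
hidden size, optimiser schedule) is an implementation choice of this
package, not a published fact; the defaults favour reproducibility and
desk-scale runtimes over capacity.
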