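---
title: "Kinematics features from hourly vital signs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics features from hourly vital signs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sepkin` treats a patient as a point moving through the space spanned by
six vital signs (HR, O2Sat, Temp, SBP, DBP, Resp — always in that
order). The working hypothesis is geometric: patients who develop sepsis
drift toward a common *sepsis position* in this space during the hours
preceding onset, while other patients fluctuate around their baseline.
Classifiers are then given, instead of (or rather than) the raw signs,
the patient's *kinematics relative to that target*:

* the unit relative-position vector
  $\vec e(t) = (\vec r(t) - \vec r_B)/|\vec r(t) - \vec r_B|$, which
  encodes *where* the patient sits relative to the target, scale-free;
* the scalar projection of the relative velocity
  $\vec v(t) = \vec r(t) - \vec r(t-1)$ onto $\vec e(t)$, the signed
  hourly rate of change of the distance along the line of sight
  (negative = approaching);
* the projection of the relative acceleration
  $\vec a(t) = \vec v(t) - \vec v(t-1)$ onto $\vec e(t)$.

The sepsis position itself is the component-wise **median of the
positive patients' normalised vital signs at their sepsis onset**. The
median (midpoint of central order statistics for even counts) makes the
estimate robust to the occasional aberrant onset row, and the estimator
sits behind a small constructor interface so that alternatives (a moving
target, per-subgroup targets) can be added without touching the feature
math. Only the static median estimator is implemented.

Assumptions worth keeping in mind: the target is *static* and *common to
all patients*; time steps are exactly one hour, so first differences are
velocities with $\Delta t = 1$; and onset is identified with the last
row of a positive patient's series (every register after the first
labelled hour is rejected, so multi-hour label spans collapse to their
first hour — a convention, since the data dialect does not state one).

## Preprocessing cascade

The stages run in a fixed order; each is exported on its own and
`preprocess_cohort()` chains them:

1. **Exclusions** — drop patients with fewer than 36 hourly registers
   (three 12-hour medical shifts), then patients with at least one sign
   entirely missing. A patient failing both is counted once, under the
   first rule (the flowchart is sequential).
2. **Limit clipping** — values outside closed per-sign operating
   intervals become missing. The published procedure takes its limits
   from an external monitoring reference without printing them, so the
   table is a configurable argument; the shipped defaults (HR 20–300
   beats/min, O2Sat 50–100 %, Temp 30–45 °C, SBP 40–300 mm Hg, DBP
   20–200 mm Hg, Resp 4–60 breaths/min) are wide plausibility bounds
   meant to catch sensor/transcription errors only.
3. **Windowing** — keep the trailing 48 hours (four shifts); shorter
   series are front-padded with all-missing rows so every patient's last
   row is aligned (for positives, the onset).
4. **Hourly-mean imputation** — a missing cell (sign *j*, window hour
   *t*) becomes the mean of sign *j* at hour *t* over all patients that
   have it. Means are computed on the window-hour index (the only time
   frame patients share after alignment) and pool the whole processing
   cohort.
5. **Linear interpolation** — residual gaps are interpolated against the
   hour index between nearest observed neighbours; leading/trailing gaps
   take the nearest observed value (linear interpolation is undefined
   there).
6. **Smoothing** — a trailing moving average of the last three hours
   (t−2..t); at the window start the average shrinks to the hours
   available so the series keeps all 48 rows.
7. **Max-normalisation** — $x_{\mathrm{norm}} = x / x_{\max}$ per sign,
   minimum fixed at zero, maxima taken over the full processing cohort
   *before* balancing and recorded in the report. Computing the scale on
   everything mirrors the published procedure but leaks test information
   into training; passing recorded `maxima` back into
   [`normalize_by_max()`] gives the fit-on-train alternative.
8. **Balancing** — optional seeded subsample of the negatives (the
   study kept all positives and drew 3,316 of 13,994 negatives; the
   package takes the target count as an argument).

Numerical notes: clipping uses closed intervals (boundary values are
kept); imputation never alters an observed value (asserted bit-exact in
the tests); smoothing cannot leave the observed hull; the degenerate
"all patients missing a sign at an hour" case is deferred to
interpolation, and a sign with *no* observed value at all is an error
(impossible after the exclusions). The entire cascade is deterministic
given the input and the balancing seed, and it is tested stage-by-stage
against an independent straight-line loop transcription of each formula
at tolerance 1e−12.

## Kinematics conventions

First differences are undefined at the window start, and the feature
matrix must keep 48 rows, so $\vec v(0) = 0$ and
$\vec a(0) = \vec a(1) = 0$. When a patient coincides with the sepsis
position (distance ≤ 1e−12, configurable) the direction is undefined;
$\vec e$ is the zero vector and both projections are 0. Projections at
hour *t* use $\vec e(t)$, as the defining equations are written. The
unit-norm invariant ($\sum_j e_j^2 = 1$ on every row with nonzero
distance, within 1e−9) and the Cauchy–Schwarz bound
$|\mathrm{Proj}^{\vec v}| \le |\vec v|$ are asserted across all tests.

## Classifier harness

Five classifiers, two sequence-aware and three flat references:

| model | architecture | source |
|---|---|---|
| `lstm` | 128 hidden units, 20 % dropout on the final hidden state, dense sigmoid head | in-package |
| `cnn` | one 1-D convolution over time (64 filters, kernel 3), ReLU, global max pool, dense sigmoid | in-package |
| `linear_nn` | single dense layer to sigmoid on the flattened input | in-package |
| `logistic_regression` | ridge-penalised logistic regression (`glmnet`, $\alpha=0$, $\lambda = 1/n$) on the flattened input | glmnet |
| `decision_tree` | CART with default controls, `xval = 0` | rpart |

The three gradient-trained models are implemented inside the package
with plain matrix operations — minibatch Adagrad (batch 64) on binary
cross-entropy — and their backward passes are verified against numerical
differentiation in the test suite. Training is reproducible: weights,
shuffling and dropout all draw from a per-spec seed in a local RNG
scope, so a fixed spec, seed and data give identical predictions
(bit-exact for a fixed BLAS, single-threaded).

Choices the stated configurations leave open, decided once here:
Adagrad learning rate 0.1 with accumulators initialised at 0.1 (the
usual framework convention; without it Adagrad's first step per
coordinate equals the raw learning rate, which overshoots badly);
forget-gate bias initialised to 1; a default budget of 50 epochs with
early stopping when the training loss fails to improve by 1e−4 for 5
consecutive epochs; flat models see the flattened 42 × C vector, since
they have no notion of time and are benchmarks only. One caveat found
during development and worth knowing: on a few hundred patients the
LSTM's training loss sits on a plateau near ln 2 for 10–25 epochs
before it starts to fall, so plateau-based early stopping can trigger
*before* any learning has happened. The evaluation-scale runs in the
tests and the acceptance script therefore train for a fixed 100 epochs
with early stopping disabled (`patience = epochs`), which is past the
plateau while keeping a k-fold comparison of both representations
within minutes on one CPU. For the cross-validation protocol: k = 5
stratified folds (class ratios preserved; the cohort design is
imbalanced), one fold assignment shared by every model and
representation so comparisons are paired, accuracy thresholded at 0.5,
and the fold standard deviation reported alongside each mean. At these
cohort sizes the sequence models remain high-variance learners (128
hidden units against ~240 training patients); fold standard deviations
of several percentage points are expected and the KF-versus-VS
difference for them is directional, not a stable effect size.

Calibration curves use 5 equal-width probability bins by default (the
reliability-diagram default of the scikit-learn lineage this harness
mirrors); empty bins are omitted.

## The synthetic-cohort generator

`sim_config()` defines the study conditions the tests run under.
Negatives are AR(1) fluctuations (autocorrelation 0.8 — hourly vital
signs are strongly autocorrelated) around typical adult ICU baselines
(HR 85, O2Sat 97.5 %, Temp 37 °C, SBP 120, DBP 62, Resp 18). Positives
follow the same process, but over their final 12 hours the *mean* path
(not each noisy realisation — patients end *near* the target, never
exactly on it) moves linearly to a planted sepsis point with the
signature of septic deterioration: HR 100, O2Sat 96 %, Temp 37.8 °C,
SBP 91, DBP 58, Resp 21.7 — systolic pressure down, heart rate,
respiration and temperature up, consistent with a hypotensive onset
profile. Series lengths are uniform on 30–120 h (so the <36-register
exclusion rule has work to do), 10 % of cells are missing, and 0.5 % are
replaced by out-of-limits sensor spikes. Every patient has its own RNG
substream derived from the master seed, so changing cohort composition
never perturbs an individual's series, and identical configs give
byte-identical cohorts.

What the generator does **not** emulate: circadian structure,
interventions (vasopressors, fluids — which make real trajectories
non-monotone), measurement clustering (vitals charted together),
label-span ambiguity, and the 34 other clinical variables of real
records. Passing tests therefore demonstrate that the pipeline computes
what it claims and that the kinematics representation helps *when the
drift-toward-a-point premise holds* — they are not evidence about any
real cohort.

## Problem sizes in the tests

The oracle-equivalence checks use 50 cohorts of 20 patients;
sepsis-position recovery uses 200 positives with stationary noise SD
0.05 (normalised scale) across 100 seeds, against the median's
asymptotic standard error $1.2533\,\sigma/\sqrt{I} \approx 0.0044$, so
the 0.02 acceptance band is ≈ 4.5 SE wide; the no-signal and
drift-benefit evaluations use 200- and 300-patient cohorts with k = 5.
These sizes give stable statistics while keeping the full suite quick
to run; results at larger cohorts differ only in narrower Monte-Carlo
error.

## Known limitations

* The static single-target median is the simplest instance of the
  geometric idea; moving or subgroup-specific targets are out of scope
  (the estimator interface anticipates them).
* Cohort-wide normalisation and hourly-mean imputation both leak
  information across the train/test boundary; this mirrors the published
  procedure and is flagged above, with fit-on-train normalisation
  available as an option.
* Accuracy at a 0.5 threshold is the only headline metric; utility- or
  AUROC-based evaluation is out of scope.
* NN determinism is best-effort: exact reproducibility assumes one BLAS
  thread and an identical BLAS build.
* Because all simulated patients share one baseline, absolute
  vital-sign levels are a stronger signal in the synthetic cohorts than
  they would be across heterogeneous real patients — that heterogeneity
  is precisely what the scale-free relative-to-target geometry is meant
  to remove. On such cohorts the raw-VS representation can outperform
  the kinematics features (the acceptance script reports both), so the
  synthetic comparison exercises the machinery rather than reproducing
  the direction of the published real-data gap.
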