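---
title: "Methods: simulating and analysing closed-loop decoded neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing closed-loop decoded neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inceptr` replicates, at desk scale, a five-session closed-loop decoded
neurofeedback ("inception") protocol: participants view one object (the
*presented* object) while learning, via real-time feedback on classifier
evidence, to covertly activate a second object (the *competitor*); the
question is whether the induced coactivation integrates the two objects'
representations, measured before and after training both behaviourally
(categorical perception) and neurally (cross-session decoding). Two
further objects (*controls*) are never trained and provide the baseline
axis for every comparison. Because no scanner is available at a desk, a
synthetic-data module with known ground truth stands in for it, which
also turns every stage of the pipeline into something that can be tested
against an answer key.

This vignette documents the generative model, the analysis pipeline, the
tunable parameters and their defaults, the numerical choices, and the
design decisions that were genuinely open — together with what the
passing tests do and do not establish about real data.

## The generative model

**Voxel space.** An abstract parcellation: `n_parcels` disjoint index
sets over a voxel vector (default 10 parcels of 12 voxels). Geometry,
atlases and anatomy are out of scope; parcels are opaque ids, as are the
measurement ROIs.

**Object patterns.** Each of the four objects has a prototype vector.
In *informative* parcels (default the first 3) prototype entries are
drawn i.i.d. `N(0, signal_sd^2)`; elsewhere they are zero, so only
informative parcels carry object information. The default
`signal_sd = 0.3` against unit-variance voxel noise was chosen so that
pairwise leave-one-run-out decoding lands near 0.8 and 4-way decoding
near 0.66 — the mid-range that object-decoding studies typically report.
This choice matters: with a much stronger signal the decoders saturate
at accuracy 1.0, and a saturated accuracy cannot decrease-or-increase
symmetrically, which degrades the integration index into a one-sided
quantity and invalidates sign-based inference. Keeping the decoders off
ceiling is a realism constraint, not a tuning knob.

**Runs.** A recognition run is 145 volumes at TR = 2 s with 48 trials
(12 per object, 3 per object per quarter, no identical back-to-back
objects, inter-trial intervals jittered uniformly over 4/6/8 s). The
hemodynamic lag is modelled as a pure 2-TR shift — the prototype is
injected into the single volume 4 s after onset, matching the analysis
rule that extracts the trial pattern 4 s after onset. No HRF
convolution: the analysis never looks anywhere else, so a spread
response would only lower effective SNR without changing any contrast.
Baseline signal is i.i.d. Gaussian noise per voxel (`noise_sd = 1`)
plus a slow one-cycle sinusoidal drift (`drift_amp = 0.5`, random
per-voxel phase); z-scoring makes the pipeline insensitive to the drift
scale, which is why the default noise model is deliberately simple. An
AR(1) option (`ar1_rho`) exists behind the config for temporally
correlated noise but is off by default.

**Integration.** Session-5 trained-axis prototypes are moved
symmetrically toward their midpoint:
`proto5(P) = proto1(P) + (lambda/2) (proto1(C) - proto1(P))` and
symmetrically for the competitor, so `lambda = 0` reproduces Session 1
exactly and `lambda = 1` collapses the pair; controls never move. This
is the simplest operationalisation of "the patterns became more
similar" with a clean endpoint at full collapse, and it makes the
Euclidean distance between the trained prototypes strictly
non-increasing in `lambda` (property-tested).

**The agent.** During feedback trials the simulated participant's
volumes carry `proto(presented) + a * proto(competitor)`, where the
ability `a` in [0, 1] follows a per-run curve (default a linear ramp
0.1 to 0.9 over the 30 feedback runs). The agent is deliberately
open-loop — ability is a schedule, not a learner — because the closed
loop under test is the *feedback engine*, not a model of human
learning.

**Behaviour.** Categorical-perception responses are Bernoulli draws
from a true logistic observer `p(x) = 1/(1 + exp(-slope (x - mu)))` on
the morph-percent axis (13 fixed steps from 18 to 82, 12 repetitions
each, trial-unique viewpoints). In the full study the Session-5
trained-axis slope is coupled to the participant's integration shift,
`slope5 = slope1 (1 - 0.7 lambda_i)`, with per-participant
`lambda_i ~ N(lambda, 0.15^2)` clamped to [0, 1]; that coupling is what
gives the brain–behaviour correlation something real to recover.

## The analysis pipeline

**Preprocessing.** Two z-scoring paths mirror the real-time/offline
split: the streaming path standardises each incoming volume against the
running mean and *sample* standard deviation of the prior TRs only
(Welford accumulator; the volume is absorbed after scoring, so the loop
is strictly causal), and the offline path standardises each voxel
against its full run. Both use an sd floor of 1e-6 with the score
forced to 0 when floored, so constant voxels yield zeros rather than
infinities; the first two volumes of a run score 0 and are never used
as trial patterns. "Prior TRs only" is a deliberate reading of the
real-time rule; including the current TR would make each score depend
on itself.

**Decoding.** Six pairwise L2-regularised logistic classifiers (one per
unordered object pair) are trained on Session-1 trial patterns.
`penalty = 1` is interpreted as the conventional inverse regularisation
strength `C = 1`. The fit is an in-package IRLS/Newton solver (ridge
objective, unpenalised intercept, backtracking line search, gradient
tolerance 1e-10); the ridge makes the objective strictly convex so the
fit is unique and deterministic even on separable patterns. Classifier
*output* is the graded probability in [0, 1] — a hard label could not
be thresholded by a staircase — and the two objects' evidences sum to 1
exactly. The activation level of a target object is the mean of the two
classifiers pitting it against each control; the direct
presented-vs-competitor classifier is never consulted, since its output
confounds "both active" with "neither active".

**Feedback engine.** Each 5-TR feedback trial starts at wobble level 13
and drops to 9/5/1 after 1/2/3+ TRs on which competitor evidence
exceeds the threshold; the trial ends with 0/0/5/10 cents (and
unhappy/neutral/smiling/laughing faces) for 0/1/2–3/4–5 above-threshold
TRs. The exact staircase schedule of the original procedure is not
publicly specified, so the package implements a dead-zone rule stated
in full: after each run, the threshold moves up by `step_up = 0.03` if
the mean above-threshold count per trial was at least 3, down by
`step_down = 0.05` if at most 1, else holds, clamped to [0.5, 0.95]
from `theta0 = 0.55`. All five constants are configurable; the defaults
were chosen once to reproduce the qualitative contract (poor runs ease
the task, strong runs create headroom) and are exercised by the
tracking tests. Within a feedback trial all five TRs are scored against
the concurrently z-scored volume; a within-trial hemodynamic lag is not
modelled, because whether the original real-time scoring lagged the
stimulus state is not stated.

**Feedback-run layout.** Only the run length (176 volumes) and the
5-TR trial length are fixed by the protocol; the number of trials per
run is not printed anywhere. The package uses 20 trials per run after a
4-TR lead-in (which also warms up the running statistics), with 2–3 TR
gaps — a layout that fills the 176 volumes at a realistic duty cycle.

**Feedback-ROI construction.** The full data-driven path is
implemented: a reference cohort (synthetic here, swappable for real
data) yields a per-parcel ranking by 4-way leave-one-run-out accuracy
averaged over subjects; nested top-N mega-ROIs are rescored to pick the
best N (smallest on ties); and each participant's ROI is refined by
greedy backward elimination on their Session-1 runs, keeping the best
set over all visited sizes including the start. Ties at an elimination
step are broken by removing the lowest parcel id, so replays are
deterministic. The 4-way classifier inside selection is one-vs-rest
logistic with the same ridge as the pair classifiers (the multiclass
scheme was not specified; one-vs-rest is the plainest reading).

**Integration indices.** Behavioural: Session-1 slope minus Session-5
slope per axis, the Session-5 fit holding `mu` at the Session-1
estimate (this halves the slope-estimate variance, which is the stated
reason for the convention; the variance reduction is itself
property-tested). "Slope" is the steepness coefficient `1/s`, so
integration (a shallower curve) is positive. Neural: Session-1
leave-one-run-out accuracy minus the accuracy of those same Session-1
fold classifiers on the Session-5 runs, per axis and ROI. The
cross-session score averages all 8 × 8 classifier-by-run accuracies;
the protocol description is ambiguous between this and a paired 8-fold
reading, and the 8 × 8 average is the lower-variance choice (a
`paired` mode is available).

**Where neural change is measured.** `run_study()` computes the
integration indices in a-priori *measurement* parcels (config
`measurement.parcels`; by default the generator's informative parcels,
standing in for anatomically defined regions), never in the greedily
selected feedback ROI. Selecting an ROI to maximise Session-1 accuracy
on the very runs that then define the Session-1 accuracy term would
bias the index positive by construction; the original design has the
same separation (a data-driven ROI drives feedback, anatomical ROIs
measure change).

**Group inference.** Effects are tested by participant-level bootstrap:
1,000 resamples of the cohort with replacement, the 2.5/97.5 percentile
band as the interval, and the p-value defined as the fraction of
resampled means with sign opposite to the observed mean — one-tailed as
literally defined, with no doubling. Under a symmetric null this p is
uniform on [0, 0.5] (its doubling is the usual two-sided p); the
calibration test checks exactly that law, and users should be aware
that thresholding it at 0.05 operates at a true two-sided level of
0.10. Session trends (threshold, competition index over the three
feedback sessions) are per-participant OLS slopes taken to the same
bootstrap. The brain–behaviour association is a Pearson correlation
with the standard t-transform p (a bootstrap-r option exists); no
multiple-comparison correction is applied across ROIs by default,
matching the original reporting.

## A known estimator bias, and why the untrained axis matters

The asymmetric fitting convention (free `mu` in Session 1, fixed noisy
`mu` in Session 5) carries a small positive bias in the null
behavioural index: the free fit's slope MLE is biased up (~+0.010 at
slope 0.2 with 12 trials/level) while fixing `mu` at a noisy estimate
biases the Session-5 slope down, leaving a null index mean near +0.006.
This is a property of the convention itself, isolated and frozen as a
test. Both axes share the bias identically, so the trained-minus-
untrained contrast cancels it — which is precisely the role of the
untrained control axis in the design. Consequently the package's null
end-to-end specificity check flags on the unbiased quantities (the
neural trained index and the trained-vs-untrained contrasts), and
readers of the raw trained-axis behavioural index should keep the
+0.006 offset in mind.

## Problem sizes and reproducibility

The default configuration reproduces the protocol composition exactly:
20 participants, Session 1 and Session 5 with 8 recognition runs each,
and three feedback sessions of 2 + 10 + 2 runs. The desk-scale voxel
space (10 × 12 voxels) and the reference cohort (3 subjects × 3 runs)
are the package's own choices, sized so a full default study runs in
minutes on one core; the validation studies in the test suite use 20
participants for recovery cohorts, 20 seeds for closed-loop trend sign
tests, 1,000 replicates for p-value calibration, and 20 scaled-down
end-to-end replicates (8 participants, 4 + 2 + 4 runs) for the null
specificity study. Every stochastic step derives its seed stably from
one master seed by hashing a stage label, so adding a stage never
perturbs earlier draws and identical `(config, seed)` pairs reproduce
bundles bit-identically.

## What the synthetic study does and does not establish

The generator emulates the *structure* of the experiment — trial
schedules, lagged single-volume patterns, parcel-limited information,
session-5 pattern shifts, a responder whose curve shallows with
integration, an agent whose competitor activation grows — with
Gaussian noise and a sinusoidal drift. It does not emulate motion,
physiological noise, spatial autocorrelation, HRF dynamics, learning
dynamics within the agent, lapses in the observer, or anatomical
structure. Passing tests therefore establish that the pipeline's
machinery is correct (oracle equivalences, determinism, causality),
calibrated (null specificity, p-value law), and able to recover known
effects at realistic SNR; they do not establish that the original
effect sizes or p-values would reproduce on real fMRI data, and the
headline statistics of the motivating study are explicitly outside
what a synthetic cohort can adjudicate.

## Degenerate inputs and edge rules

Constant voxels z-score to zero; fewer than two prior volumes score
zero; one-sided response sets are flagged non-identifiable with the
slope capped at 10 per morph-%; evidence ties at exactly the threshold
do not count as above; classifier score ties go to the alphabetically
first object; ranking and elimination ties resolve by parcel id;
all-zero effect vectors make the sign-based p undefined (flagged);
cohorts of fewer than three participants skip the correlation. Empty
parcels are excluded from ranking with a warning, and schedule
constraints are satisfied by rejection sampling with a 1,000-retry
budget (the constraints are always satisfiable, so exhaustion indicates
a misconfiguration).
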