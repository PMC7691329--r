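---
title: "Models and methods behind orientrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orientrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orientrack)
```

orientrack implements the quantitative workflow of head-fixed trackball
orienting experiments: a closed-loop two-alternative task, optogenetic
effect statistics, a calcium-trace pipeline, population decoding, spike
modulation, and pose analysis. This vignette explains the underlying
models, the parameters that matter, what the synthetic generators do and
do not emulate, and the design choices made where conventions diverge.

## The task model

A trial presents a lateralized cue; the animal answers by rotating a
trackball whose cumulative angle is tracked from cue onset at ~10 ms
resolution. One sign convention is declared once and drives everything
downstream: **positive angle is the rotation that moves a right-side
stimulus toward the screen center in the inward task**. For the left
analysis hemisphere (the package default, as in lateralized perturbation
experiments) the positive rotation is the contraversive action.

Outcome classification is purely cumulative: the first time the angle
reaches +15° or −15° within the 1 s response window ends the trial;
whether that is correct depends on the cue side and the contingency
(inward: right cue ⇒ positive is correct; outward swaps the rule). A
wrong-way excursion must be offset before the correct threshold can be
reached, exactly as in closed-loop stimulus coupling. No crossing within
the window is a timeout. Two structural consequences are tested as
invariants: swapping the contingency swaps correct and incorrect while
preserving timeouts and response times, and relabeling the hemisphere
swaps contra/ipsi labels without touching outcomes.

Parameters (with defaults) live in `task_config()`: threshold 15°,
response window 1 s, hold-still 1 s and inter-trial interval 2.5 s
(simulated as dead time, since no analysis uses them), ball calibration
0.15°/pixel, spontaneous threshold 5° with 2 s trials, laser window
0.3 s before to 1 s after cue onset. Laser trials are drawn uniformly at
random among all subsets with no two adjacent trials
(`laser_schedule()`); we draw directly from that set via the gap-offset
bijection rather than by rejection, which is exact and fast, and makes
the realized fraction equal the target up to rounding.

In spontaneous sessions both anti-bias rules run together: the
software-designated rewarded direction repeats after an unrewarded trial
and switches after a rewarded one. These two rules can be stated in ways
that conflict on edge cases; we resolve them as "switch after reward,
repeat otherwise", which the engine applies deterministically and the
tests trace rule-by-rule.

## Behavioral statistics

Rates respect their natural denominators: timeout rate over all trials
of a cue; incorrect rate over completed trials only (timeouts are
excluded from accuracy and analyzed separately). The laser-effect
indices are relative changes of paired rate sums; both the
contraversive-action pair (correct on contra-cued plus incorrect on
ipsi-cued — both being contraversive choices) and the right-stimulus
pair (correct on right-cue plus incorrect on left-cue) exclude timeouts
by construction. Ball velocity uses magnitudes of per-tick steps from
movement start (0.5° criterion) to threshold; direction handling is
unspecified in common usage, so we take the direction-agnostic mean.

The permutation test mirrors the experimental logic: under the null the
laser label is exchangeable within each animal, so each round reshuffles
labels per animal (preserving per-animal laser counts), pools all
animals' trials, and recomputes the pooled laser-minus-nonlaser change.
The observed effect is computed by the identical pooled path. The
two-tailed p counts null values at least as extreme on either side of
zero; centering at the null median would be the alternative, but zero is
the natural center for a difference statistic and matches the
"proportion at least as extreme" phrasing of standard practice. No +1
smoothing is applied, so p can be 0 at resolution `1/n_perm`; the
resolution is always reported. Cue-pair families are evaluated at the
Bonferroni level 0.05/2 = 0.025 (`bonferroni_alpha()`).

The p-values of rank tests come from `stats::wilcox.test` (exact for
small tie-free samples); the accompanying z is the tie-corrected normal
approximation, signed so positive z means the first sample is larger.
Zero paired differences are dropped, the classical signed-rank
convention.

`fisher_exact_two_sided()` uses the point-probability rule (sum of
same-margin tables whose hypergeometric probability does not exceed the
observed, with a 1e-7 relative tie tolerance) and accumulates in log
space; contrasts between strongly selective populations produce p-values
around 10⁻⁷⁰ and beyond, which would underflow a linear-space sum
long before they become unrepresentable as logs. The implementation is
cross-checked in the tests against an independent
binomial-coefficient enumeration and `stats::fisher.test`.

## The synthetic behavior generator

`agent_params()` defines a per-trial generative model: timeout with
probability `p_timeout`; otherwise a direction choice whose
cue-conditional correctness is `p_correct_right`/`p_correct_left`, with
laser trials adding `laser_delta_contra` to the probability of the
contraversive choice (clipped to [0, 1]; clips are counted). Response
times are log-normal, truncated to the response window, with defaults
targeting a ~0.4 s median — the middle of the range seen in trained
animals (roughly 0.26–0.57 s). Ball traces are synthesized as noisy
ramps consistent with the drawn outcome and response time; timeout
trials get sub-threshold wander. A `traces = FALSE` fast path draws
outcome-level trials from the same model for large calibration runs.

Because the model is explicit, the expected contraversive-action index
has a closed form (`expected_contra_action_delta()`): with symmetric
accuracy p and laser shift d it is `2d / (p + (1 − p))` before clipping.
The acceptance script injects d = +0.1 at p = 0.8 (expected index +0.20)
and recovers it from a simulated 20-mouse cohort.

What the generator does **not** emulate: learning and motivational
drifts across a session, sequential dependencies beyond the anti-bias
rule, lapses correlated with velocity, and any laser effect on timeout
probability or response time (the deltas for those metrics are null by
construction, which is what the calibration tests require).

## The calcium model and trace pipeline

`calcium_sim_params()` describes a linear-kernel indicator model at
5 Hz: each neuron has non-negative weights for cue side (impulse at
stimulus onset) and action direction (impulse at the response), convolved
with a difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s —
GCaMP6s-like). Measured soma fluorescence is

    soma_raw = baseline · (1 + signal) · drift + r · neuropil_raw + noise

with r = 0.7, so the standard correction `F = soma_raw − 0.7·neuropil_raw`
removes the contamination *by construction* — making the correction step
testable — and a mismatch can be introduced by changing either
coefficient independently. Drift is multiplicative: a linear component
(default 20% per 10 min), a slow sinusoid (amplitude 0.05, period 300 s
≥ 100 s so the 60 s envelope can track it), and a gentle random walk.

The pipeline follows the standard order: neuropil subtraction → F0 as
the highest-density fluorescence value → percent ΔF/F → drift removal →
z-scoring. Numerical choices:

* **F0 density mode**: Gaussian KDE with Silverman's bandwidth
  (`bw.nrd0`), 512-point grid spanning the 1st–99th percentile. ROIs
  with F0 ≤ 0 are flagged invalid and excluded downstream.
* **"Gaussian of 1 s width"** is read as σ = 1 s (not FWHM); it is a
  `gauss_width_s` argument.
* **Envelope windows**: centered min-then-max filters of exactly 60 s in
  frames (301 frames at 5 Hz, forced odd), constant edge handling.
* **Fixed-point refinement**: the envelope is estimated on the smoothed
  trace but subtracted from the unsmoothed one, which leaves quiet
  periods a fraction of a percent below zero after one pass; one
  further application of the same operator anchors quiet periods at
  zero and makes detrending idempotent in practice (the tests bound the
  second-application change below 1% RMS). The envelope method assumes
  activity returns near baseline somewhere within every 60 s window;
  with very dense transients the baseline is biased upward — a known
  limitation shared by all lower-envelope detrenders.

Trial tensors are aligned to stimulus onset (window −1 to +2 s) or to
the response (−0.2 to +0.4 s); completed trials carry one of four cue ×
action conditions, and sessions with fewer than 5 trials in any
condition are flagged excluded. Post-stimulus statistics use the 1 s
window mean; marginal condition means average the two constituent
condition means (so unequal trial counts cannot bias them), population
contrasts are paired signed-rank across neurons, and the per-neuron
action-difference test — whose form is a package default since field
practice varies — is a two-sided across-trial rank-sum at α = 0.05, with
an exact binomial CI on the significant fraction. The velocity median
split uses one shared per-session split point.

Bouton (axonal varicosity) analysis skips neuropil subtraction, tests
responsiveness by comparing 1 s pre-stimulus means against 0.6–1.2 s
post-stimulus means (signed-rank, p < 0.01), computes AUROC between
contra- and ipsi-stimulus responses with the contralateral condition as
positive class, maps it to the preference score `2·(AUROC − 0.5)`, and
calls a preference significant outside the central 95% of 1000
label-shuffles. The shuffle machinery is rank-based, hence invariant to
monotone transforms of the responses — a property test in the suite.

## Decoding

Features are per-ROI means over −0.2 to +0.4 s around the response;
no feature standardization is applied. The classifier is a linear
soft-margin SVM with C = 10⁻⁴ via e1071/LIBSVM. Per iteration, each
session contributes 5 trials per action label, drawn with right/left cue
composition as balanced as the session allows (5 is odd, so one cue
contributes 3 and the other 2, the assignment randomized); same-label
trials are randomly paired across sessions into pseudotrials whose
feature vectors concatenate all sessions' ROIs. Cross-validation is
stratified 10-fold over the 10 balanced pseudotrials (equivalent to
leave-one-out at this size; cross-validating over a larger pool would be
the alternative reading), and the final accuracy averages fold means
over iterations.

Chance is estimated exactly as the procedure prescribes: identical
pipeline with shuffled *test* labels, significance being an observed
mean outside the central 95% of the shuffled iteration means. Note that
evaluating source-shuffled labels against themselves instead would show
the classic leave-one-out anti-learning bias (accuracy systematically
below 0.5, because the held-out trial's class is always the training
minority); test-label shuffling is immune to it, which is presumably why
the original procedure uses it.

The within-session comparison subsamples unlabeled ROIs to the labeled
count anew each iteration and compares session-wise mean accuracies with
a paired signed-rank test. For the synthetic check of this comparison
the generator gives labeled neurons twice the action weights and is run
in a regime (action-weight SD 0.1, noise SD 0.05 at 60 neurons) where
single-session accuracies fall in the 0.6–0.95 range rather than at
ceiling, since at ceiling both populations saturate and the comparison
is uninformative.

## Spikes and pose

Spike analysis is deliberately simple: block firing rates over half-open
`[start, end)` intervals (boundary spikes counted once), condition means
as total spikes over total duration, and the laser modulation index
`(FR_l − FR_nl)/(FR_l + FR_nl)`, undefined (flagged, not modulated) when
both rates are zero. Which significance test lies behind "modulated" is
a package default: a two-sided rank-sum across block-wise rates at
α = 0.05. The laser-on epoch is taken to be the block interval itself;
an explicit epoch argument can restrict it. The generator inverts the
index — laser rate `r·(1+m)/(1−m)` for target index m — and draws
homogeneous Poisson counts per 6 s block with 1 s gaps and half the
blocks stimulated, which suffices for unbiasedness checks across
m ∈ {−0.8 … 0.8} but does not model bursting, adaptation, or
light-onset transients.

The pose transform is rigid per frame: translate the anchor (tail base,
or headplate when head-fixed) to the origin and rotate so the nose lies
on +y; positive x is then the animal's right, and the clip summary is
the mean x of both forepaws. Rigidity (distance preservation) and
equivariance to global rotations/translations of the input are tested to
1e-9. The generator sweeps a nose turn with laterally offset paws plus
coordinate noise; it does not emulate tracking dropouts beyond missing
parts (frames missing anchor or nose are skipped and logged) or
perspective distortion.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and runs under an
isolated RNG state (the caller's stream is untouched); R's default
generator is used rather than a counter-based one, which keeps results
reproducible across platforms within R without hand-rolling a generator.
Child seeds are derived arithmetically below 2³¹.

The shipped calibration sizes were chosen once as the smallest runs that
make the target tolerances statistically meaningful: 500 null cohorts of
6 mice × 300 trials at 200 permutations for type-I calibration (the
binomial CI of a 5% rate at 500 replicates is about ±2%), a 20-mouse ×
900-trial cohort for effect recovery within ±0.05, 200 neurons × ~20 min
at 5 Hz for the imaging round-trip, and 100 decoder iterations (the
iteration mean's SD is below 0.01 for the configurations tested). What
passing these synthetic checks shows is that the *estimators* are
correct and calibrated under the generative model; it does not certify
performance on real data, whose noise is not Gaussian, whose indicators
are nonlinear, and whose behavior is not stationary.
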