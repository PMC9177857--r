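---
title: "Models and methods behind olfrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olfrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfrl)
```

`olfrl` implements the computational chain of a three-odor go/no-go reward
conditioning paradigm in head-fixed mice: cue values learned by a
trial-based TD(0) rule, a pupillometric observation model that yields the
learning rate, lick-based behavior, tetrode spike analysis, and a
miniature event-related BOLD GLM. This vignette explains the models, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The task and the trial-sequence generator

A session presents three odors in equal proportion, rewarded with
probability 1.0 (CS100), 0.5 (CS50) and 0.0 (CS0); odor lasts 1 s, the
outcome arrives 2.7 s after odor onset, and inter-trial onsets are
jittered uniformly in 10–12 s (`task_config()`). Two run constraints
shape the pseudo-random order: no cue more than three times in a row, no
more than three consecutively rewarded trials.

The cue order is drawn position by position among the cues still
available (probability proportional to remaining count), excluding any
cue that would break the run limit; dead ends restart the draw. For
rewards, the obvious scheme — independent Bernoulli draws with the
offending draw resampled whenever a run would exceed the limit — has a
side effect worth understanding: because CS100 is *always* rewarded,
rewarded runs arise frequently and the resampling almost always lands on
a CS50 trial, forcing it unrewarded. Empirically this depresses the
realized CS50 reward frequency from 0.50 to about 0.41, which would in
turn drag the learned CS50 value well below the programmed probability.
Since the analyses (and the task's logic) treat 0.5 as the true CS50
rate, the default scheme (`reward_scheme = "balanced"`) instead assigns
each cue an exact reward quota (25 of 50 CS50 trials in a 150-trial
session) in random order and repairs any forbidden run by *moving* a
rewarded CS50 draw to a randomly chosen legal position, preserving the
marginal frequency exactly. Both schemes necessarily leave a local bias —
a CS50 trial immediately after a long rewarded streak is less likely
rewarded — but only the marginal matters for value convergence. The
literal resampling scheme remains available as
`reward_scheme = "resample"`.

## Trial-based TD(0)

Each trial has three timepoints: baseline (*t* = 0), odor (*t* = 1),
outcome (*t* = 2), with one baseline state, three cue states and one
outcome state whose value is pinned to 0 (the trial ends there). The
prediction error is δ~t~ = r~t~ + V(s~t~) − V(s~t−1~) and the previous
state's value moves by α·δ~t~. There is no discounting and no
eligibility trace; with values initialized in [0, 1] and α ∈ (0, 1) all
values remain in [0, 1] (a property the test suite checks over hundreds
of generated sessions).

One point is under-determined by the equations alone: within a trial,
should the *t* = 1 update be applied before computing δ~2~? Because δ~1~
updates the baseline state and δ~2~ updates the cue state, the two
updates touch disjoint values and the question is moot — `td_step()`
computes both errors from the values holding at trial start and applies
both updates; a `sequential_within_trial` flag makes the (numerically
identical) sequential order explicit.

Two initializations are supported: zeros, for learning simulations in
naive animals; and (0, 0.5, 1) for CS0/CS50/CS100, for building scanner
regressors from animals that are already trained. At α = 0.28 the values
averaged over the final third of 150-trial sessions reach the programmed
reward probabilities, while |δ| at the outcome decays to zero for CS100
and CS0 and stays near 0.5 for CS50 — the uncertainty that drives the
downstream surprise analyses.

## The pupil observation model and learning-rate estimation

Per-trial pupil dilation (percent change from the −2..0 s pre-odor
baseline) is summarized by three window means — d(0) over −2..0 s, d(1)
over 0..2.7 s, d(2) over 2.7..5.4 s — and modeled as
d(t) = Σ~τ=0..t~ a~τ~ V(s~t−τ~) + Σ~τ=0..t−1~ b~τ~ |δ(t−τ)|, evaluated
literally at the three timepoints (the sums are ragged at *t* < 2). The
free parameters are α (through the TD trace) and the five linear
coefficients.

Estimation choices, where the procedure was open:

* **Distance**: sum of squared errors over *per-trial* window means.
  Per-trial (rather than per-cue-type-average) fitting retains the
  outcome-history variability that identifies α; a per-type-average mode
  would discard most of it.
* **Optimizer**: for fixed α the model is linear in (a, b), so the inner
  fit is an exact least-squares solve; the outer 1-D problem in α uses a
  grid (0.02–0.98, step 0.02) followed by golden-section refinement to
  1e-6. With an exact inner solve and a dense grid, random multi-starts
  add nothing.
* **Aggregation**: α is estimated per session and averaged (a joint fit
  with one shared α is available via `joint = TRUE`).
* **Exclusions**: trials flagged by preprocessing (any frame-to-frame
  change above 5%, e.g. blinks; windows outside the trace) are omitted
  from the loss, not imputed.
* **Identifiability**: with no value/error signal in the pupil the loss
  is flat in α; the fit flags such sessions rather than reporting an
  arbitrary α.

Parameter-recovery simulations (20 replicates per α* ∈ {0.1, 0.3, 0.5},
single 150-trial sessions, window noise SD 0.5%) recover α within ±0.05
on average.

The synthetic pupil trace is rendered at 20 samples/s (the video frame
rate) by holding each window's target value across its interval, so that
window means recomputed from the trace reproduce the model values
exactly; smoother interpolation would look prettier but break that exact
round trip, which the tests rely on.

## Licking behavior

A go-response is ≥3 licks in the anticipatory window (1.5–2.8 s) *or* ≥3
licks in the reward window (2.8–4.1 s) — the windows are scored
separately, not pooled, reading the criterion's "or" disjunctively.
CS100/CS50 are go cues (Hit/Miss), CS0 is no-go (False alarm / Correct
rejection); performance is the percent of Hits plus Correct rejections,
with 80% the inclusion criterion.

The outcome-history regression models the CS50 anticipatory lick count
with a log-link Poisson GLM on the ±1-coded outcomes of the six previous
CS50 trials (cue-specific history) or six previous CS100/CS0 trials
(satiety). Choices: trials lacking a complete 6-back history are dropped
(no partial designs); an intercept is included because counts have a
nonzero baseline (disable with `intercept = FALSE`); no exposure offset,
since the count window has constant length; the standardization divides
each coefficient by σ(counts) — fitted means give near-identical scaling
— before the `exp(β*) − 1` transform.

The synthetic agent licks as an inhomogeneous Poisson process: baseline
rate 0.2 Hz throughout, an anticipatory rate `base + 10·V(CS) + history −
satiety` Hz during 1.0–2.8 s (history: ±1 Hz by the previous CS50
outcome, on CS50 trials; satiety: −0.5 Hz after any rewarded trial), and
an 8 Hz consumption burst on rewarded trials. These defaults give session
performance around 90–96%, comfortably above the criterion, with realistic
misses on low-value CS50 trials. Note one consequence of driving the
agent with TD values: V(CS50) itself integrates many past outcomes with
geometrically decaying weights, so the regression on such data shows
effects beyond lag 1 — just as real mice do. The pure "planted 1-back"
recovery simulations therefore freeze the values (α ≈ 0, trained
initialization) so that only the explicit 1-back term remains.

## Spike detection and unit QC

The preprocessing chain is median subtraction across the channels of a
recording site, a zero-phase 4th-order Butterworth band-pass (300–5000 Hz
at 30 kHz), and detection of local maxima of the absolute filtered signal
above 7.5× the median absolute deviation, with a 1 ms minimum peak
distance and cross-channel duplicates within a tetrode collapsed to the
highest peak. Choices: the MAD is *raw* (not scaled by 1.4826), per
channel; polarity is absolute by default (`polarity = "neg"` restricts to
negative-going peaks); zero-phase filtering preserves spike timestamps.

A caveat the simulations exposed: when the site median is computed over
only a handful of channels, it tracks the bulk of the noise but not its
tails, so the MAD (a bulk statistic) underestimates the tail scale and
the detector's false-positive rate rises above the Gaussian expectation.
With a realistic site size (16+ channels) the effect vanishes; detection
on synthetic 16-channel fixtures at 10× MAD amplitude achieves recall and
precision ≥ 0.95 at ±0.5 ms matching.

Units are kept when refractory violations (ISIs < 2 ms) are below 2% of
spikes and the baseline rate is below the region cutoff — 5 Hz in the
olfactory tubercle (putative striatal projection neurons), 10 Hz in
anterior piriform cortex (putative principal cells).

## Population vectors

Firing rates are binned (counts divided by bin width, in Hz) in sliding
windows — 500 ms stepped by 125 ms for display, non-overlapping 250 ms
bins for statistics — and concatenated across sessions by matching cue,
trial order and, for CS50, outcome, truncating supernumerary CS50 trials
from the end to the cross-session minimum. Consecutive trials are
averaged in pairs (an odd trailing trial is dropped) before computing the
Euclidean distance to the baseline vector (each unit's mean rate in
−2..−1.25 s, computed on the raw, un-paired trials) and the mean Pearson
correlation between population vectors of different cue types. Population
trajectories time-embed the trial-averaged unit × time matrix (m = 4
delayed coordinates, one-bin delay) and project onto principal components
fitted *jointly* across cue types, so trajectories share axes and are
visually comparable.

## auROC profiles, clustering and the coding tests

Each unit's response profile is the sliding-window auROC (500 ms / 125 ms
steps; midrank tie handling) of its rate distribution against its pooled
baseline distribution (−1.8..−1.4 s, all trials), concatenated over the
four conditions CS0, unrewarded CS50, rewarded CS50, CS100. Units are
clustered by average-linkage agglomeration on Euclidean distances between
their first five principal-component scores. The tree is cut at a
*fraction of the maximum merge height* (default 0.5; an absolute-height
mode exists) — the study's absolute cutoffs are not recoverable without
its exact profile scale. Flat clusters are then mapped to functional
groups by threshold rules on the cluster-mean profile (strong-value
conditions): predominantly below 0.5 across the task window → inhibited;
elevated late wait that rises across the wait → ramping; elevated at CS
with the wait back near baseline → transient; otherwise sustained. One
honest limitation: on a *homogeneous* population the PC space contains
only noise and a fractional cut is scale-invariant, so the number of flat
clusters is noise-driven at any cutoff; the functional grouping, not the
flat-cluster count, is the stable output, and the tests assert exactly
that.

The coding tests follow the stated criteria: monotonic reward-probability
coding requires both adjacent two-sided rank-sum comparisons (R0 vs R50,
R50 vs R100) significant at 0.05 with correctly ordered locations
(reversed for inhibited clusters), falling back to cue dominance
(strongest vs second-strongest response); reward surprise requires a
positive mean rate jump on rewarded CS50 trials that exceeds the CS100
jump, in either the short- (2.7–3.2 s) or long-latency (3.2–4.5 s)
window, with the prior-rate window at 2.2–2.7 s; outcome discrimination
is the one-directional rewarded-vs-unrewarded CS50 comparison; the
chance count for any strict three-cue ordering among units that
discriminate all cue pairs is the discriminative count divided by 3! = 6.
Responsiveness screening compares each task window against baseline with
a Friedman test over per-trial paired blocks — with two conditions this
degenerates to a sign-type test, so an exact Wilcoxon signed-rank
alternative is provided (`method = "signed-rank"`) — followed by
Benjamini–Hochberg correction across units × cues × windows. History and
satiety effects on CS50 responses use a one-way ANOVA across the four
annotated subgroups (previous CS50 rewarded / unrewarded; preceding trial
CS100 / CS0) with Tukey contrasts for the history and satiety pairs.

## The synthetic spiking population

Units mix four archetypes (defaults: 40% transient, 30% ramping, 20%
inhibited, 10% sustained) around a 3 Hz baseline with ±30% unit jitter
(below the 5 Hz QC cutoff). Transient units respond during the odor,
either monotonically in value or dominated by one cue; dominant-cue
preferences are assigned by *quota* in proportion (0.5, 0.3, 0.2) for
(CS100, CS50, CS0) rather than by independent draws, so that the
dominant subpopulation is monotonic in aggregate by construction — with a
few dozen units, i.i.d. preference draws would scramble that ordering in
a substantial fraction of simulated experiments, which is a property of
small-sample multinomials, not of the circuit being emulated. Ramping
units climb linearly through the wait in proportion to cue value, with an
additive ±1.5 Hz modulation by the previous CS50 outcome (the history
signal); inhibited units drop to 30% of baseline during the task window;
excited archetypes respond to delivered rewards with amplitude
`8·(1.2 − V)` Hz, making the unexpected CS50 reward the strongest response
(surprise), inverted for inhibited units. Spike trains are inhomogeneous
Poisson with piecewise-constant rates; the ramp is a four-step staircase.
The generator emulates rate structure only — no refractoriness, bursting,
correlated noise, drift or waveform variability — so passing tests
demonstrate the correctness of the analysis chain on data satisfying its
assumptions, not robustness to every pathology of real recordings.

## The BOLD phantom and GLM engine

Events are zero-duration sticks convolved in continuous time with a
unit-peak gamma kernel (default time-to-peak 1.0 s, reflecting the much
faster rodent hemodynamics; the exact empirical rodent kernel is not
published in a reusable form, so generator and fitter share this
parametric kernel and all checks are self-consistent) and sampled at the
volume grid (TR 1.3 s), which handles acquisition-unaligned onsets
naturally. The three design variants follow the study: a single CS
regressor with a V(CS) parametric modulator plus four outcome-type
regressors; separate cue regressors with a previous-CS50-outcome
modulator; and a single US regressor with the two *non-orthogonalized*
modulators −V(CS) and binary r, so each modulator's effect is adjusted
for the other and their entry order is irrelevant. Modulators are
mean-centered over their events; lick events (HRF-convolved), a CSF
nuisance series and a constant complete every design. Estimation is
ordinary least squares per voxel without prewhitening (the phantom's
AR(1) coefficient, default 0.3, is mild; inference rides on the
between-session level). Group statistics are voxel-wise one-sample *t*
tests across sessions — a deliberate simplification of the sandwich
estimator used for the repeated-measures structure of the original data —
thresholded per tail with Benjamini–Hochberg at q = 0.025. Percent signal
change scales event betas by the kernel peak and the *region-mean*
constant-term beta, compensating the lower absolute intensities of
ventral structures under a surface coil. Frame-wise displacement is the
sum of absolute first differences of the six realignment parameters, and
an event is low-motion when the frames at and after it are at or below
0.05 mm. Beta-series connectivity correlates per-trial betas between
regions for one event type, Fisher-z-transforms, tests the session z's
against zero (Bonferroni across pairs, or per-tail FDR in voxel mode) and
reports tanh of the mean z as the group correlation. The phantom is a
small labeled grid (default 24×24×4; tests use smaller) with abstract
slab regions, not anatomy.

## Problem sizes and runtime

The test suite runs everything at desk scale: populations of 40–100 units
over one or two 150-trial sessions, pupil recovery with 20 replicates per
generative learning rate, 10,000 generated sequences for the task-contract
checks, 100-session recovery runs for the history regression, and BOLD
phantoms of a few hundred voxels over ~250 volumes — sizes chosen so the
full suite completes in a few minutes on one CPU while keeping every
statistical conclusion stable under its fixed seed.

## Known limitations

* The reward-run repair preserves marginal but not local reward
  statistics; analyses sensitive to the conditional structure of reward
  sequences should use `reward_scheme = "resample"` and accept the
  marginal bias it implies.
* The Friedman-based responsiveness screen with two paired conditions is
  a sign-type test and discards magnitude information; the signed-rank
  mode is stricter.
* The hierarchical-clustering cutoff is expressed relative to the data's
  own merge-height scale; cluster *counts* are therefore not comparable
  across datasets, only the functional groupings.
* OLS without prewhitening leaves session-level test statistics mildly
  optimistic under autocorrelated noise; group-level inference, which the
  package reports, is unaffected under the null.
* The one-sample group *t* ignores repeated measures per animal; with
  several sessions per subject its effective sample size is optimistic.
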