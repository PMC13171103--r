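---
title: "Models and methods behind setshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind setshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setshift)
```

# Scope

`setshift` re-implements, as a tested and reusable pipeline, a family of
analyses of medial prefrontal cortex (mPFC) population calcium activity
recorded while mice perform attentional set-shifting: single-neuron ROC
tuning classification, bootstrap PCA state-trajectory geometry, two-state
hidden-Markov-model (HMM) decoding of behavioral states, and logistic
decoding of trial outcomes. Because the recordings such analyses were
developed on are not publicly deposited, the package also contains a
first-class synthetic-session generator that emulates the statistical
structure those analyses assume — planted single-neuron tuning, a latent
early/late behavioral switch, calcium-kernel dynamics at 20 Hz, and
group-level effects mimicking chemogenetic locus coeruleus (LC) inhibition —
so that every stage runs, and can be validated against recoverable ground
truth, with no external data.

# The behavioral model

A session is one extra-dimensional shift (EDS) stage: the animal must switch
its attention from a previously relevant perceptual dimension (digging
medium) to a newly relevant one (odor). The generator draws a latent switch
trial `s` (geometric beyond a minimum index, or fixed), emits
Bernoulli(`p_correct_early`) outcomes before `s`, and all-correct outcomes
from `s` on, extending the sequence until the stage criterion could be
declared: six consecutive correct trials with at least two correct
rejections accumulated. Three structural conventions matter:

* **The last error defines the switch.** The trial immediately before `s` is
  always incorrect, so the behavioral switch point recovered by
  `label_states()` (start of the terminal consecutive-correct run) equals
  the planted index exactly. Without this, a lucky run of early correct
  trials would merge into the terminal run and planted truth would disagree
  with the behavioral labeling.
* **Resampling of degenerate sequences.** Sequences with a premature run of
  six correct trials (the stage would have ended), fewer than two incorrect
  trials (contrasts would be one-class), more trials than the balancing
  target of 31, or a terminal run shorter than 22% of a long session (the
  late state would be a sliver after balancing) are redrawn. The
  `min_switch_index` default of 7 guarantees at least six distinct early
  trials.
* **Trials-to-criterion counts all trials** including the criterion run,
  and correct rejections accumulate across the stage; whether rejections
  must fall inside the run is not specified by the task description we
  follow, and the cumulative reading is used.

Group defaults set expected session lengths of roughly 15 (control) and 24
(test) trials, in the range reported for EDS under these conditions.

# The calcium-trace model

Each neuron's trace at 20 Hz is i.i.d. Gaussian baseline noise
(`noise_sd`, default 1 z) plus event-locked drives convolved with a
difference-of-exponentials kernel `exp(-t/0.5) - exp(-t/0.1)` (GCaMP6f-like
rise 0.1 s, decay 0.5 s). A drive is a constant-rate boxcar spanning the
5 s before each choice — the window every analysis consumes — rather than a
ramp; window means of a boxcar are easy to reason about and no single-trial
response shape is claimed for real mPFC. For synthesis the kernel is scaled
to unit sum so that a sustained drive of amplitude `a` plateaus at `a`
z-units; a unit-peak normalization would inflate a boxcar ~15-fold at this
sampling rate and destroy the z-unit meaning of `effect_size`.

Per neuron, tuning is planted for three task variables: *choice* (drive on
trials whose upcoming outcome is correct), *history* (drive on trials
following a correct trial; trial 1 carries none), and *switch* (drive on
late-state trials). Exactly `round(f * N)` neurons are tuned per variable,
selected by rank-thresholding correlated Gaussian copula scores whose
common-factor loading (`mixed_tuning_rate`) raises co-tuning (mixed
selectivity) without changing the marginal counts. Fixed counts rather than
Bernoulli draws make fraction-recovery tests meaningful: the planted value
is exact, so deviations measure the classifier, not the coin.

Two further choices shape realism:

* **Shared trial-to-trial drive fluctuations.** Each variable's drive
  amplitude carries a zero-mean Gaussian fluctuation per trial
  (`drive_noise_sd`), shared by all neurons tuned to that variable. Purely
  i.i.d. noise would make 5 s window means nearly noise-free
  (sd ~0.1 z), and both population decoders would saturate at accuracy 1.0;
  shared fluctuations are the standard account of cortical trial-to-trial
  covariability and set a realistic decoding ceiling while leaving
  single-neuron tuning recoverable.
* **A small neural lead.** The switch drive turns on at half amplitude
  `neural_lead` trials before the behavioral switch (rule acquisition
  precedes the criterion run).

## Planted group effects

The test group (LC inhibition) differs from control in four planted ways,
each matching the direction of the condition it emulates: larger tuned
fractions per variable ((0.17, 0.13, 0.25) vs (0.10, 0.06, 0.17) for choice,
history, switch); a smaller early/late population mean shift
(`separation_scale` 0.3 vs 1.0; switch-tuned late amplitude is
`effect_size + 2 * separation_scale` z); noisier drives
((1.5, 1.5, 1.5) vs (0.5, 0.4, 1.5) z), the counterpart of "elevated noisy
activity" under LC inhibition; and a larger neural lead (3 vs 1 trials).
With these defaults the decoders land near the magnitudes reported for such
data (HMM state accuracy ~0.93 vs ~0.82, choice decoding ~0.93 vs ~0.85)
without being fitted to them.

One direction deliberately *not* planted at the population-geometry level:
after per-neuron z-scoring, a neuron's amplitude is normalized by its own
variance, so the separation seen by trajectory distances saturates in
`effect_size`, and the test group's broader tuning (more switch-tuned
neurons) raises its population separation by almost exactly as much as its
reduced amplitude lowers it. The group contrast in trajectory distance
reported for the real recordings therefore reflects biology this
generator's licensed knobs cannot reproduce while keeping
`tuning_fractions(test) >= control`; the package tests monotonicity of
distance in `separation_scale` within group instead.

# Preprocessing

Traces are z-scored per neuron across the whole session (sample sd,
denominator `n - 1`); zero-variance neurons are an error, not a silent
drop. Event-aligned tensors use half-open 50 ms bins `[t, t + 0.05)` in
choice-relative time with edges shared across trials; trailing partial bins
are dropped. Calcium-transient metrics use a hysteresis detector (onset
above 2 z, offset below 0.5 z, merged within one supra-offset excursion);
amplitude is the event maximum and duration the time above half that
maximum — the metrics are standard, the detector itself is an artifact
choice since none is specified for the analyses we follow, and supra-
threshold time would be a defensible alternative to full-width at half
maximum.

# Single-neuron tuning

For each neuron the three contrasts compare 5 s pre-choice window means:
early vs late (switch), previous-trial correct vs incorrect (history,
trial 1 dropped), and upcoming correct vs incorrect (choice, all trials).
Discrimination is the ROC AUC computed by the rank formula (identical to
pair counting, ties counted half). Significance is a two-sided
label-permutation test on `|AUC - 0.5|` with add-one correction,
`p = (1 + #{permuted >= observed}) / (n_perm + 1)`, default 1000
permutations; the permutation null was chosen because the original
description states only "significant (p < 0.05) in the ROC analysis". No
multiple-testing correction is applied across neurons or contrasts —
responsive fractions are reported at raw alpha, as is conventional for this
figure type — and a contrast with fewer than two trials in a class is
marked unclassifiable rather than erroring the session.

Two properties of this design deserve emphasis. First, the three label
vectors are correlated by construction (late trials are all correct), so a
strongly switch-tuned neuron often reaches significance on the choice
contrast too: mixed selectivity partially *emerges* from the task
structure, as the original analyses themselves note ("the two measurements
of behavior ... are not completely orthogonal"). Second, as a consequence,
detected per-variable fractions are upward-biased relative to planted
fractions by both alpha-level false positives (~`0.05 * (1 - f)`) and this
contamination; recovery tests that compare detected to planted under a
binomial interval are run at a pooled size (2 sessions of 60 neurons per
group) where the interval accommodates the alpha-level bias, and cells
dominated by contamination are expected to exceed it — that excess measures
a real property of correlated contrasts, not an implementation defect.

# State-trajectory geometry

Per state (early/late), activity is trial-averaged in 50 ms bins over the
ten seconds centered on choice, per session, then neurons are stacked
across sessions on the common choice-relative grid. Trajectories are
smoothed per neuron with a Gaussian kernel (sigma 150 ms, truncated at
3 sigma, edge-renormalized). Each bootstrap iteration samples
`floor(0.8 N)` neurons without replacement (20 iterations by default); PCA
is fitted jointly on the row-concatenation of both states' trajectories —
so distances live in a single space — and both are projected on the leading
6 components, which on default synthetic data explain well over 80% of
variance. Separation is the per-bin Euclidean norm across retained PCs,
summarized by its mean and peak over bins with centers in the open
pre-choice interval (-5, 0) s; similarity is the unweighted mean over
retained PCs of the Pearson correlation between the two states' per-PC
time series, excluding zero-variance series.

# HMM state decoding

Per-trial features are the 5 s pre-choice window means per neuron (the
50 ms segmentation followed by averaging collapses to this scalar), reduced
by PCA across trials to 3 components — matching the choice decoder's "first
three principal components", since the dimensionality for the HMM is
otherwise unstated. The decoder is a 2-state Gaussian HMM with diagonal
covariance, variance floor 1e-6, fitted by Baum-Welch with scaled
forward-backward recursions (per-row log-density shifting; no underflow at
any practical sequence length), stopping at a log-likelihood gain below
1e-4 or 100 iterations. Decoding is exact Viterbi in log space with ties
broken toward the lower state index.

The bootstrap protocol per iteration: sample 40% of neurons; balance the
trial count to 31 by drawing extra trial indices with replacement and
inserting each duplicate adjacent to its source (naive resampling would
destroy the single-switch transition structure); refit PCA; initialize with
K-means (Lloyd, 10 restarts, best within-cluster sum of squares) *and* with
the best contiguous changepoint split, run EM from both and keep the
higher-likelihood fit — the usual guard against EM local optima, which here
tend to latch onto the outcome axis; fit on a random 90% of trials passed
to EM in chronological order; Viterbi-decode the full sequence so held-out
trials keep temporal context; map hidden states to early/late by majority
overlap with behavioral labels on the training trials (ties and absent
states map to early); and score accuracy on the held-out 10% and on all
trials, plus the switch-point error `delta_switch` = start of the terminal
predicted-late run minus the behavioral switch point. Iterations whose
path has no terminal late run are recorded invalid and excluded from
summaries, with the failure rate reported rather than hidden — under weak
signal this failure mode is common and is itself informative.

The terminal-run estimator is asymmetrically sensitive to noise: a flipped
trial inside the late block pushes the estimated switch later (positive
error), while flipped early trials rarely connect to the terminal run. Mean
`delta_switch` is therefore positively biased under symmetric decoding
noise, and summaries use the median as the robust per-session statistic.

# Choice decoding

An L2-penalized logistic regression (penalty 1e-3 on non-intercept weights,
Newton/IRLS, gradient tolerance 1e-8) predicts each trial's outcome from
the first three PCs of the pre-choice means, under the same
neuron-subsampling and trial-balancing bootstrap, with a 90/10 split
stratified by outcome (the original protocol does not state stratification;
unstratified splits frequently produce one-class held-out sets at these
trial counts). The penalty guarantees existence and uniqueness on separable
bootstrap samples, where an unpenalized fit diverges. Probabilities above
0.5 map to "correct"; an exact 0.5 maps to "incorrect" — a zero-measure
case fixed for determinism.

# Group statistics and the pipeline

`compare_groups()` follows the source decision rule: two-tailed Wilcoxon
rank-sum (normal approximation with tie correction, reporting the first
sample's rank sum) when both samples exceed 7, otherwise a pooled-variance
two-sample t-test; the rule keys on `min(n1, n2)` since the original is
ambiguous for mixed sizes, and the normal approximation suffices because
small samples route to the t-test anyway. Chi-squared comparisons of
responsive fractions are Pearson tests on 2x2 tables, df 1, no continuity
correction.

`run_pipeline()` chains everything over a simulated two-group cohort and
writes a single deterministic `report.json`: per-session seeds derive from
the master seed, and no timestamps enter the report, so identical
configurations are byte-identical on disk (stage timing goes to optional
console logging). The desk-scale default — 4 sessions per group, 60 neurons
per session, 200 bootstrap iterations per decoder, 1000 permutations —
completes in well under a minute; the full-protocol setting of 1000
iterations is a parameter, not a different code path.

# Problem sizes used by the test suite

Validation runs at sizes chosen to keep the full suite interactive while
leaving comfortable statistical margins: exhaustive Viterbi checks at
sequence lengths up to 10 against all `2^T` paths; EM monotonicity on 100
random datasets; permutation-test calibration on 1000 planted-null neurons —
on a trial scaffold with balanced state classes (15 early / 16 late),
because at task-criterion trial counts (~6 late trials) the discrete
two-sided permutation null cannot resolve the 0.05 quantile and the test is
conservative by construction (measured type-I ~0.03-0.04 there), so
calibration is checked where the null has enough support; planted-tuning
recovery on 4 control sessions of 60 neurons at 1000
permutations; fraction recovery on 2 sessions per group (with the
chi-squared group-difference detection on 4, where the test has power); geometry
monotonicity over 5 separation levels times 20 seeds (Spearman over level
means); and decoder group-direction consistency over 50 master seeds of
3-session cohorts at 200 bootstrap iterations.

# Known limitations

The generator does not emulate: single-trial response shapes beyond the
boxcar-kernel convolution; pre-EDS task stages beyond stage labels;
video-derived behavior; spike-to-fluorescence biophysics; or
non-stationarities such as photobleaching and drift. Passing tests
therefore demonstrate correctness of the analysis pipeline and
recoverability of planted structure under the stated statistical model —
they do not certify that real mPFC data satisfy that model. The
bootstrap-iteration sampling units ("n = 20 bootstraps") mirror the source
analyses and are pseudo-replicates; p-values computed over them are
reported as such and should be read accordingly.
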