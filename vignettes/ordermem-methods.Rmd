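---
title: "Models and methods behind ordermem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ordermem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ordermem analyses population spiking activity recorded while a subject
watches a short episode (an 8-s video) and then judges which of two probe
frames came earlier — a temporal order judgment (TOJ). The package asks,
with a fully synthetic and therefore fully testable substrate, the
questions this paradigm is designed to answer: do single neurons carry an
onset-anchored, decaying trace of elapsed time (temporal context cells)?
Is elapsed time decodable from the ensemble? Does spike timing coordinate
before a correct decision? And does the retrieval-period population state
reinstate the encoding-period state on correct trials?

This vignette records the models, the tunable parameters, and the design
choices made where the design was genuinely open. Everything quantitative
claimed here is computed by the test suite or by `scripts/acceptance.R`;
nothing is asserted from memory.

## Time conventions

All spike and event times are trial-relative seconds, zero at trial start,
and every interval is half-open `[start, end)`. A trial consists of a 1-s
pretrial fixation, the 8-s encoding video, a retention delay of 0 s
(immediate) or 3.6 s (delayed), the TOJ period from probe onset to the
behavioural response, 4 s of feedback, and a 1-s inter-trial interval.
Reaction times above 10 s are excluded from behavioural analyses.

## Temporal context cells: nested rate models

Encoding-period firing of each unit is summarized as 50-ms binned counts
summed across trials, and three nested rate models are fit by maximizing
the Poisson likelihood:

* constant: $r(t) = a_0$;
* Gaussian: $r(t) = a_0 + a_1 e^{-(t-\mu)^2 / 2\sigma^2}$;
* ex-Gaussian: $r(t) = a_0 + a_1\,g(t;\mu,\sigma,\tau)$, where $g$ is the
  density of a Gaussian$(\mu,\sigma)$ convolved with an exponential decay
  of time constant $\tau$, rescaled so its peak equals 1.

Both nonlinear models use the *peak parametrization*: $a_1$ is the rate
change at the extremum in Hz, so the amplitude criteria below act on a
physically meaningful scale and — more importantly — the Gaussian is
*exactly* the $\tau \to 0$ limit of the ex-Gaussian over the same
parameter box. The implementation includes that limit in the family
(values $\tau \le 10^{-6}$ evaluate the Gaussian branch, and the box
reaches $\tau = 0$), so the maximized log-likelihoods are provably nested:
constant $\le$ Gaussian $\le$ ex-Gaussian, up to optimizer tolerance. The
ex-Gaussian density is evaluated in log space; both degenerate regimes
(small $\tau$: Gaussian-like; small $\sigma$: pure exponential from
$\mu$) are numerically stable.

Bounds are $\mu \in [0, 2]$ s, $\sigma \in (0.01, 2]$ s,
$\tau \in [0, 20]$ s, $|a_1| \le 100$ Hz. Optimization is bounded
quasi-Newton (L-BFGS-B) from 10 random starts plus two data-driven starts
and one start at the best nested solution.

A unit is classified as a temporal context cell when

1. the ex-Gaussian beats the Gaussian (df 1) **and** the constant (df 4)
   model at the 0.05 level by likelihood-ratio tests,
2. the fitted curve changes by at least 2 Hz from baseline, and
3. the fitted curve reaches at least 4 Hz.

The amplitude criteria are evaluated on the fitted curve rather than raw
PSTH bins, to avoid bin-noise sensitivity. The *relaxation time* is the
interval from the fitted curve's extremum to its first 63 %
($1 - 1/e$) return toward baseline, found by root bisection; for a pure
exponential this equals $\tau$ exactly. Curves that have not decayed
within 20 s are censored at 20 s.

**A calibration caveat.** Under a constant-rate null, the shape
parameters $(\mu, \sigma, \tau)$ are unidentified whenever $a_1 = 0$, so
likelihood-ratio statistics against the constant model are not
$\chi^2_4$-distributed (the classical unidentified-nuisance problem); a
thorough multi-start optimizer makes this test anticonservative. The
sequential comparison that actually gates classification — ex-Gaussian
against Gaussian, df 1 — is close to nominal (measured rejection at the
0.05 level is about 0.06–0.07 on 250 null units), and the two amplitude
criteria further suppress false positives, which is why the classifier's
null TOJ/TCC rates stay low even though the df-4 statistic runs hot. The
acceptance suite calibrates the df-1 test.

## Task GLMs

Each unit is modeled independently with a Poisson GLM on one observation
per (trial × epoch), with the epoch duration entering as a log offset.
Epoch indicators (encoding, delay, TOJ, feedback, ITI; pretrial fixation
is the reference) are mutually exclusive within a row; trial-level
covariates (block, reaction time, outcome, condition, response side) are
repeated across the trial's rows. The TOJ epoch can be decomposed into a
visual window (0–200 ms after probe onset), a retrieval/comparison window
(200 ms after onset to 200 ms before response), and a motor window (last
200 ms); trials with RT ≤ 0.4 s lose the retrieval row with a warning.

Model search is forward–backward on *adjusted McFadden pseudo-$R^2$*,
$1 - (\ell_{\text{full}} - k)/\ell_{\text{null}}$ with $k$ the number of
non-intercept terms: a candidate is added when its gain exceeds 0.01 and a
retained term is dropped when its removal costs less than 0.005. A unit is
a TOJ cell when a TOJ-related regressor is retained with Wald $p < 0.05$
in the final model. The eye-movement control model appends four
oculomotor regressors (saccade frequency, fixation frequency, scan-path
length, fixation duration, computed over the TOJ period); the *strict*
TOJ criterion additionally requires that none of them is retained.

Mixed-effects summaries (reaction time against condition and outcome, and
the video-half control below) are thin contracts over `lmerTest::lmer`
with a per-subject random intercept, degrading to `lm` for a single
subject.

## Spike-train synchrony

Pairwise synchrony uses the time-resolved SPIKE-distance. At each grid
time $t$ each train contributes its preceding and following (corner)
spikes, the latencies $x_P, x_F$, the local interval $x_{ISI}$, and the
offsets $\Delta t_P, \Delta t_F$ from its corner spikes to the nearest
spike of the other train; the per-train term is
$S_n = (\Delta t_P x_F + \Delta t_F x_P)/x_{ISI}$ and the profile is
$S = (S_1 x_{ISI,2} + S_2 x_{ISI,1}) / (2 \langle x_{ISI}\rangle^2)$.
Auxiliary spikes at both window edges (the metric's standard edge
convention) keep the profile defined for sparse trains; the sampling grid
is 1 ms by default and time averages use the trapezoid rule. The profile
is zero for identical trains, bounded by 1, symmetric, and
translation-invariant; the test suite checks it against an independent
loop-based evaluator of the same formula at 10^-9 tolerance.

Group contrasts (correct vs incorrect, immediate vs delayed) use per-bin
t statistics against a permutation null (1,000 relabelings; sign-flips of
session-level differences in the default paired-across-sessions mode),
with Benjamini–Hochberg correction at q < 0.01. P-values use the add-one
convention, so the smallest attainable p is $1/(n_{perm}+1)$.

## Decoding elapsed time

The 8-s encoding period is divided into 32 bins of 250 ms, giving a
trial × bin × neuron rate tensor. A Gaussian linear discriminant with
per-class (bin) means, pooled covariance, and uniform priors decodes bin
identity; the pooled covariance receives fixed diagonal shrinkage 0.1
because ensembles are small (~10 units) and nested cross-validation for
the intensity would be disproportionate. Cross-validation is 5-fold at the
*trial* level, stratified by delay condition; all 32 samples of a held-out
trial are held out together, so no trial contributes to both training and
test. Trials can be subsampled without replacement to a common count
before folding.

Decoding error is the mean absolute bin distance times the bin width. For
an uninformative decoder the chance level is closed-form:
$E|U - V| = (B^2 - 1)/(3B)$ bins for $B$ independent uniform bins — 2.664 s
at $B = 32$, 0.656 s at $B = 8$. The permutation null shuffles bin labels
within trial; the default mode keeps the fitted decoder's held-out
predictions and permutes only the labels (fast and exact for the null of
no time information), while a refit mode retrains the decoder per shuffle
at reduced folds. Early-bin-exclusion repeats the analysis after dropping
the first 1–6 s in 1-s increments (the increment is a parameter; 1 s is
the default), recomputing chance for the reduced bin count.

Representational similarity matrices z-score each neuron's trial-averaged
time course (removing baseline rate differences between neurons) and
correlate the population vectors of all bin pairs; drift appears as decay
of correlation with temporal separation.

## Encoding–retrieval reinstatement

For each trial, population vectors are the per-neuron mean rates over the
encoding span (all 8 s, or its first/second half for the control) and
over the TOJ period (probe onset to response, matching the GLM's epoch
definition). The reinstatement index is the squared Mahalanobis distance
of the retrieval vector from the trial's own encoding vector, under the
covariance of encoding vectors across trials, divided by twice the number
of neurons (the printed normalization, kept as is). The trial-matched
difference form is deliberate: the permutation control, which permutes
the encoding and retrieval matrices independently across trials, is only
meaningful for a statistic that pairs the two periods trial by trial.
The covariance uses Ledoit–Wolf shrinkage toward the scaled identity, the
appropriate estimator at ~10 neurons and ≥90 trials; a bare-inversion
option exists for oracle comparisons. Lower index = stronger
reinstatement.

Inference: per-session permutation control (1,000 independent shuffles of
both matrices), a paired across-session outcome contrast (sign-flip
permutation plus exact sign test on session-level means), and a pooled
cohort control that averages observed and null group means across
sessions before comparison — the design used when several sessions of one
subject are tested together, and the one with adequate power at
single-session ensemble sizes. The video-half control fits
`index ~ correctness * half + delay` with a per-subject random intercept.

## The synthetic session generator

The generator is first-class, tested code; its defaults define the
conditions the pipeline is validated under.

* Task structure: 180 trials per session, 8-s encoding, 0/3.6-s delays in
  equal proportion, Bernoulli(0.65) correctness (within the observed
  62–79 % behavioural range), log-normal reaction times with parameters
  (0.6, 0.8), which place 1.7 % of RTs above the 10-s exclusion cutoff —
  matching the published exclusion rate.
* Ensemble: 10 units, baseline ~8 Hz (log-normal across units). 16 % are
  temporal context cells (mirroring 111/676 recorded neurons), with
  latency uniform on 0.05–1 s, width 0.05–0.3 s, relaxation constant
  log-uniform on 0.1–20 s, peak amplitude 8 Hz; 48/111 of them decrease
  rather than increase at onset (floored at 0.5 Hz). 68 % are TOJ cells
  (461/676) whose rate is multiplied by 1.5 during the TOJ period.
* Trial-wise structure: a latent per-(trial, unit) log-normal gain
  (SD 0.3) perturbs encoding rates; on correct trials the TOJ-period gain
  is correlated with it at ρ = 0.4, on incorrect trials it is
  independent. On correct trials a shared 6-Hz sinusoidal gain of
  amplitude 0.3 modulates all units in the final second before the
  response, coordinating spike timing.
* Spikes are inhomogeneous-Poisson realizations by thinning against the
  supremum rate; all randomness flows from a single seed through named
  substreams, so sessions are byte-reproducible.

The TOJ gain, reinstatement correlation, synchrony gain, and pattern SD
are free parameters — the source analyses report no effect sizes for
them — chosen once at values that produce effects detectable at the
published problem sizes without being trivially large.

**What the generator does not emulate.** Real encoding activity contains
stimulus-driven dynamics beyond the onset-anchored relaxation: video
content evokes rich, time-varying responses throughout the 8 s. The
generator's only time information is the ex-Gaussian relaxation, so
late-video bins differ only through slow exponential tails. Consequently
passing tests demonstrate that the pipeline recovers what the generator
encodes — they do not show that 10 synthetic units match the information
content of 10 real units. This matters for one analysis: decoding after
exclusion of the first 6 s. Under the generator, late-period information
at 10 units × 180 trials is below the detection threshold of any decoder;
the property that temporal information survives early-bin exclusion is
therefore demonstrated on a temporal-context *population* of 20 units ×
360 trials (roughly two sessions' worth), which the acceptance suite
documents as its problem size.

**Problem sizes used by the acceptance analyses.** Parameter recovery:
5 replicate units per τ ∈ {0.5, 2, 8} s at 180 trials. Decoder validity:
one 20-unit × 360-trial temporal-context population, 1,000 permutations.
Null calibration: 250 constant-rate units for the LRT; 30 units across
three effects-off sessions for the TOJ-cell rate; 800 bins across 40
curve-group draws for the permutation test. Effect recovery: 20 seeded
runs each for the pre-response synchrony advantage (cohorts of 5 × 80
trials), the reinstatement contrast (cohorts of 3 × 90 trials, pooled
permutation control), and the decoding–behaviour correlation (cohorts of
10 × 60 trials with the session amplitude scale coupled to accuracy at
logit slope 1). Cohort-level runs mirror the source's across-session
inference; single sessions carry the qualitative sign but not stable
significance at these effect sizes.

## Degenerate inputs and tie-breaks

All-empty spike trains fit as a flagged zero-rate constant model. Rates
are floored at 10^-8 Hz inside likelihoods. Posterior argmax ties break
toward the earlier bin (`max.col(..., "first")`). Blinks touching the
gaze-trace boundary are filled with the nearest valid sample, with a
warning. Sessions with fewer trials than neurons + 2 refuse to estimate a
covariance. Permutation p-values are never zero (add-one convention).

## Known limitations

* The generator's temporal structure is the model family the fitter
  assumes; recovery tests are therefore well-specified by construction
  and say nothing about model mismatch on real data.
* The df-4 LRT against the constant model is anticonservative (see
  above); classification relies on the sequential df-1 test plus
  amplitude criteria.
* Eye events are consumed at event level; raw tracker formats are out of
  scope.
* Single-session outcome contrasts (synchrony, reinstatement) have
  limited power at 8–10 units; across-session designs are the supported
  inference level, as in the source analyses.
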