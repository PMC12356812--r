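---
title: "Models and methods behind gradcpt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradcpt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradcpt)
```

This vignette explains the models the package implements, the choices
made where the method left room for interpretation, and what the
synthetic-data generator does and does not emulate. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The paradigm

In the gradual-onset continuous performance task (gradCPT), scene images
cross-fade continuously: the scene of trial $n$ rises linearly from
weight 0 at its own onset to 1 at the onset of trial $n+1$, then falls
back to 0, so adjacent scene weights always sum to 1. Observers press for
one scene category (go, 90% of trials) and withhold for the other
(no-go). Below the scene stream, a peripheral window shows a dot
revolving once every 2 s. During a single 30-s *critical period* the
window's refresh rate steps down from 180 Hz through 90/60/45/36 Hz to a
30- or 20-Hz target, dwells, and returns by the mirrored ramp. The
rotation period never changes, so a lower rate shows fewer, larger
angular steps per second — motion judder of increasing salience.

## Timeline model

`session_config()` holds the design constants; every invariant (trial
counts, durations, divisibility of the morph grid, monotone ramp) is
validated at construction, so downstream code never re-checks them.

Three details are worth spelling out:

* **Morph quantization.** The display updates weights every 25 ms, i.e.
  in 32 steps per 800-ms trial. A 60/40 morph — the landmark that opens
  the unambiguous response window 480 ms after onset — corresponds to
  19.2 steps and is therefore not exactly representable on the update
  grid; the displayed weight at that instant is 19/32 = 0.59375.
  `morph_weight()` returns the quantized (displayed) weight by default
  and the exact linear envelope with `quantize = FALSE`. The window
  boundaries themselves are defined in time (480/240 ms), not in weight,
  so this has no effect on classification.
* **Frame timing.** Frame periods are the exact rationals $1/\text{rate}$
  (the oft-quoted 5.56 ms at 180 Hz is the 2-decimal rounding of 1/180 s);
  using rounded periods would drift by tens of frames over 480 s.
* **Dot phase.** Within a segment the dot advances by
  $360^\circ/(\text{rate}\times 2\,\mathrm{s})$ per frame; each segment's
  starting phase is taken from the continuous envelope
  $(180^\circ/\mathrm{s})\,t$, so rate changes alter step size and tick
  spacing but never phase. The test suite checks tick-by-tick equality of
  the stepped trajectory and the envelope over a schedule containing the
  full ramp.

The critical-period onset is drawn uniformly over onsets for which the
*entire* 30-s window stays at least 60 s from both session ends. The
exclusion of "the first and last minute" is read session-wise (a trial
lasts 0.8 s, so a minute-scale exclusion can only refer to the session),
and conservatively applied to the whole window rather than its onset
only. Each ramp step lasts one half rotation (1 s); with four
intermediate rates this makes both ramps 4 s, consistent with the 30-s
window around a 22-s dwell.

## Response classification

The unambiguous window of trial $n$ is
$[\text{onset}_n + 0.48\,\mathrm{s},\ \text{onset}_{n+1} + 0.24\,\mathrm{s})$,
560 ms long. Presses outside every window are ambiguous; their candidate
set is the previous and current trial — the ambiguous band
$[\text{onset}+0.24, \text{onset}+0.48)$ lies between those two trials'
windows, so no other trial is a plausible owner. Rules apply in order:

1. if exactly one candidate has no assigned press, it takes the press;
2. otherwise, if the candidates differ in label, the go trial takes it;
3. otherwise presses at most 480 ms after the current onset go to the
   previous trial, later ones to the current trial.

Further decisions the method itself does not fix:

* presses in the opening 480 ms of the first trial have no previous
  trial; their candidate set is the current trial only;
* a trial keeps at most one press (the earliest); surplus presses are
  counted as discarded, since a trial's RT must be unique;
* RT is press time minus the assigned trial's onset (the 480/240-ms
  landmarks are onset-anchored);
* the ambiguous fraction is reported against all trials, counting trials
  whose final press arrived through a stage-2 rule.

The implementation is verified against a brute-force resolver — an
independently coded per-press scan over all windows followed by a literal
transcription of the rules — on 10^4^ random sessions of up to 20 trials
with press streams dense enough to exercise every branch, including
occupied-candidate discards and session edges.

## Variance time course and attentional state

The VTC uses correct go responses only; this is taken literally, so a
commission press's RT never enters the series — the no-go trial is
interpolated over like any error trial. Gaps receive the mean of the
nearest valid RT on each side (a run of gaps shares one bracketing pair);
leading/trailing gaps copy the single nearest valid RT. The deviation is
the absolute z-score with the population (1/n) standard deviation — the
median split is invariant to the n vs n−1 choice, so no downstream label
can depend on it.

Smoothing uses a Gaussian kernel with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ (≈ 3.82 trials at FWHM 9),
truncated at ±10 lags so the centre trial integrates information from
the surrounding 20 trials, and renormalized to unit mass after
truncation. At the series edges the kernel is re-truncated to the
available trials and renormalized again — no padding or reflection, so
no RTs are fabricated outside the session. Trials at or below the median
of the smoothed series are in-the-zone; ties go to in-the-zone, which
matters only for degenerate (constant) fixtures since smoothed RT series
are continuous-valued.

"In-the-zone moments during the critical period" are operationalized as
trials whose *onset* lies in the window (the trial grid is the finest
resolution at which states exist); the same convention maps detection
presses to states.

## Detection coding

Hit/false-alarm boundaries are closed: a press exactly at the window
edges counts as a hit. The full 30-s window (ramps plus dwell) is
critical by default, matching how the 30-s figure is used; a
`window = "dwell"` switch restricts to the 22-s dwell for sensitivity
analyses, and no grace period is added after the window. For cohort
summaries, out-of-the-zone press proportions are computed per participant
and then averaged (equal weighting); participants with no analysable
press are undefined, not zero, and drop out of that analysis — pooling
presses across participants before averaging is the alternative reading
and is deliberately not used.

## JZS Bayes factor

The one-sample test contrasts a point null with a Cauchy prior
(scale $r = \sqrt{2}/2$, the conventional "medium" default; the scale is
exposed because the convention is a choice, not a property of the data)
on the standardized effect $\delta$. Writing the Cauchy as an
inverse-gamma scale mixture of normals reduces the marginal likelihood to
a one-dimensional integral over the mixing variance $g$,

$$\mathrm{BF}_{10} = \int_0^\infty
  (1+ngr^2)^{-1/2}
  \left(\frac{1+t^2/((1+ngr^2)\nu)}{1+t^2/\nu}\right)^{-(\nu+1)/2}
  \frac{g^{-3/2}e^{-1/(2g)}}{\sqrt{2\pi}}\,dg,$$

evaluated by adaptive quadrature (relative tolerance $10^{-8}$) with the
integrand assembled on the log scale so extreme $t$ or $n$ cannot
underflow. A zero-variance sample off the null returns
$\mathrm{BF}_{10}=\infty$; at the null it is an error (the t statistic is
undefined). The tests verify this quadrature against an independent
route: a stratified Monte-Carlo average of the noncentral-t likelihood
over draws from the Cauchy prior itself, a different representation
evaluated through different code. Evidence bands follow the conventional
1/3/10/30 thresholds, with reciprocal `_null` bands below 1.

## The synthetic-session generator

The generator exists so every downstream stage is testable end to end;
its defaults are fixtures chosen once, not estimates.

* **Latent state:** a two-state Markov chain over trials with symmetric
  switching probability $1/\text{state\_dwell\_mean}$ (default dwell 30
  trials = 24 s, a slow fluctuation) and a stationary 50/50 start. A
  discrete chain matches the binary in/out-of-the-zone construct and
  makes recovery tests crisp. Note the switching-probability
  parameterization means dwell 1 is deterministic alternation (dwell 2
  gives independent coin flips).
* **RTs:** lognormal (strictly positive, right-skewed — standard for RT
  data) with median 0.70 s, log-sd 0.10 in-the-zone vs 0.22
  out-of-the-zone, truncated to (0, 1.04 s] so every press stays inside
  its trial's assignable range. The median sits mid-window so most
  presses are unambiguous; the ≥2× sd ratio is what the state-recovery
  test exploits.
* **Lapses:** omission probability 0.05/0.16 and commission probability
  0.03/0.10 (in/out). These make omissions the dominant error, place both
  error types higher out-of-the-zone, and land overall accuracy near
  90%.
* **Detection presses:** an inhomogeneous Poisson process whose hazard is
  piecewise-constant over time, switching at trial boundaries (where the
  latent state can change) *and* at the critical-window edges — so a
  zero false-alarm hazard really produces zero presses outside the
  window. Defaults: 0.05/0.15 per second (in/out) inside the critical
  period, 0.002/0.008 outside, and a ×1.3 gain at the 20-Hz target rate.
  Poisson hazards keep hit/false-alarm counts analytically checkable.

What the generator does **not** emulate: learning and fatigue trends,
post-error slowing, eye movements, multiple main-task presses per trial
(exercised instead by hand-built fixtures in the classifier tests), and
the empirically much higher ambiguous-trial share of real data (~14–19%
there; the simulator's single-press, mid-window regime yields ~2%).
Passing tests therefore show the pipeline is correct under the assumed
structure, not that real data satisfy that structure.

## Problem sizes and determinism

All randomness flows through explicit seeds (`withr::with_seed`, so the
caller's RNG state is never disturbed). The test suite runs full
600-trial sessions where the session structure matters, and scales counts
to what each question needs: 10^4^ instances for the classifier/oracle
equivalence, 200 null sessions for the critical-window in-zone
calibration, 100-session cohorts for the direction-of-effect checks, 50
chains of 6000 trials for the dwell calibration, and 20 $(t, n)$ pairs
at 2×10^5^ stratified prior draws for the Bayes-factor oracle. The
pipeline writes byte-identical tables under a fixed master seed, with
every derived per-participant seed recorded in the run manifest.

## Known limitations

* The simulator's hazard and lapse defaults are plausibility fixtures;
  nothing fits them to experimental data, and analyses of real sessions
  should treat the direction-of-effect tests as pipeline validation
  only.
* Scene identity is modelled as a category label; actual image pairing
  and rendering are out of scope.
* Mixed-model inclusion Bayes factors and contingency-table tests are
  not reimplemented; the pipeline emits the per-participant and
  error-rate tables those off-the-shelf analyses consume.
* The reader for deposited raw data is limited to the package's own
  tabular format; adapters for other layouts must be written against
  `read_session()`'s validated schema.
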