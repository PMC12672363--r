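---
title: "Methods: lever-press vigor and striatal dopamine photometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lever-press vigor and striatal dopamine photometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pressvigor)
```

# The problem

Head-fixed mice perform self-paced inward presses of a loaded lever for water
rewards while striatal dopamine (DA) is monitored with a fluorescent sensor
through an optical fiber. Two questions drive the analysis: (1) how vigorous
is each press — its amplitude (mm) and peak velocity (mm/s) — and how does
vigor change under optogenetic, pharmacological or task manipulations; and
(2) how does the photometry signal decompose into a slow "tonic" ambient-DA
component and fast "phasic" subsecond DA transients, and how do those relate
to presses. `pressvigor` implements the full chain: the online trial
controller, offline press kinematics, photometry preprocessing and
decomposition, event alignment, and the session-level inferential layer,
together with a synthetic-session generator that provides ground truth for
every stage.

# The trial controller

`run_task()` re-implements the acquisition-time state machine on a recorded
lever trace (mm, inward positive, rest at 0):

* a trial starts once the lever has stayed inside the ±0.5 mm detection band
  for 300 ms; any deflection resets the clock. Stillness accumulated during
  the preceding inter-trial interval counts, but a trial can never start
  before the ITI has elapsed;
* a press is rewarded if it crosses the detection threshold and then the
  reward threshold (4.1 mm default) strictly within 0.5 s; the ~5 µl water
  reward is delivered 0.5 s after the reward crossing and ends the trial;
* otherwise the trial times out at 30 s; each trial is followed by a 1-s ITI
  in which deflections are never rewarded;
* with the uncued mid-session threshold shift armed
  (`apply_threshold_shift()`), trials from the configured index (80 in the
  task as run) are scored with a 10% higher reward threshold.

Timing conventions that the implementation fixes: all comparisons run on the
10-ms centred median-filtered position (single pathway, matching the online
smoothing; an offline zero-phase filter differs from a causal controller by
at most one sample); times live on the sample grid as integer indices, so
"within less than 0.5 s" is a strict inequality in samples; a trial cut off
by the end of the recording is discarded. The compiled state machine is
validated sample-for-sample against `run_task_reference()`, a deliberately
naive R interpreter of the same rules that shares no code with it.

# Press kinematics

`preprocess_lever()` decimates the acquisition-rate trace (nominally 10 kHz)
to 1 kHz with an anti-aliasing zero-phase Butterworth stage, then applies the
30 Hz low-pass with 6 poles in total (an order-3 Butterworth run forward and
backward, magnitude $1/(1+(f/30)^6)$). That closed form is the test oracle
for the filter stage; probe sinusoids must match it to 1%. Odd-reflection
padding suppresses the forward–backward edge transients.

Instantaneous velocity is the central difference of the filtered 1 kHz trace
(the estimator is not dictated by the acquisition system; central differences
are unbiased to second order on this grid). Movement segments are maximal
runs of inward velocity above 5 mm/s. A press window opens at a rising
crossing of the detection threshold and closes when the lever has stayed
below it for 50 ms. The dwell matters: sequential deflections riding on one
another, and the fast ringing of a dropped lever, dip below the detection
band for only a few milliseconds; without the dwell those dips would split
one press into several and the let-go exclusion rule could never see the
outward overshoot. 50 ms is longer than half a period of the 15–25 Hz
ringing and far shorter than any inter-press interval, so the choice is not
delicate.

Press amplitude is the furthest inward distance in the window; peak velocity
the largest velocity over the window's movement segments. When a mouse lets
go of the lever mid-press the sprung lever whips back through rest, and the
ringing's inward half-cycles reach several hundred mm/s — an order of
magnitude above true press velocities. `exclude_letgo()` truncates the
analysis window at the first time the lever overshoots rest outward by
strictly more than 2.5 mm and recomputes both metrics; on paired synthetic
sessions differing only in the artifact, session velocity estimates agree to
well under 1%.

Session vigor is summarized by bootstrap medians (`bootstrap_median()`,
1,000 resamples): the point estimate is the mean of the resampled medians —
stabler than the raw median when trial counts are small or imbalanced — with
a percentile 95% interval; the raw median is reported alongside. Percent
change of manipulation versus control trials, the 30-trials-before /
200-s-after threshold-shift contrast, and the trial-n-versus-n+1 contrast
all operate on these summaries.

# Photometry

The photoreceiver voltage (nominally digitized at 2 kHz) is decimated to
1 kHz and low-passed at 30 Hz with 10 poles total for time-domain analyses.
`normalize_to_initial()` divides by the mean of the first 15 s, recording
that mean as the baseline-fluorescence (F0) estimate; the record guards
against double normalization, and the operation is scale-invariant.

**Tonic component.** Photobleaching makes the raw baseline decline over a
session, so condition effects on tonic DA are measured as ratios:
`bleaching_ratio()` averages the normalized signal in 2-min bins and divides
each bin by the saline-reference mean of the same bin
(`saline_reference()`, the per-bin mean over the cohort's saline sessions).
The saline reference divided by itself is exactly 1 in every bin; a
condition that multiplies the DA-bound sensor fluorescence by g settles at a
ratio near g once drug uptake is complete. No further bleach correction and
no rolling-baseline ΔF/F is computed anywhere; analyses stay in normalized
voltage.

**Phasic component.** `compute_psd()` estimates the 0.1–11 Hz power spectrum
of the raw, unfiltered voltage by the multitaper method: a single window
spanning the record for 0.1 Hz resolution, time-bandwidth 3, 5 tapers, mean
of eigenspectra. The discrete prolate spheroidal tapers are computed from
the Slepian tridiagonal eigenproblem (Sturm-count bisection plus inverse
iteration in compiled code; columns match SciPy's reference implementation
to machine precision). A Welch estimate over 60-s Hann segments is available
as a cross-check. `phasic_power_index()` fits $a/f + c$ to the out-of-band
frequencies and reports observed/predicted band power in 0.5–4 Hz, the band
where subsecond DA transients live: ~1 when the band is indistinguishable
from the aperiodic floor (white noise, or a complete mDAN lesion), large
when transients are present.

**Event alignment and repair.** `event_triggered_average()` returns
per-event snippets, mean and s.e.m., dropping (and counting) events too
close to the record edges. `signal_at_press_timepoints()` samples the trace
0.5 s before press onset (configurable — the relevant lead time is 0.5–1 s),
at onset, and at the peak-velocity time. `transient_amplitude()` measures
peak-minus-baseline responses, used to compare stimulation-evoked against
reward-evoked transients. `blank_and_inpaint()` removes optogenetic light
artifacts ±6 ms around each pulse before any filtering, filling interior
gaps by shape-preserving piecewise-cubic (PCHIP) interpolation and edge gaps
by linear continuation; samples outside blanked windows are returned
bit-identical.

# Inference

* `vigor_da_regression()`: per-press vigor on instantaneous DA, ordinary
  least squares with Pearson r and the F-test p-value for the slope.
* `mixed_effect_contrast()`: session-level values (percent change of vigor,
  matching the unit in which session effects are plotted) modelled as
  `value ~ session_type + (1 | mouse) + (1 | mouse:session_number)` by REML
  with Satterthwaite degrees of freedom. `session_number` is the
  within-mouse session index, pairing the k-th manipulation session with the
  k-th sham session; that reading makes the model identifiable with one
  observation per session. The paper-side software does not state its
  p-value method, so Satterthwaite is documented as an approximation;
  singular fits are flagged but still reported.
* `choose_test()`: the test-selection policy — Shapiro–Wilk at α = 0.05 on
  the paired differences (or each group), dispatching to the paired t-test /
  Welch two-sample t-test or to the Wilcoxon signed-rank / Mann–Whitney
  test. All tests two-sided. Zero-variance inputs short-circuit to a
  degenerate branch (p = 1 for no difference) rather than erroring.
* `multi_group_contrast()`: repeated-measures omnibus (one-way ANOVA with a
  subject error stratum when the design is balanced, a mixed model
  otherwise) followed by many-to-one comparisons against the reference
  condition with single-step multivariate-t (Dunnett-style) familywise
  control on the mixed-model fit, which covers missing cells without a
  bespoke closed form.

Each test's type-I error under its own null is verified to lie in
[0.03, 0.07] at α = 0.05 over 500 replicates, and the mixed model recovers
an injected +10% session effect within two standard errors.

# The synthetic-session generator

No raw recordings are distributed with the study, so every stage is
exercised against `simulate_session()` / `simulate_photometry()`, whose
defaults encode the study conditions and whose ground truth is never read by
analysis code.

**Lever.** Presses are raised-cosine (Hann) velocity pulses: duration
$T = 2A/V_p$ solved from the drawn amplitude and peak velocity, with a
slower raised-cosine return. Amplitudes are log-normal
(meanlog log 4.8 mm, sdlog 0.4), placing ~65% of presses above the 4.1-mm
reward threshold — matching the roughly two-thirds rewarded-press rate of
well-trained mice. Peak velocities are log-normal (meanlog log 85 mm/s,
sdlog 0.35), drawn independently and clipped into $[4A, 40A]$ so press
durations stay in 0.05–0.5 s: the pulse family is otherwise infeasible or
unphysically slow, and real ballistic presses show amplitude–velocity
scaling. Press onsets follow an exponential renewal process (0.25/s) with a
2.5-s refractory gap — "every few seconds" — left configurable because the
inter-press-interval family is not characterized beyond that. Postural
micro-adjustments (0.1/s, 0.2–1.3 mm Hann blips) sit below the press
threshold; encoder noise is 0.02 mm white. A let-go release replaces the
smooth return on a configurable fraction of presses: a 30-ms drop to 4 mm
outward overshoot followed by 18-Hz ringing decaying 0.35× per half-cycle,
so the overshoot always engages the >2.5 mm exclusion rule (also after
30-Hz filtering) while the inward rebound stays below the 1.7-mm press
threshold and never spawns spurious presses. Rewards are not scripted: the
emitted trace is scored closed-loop by `run_task()`, and
`replay_ground_truth()` provides an independent event-level check of every
reward decision.

**Photometry.** The voltage composes as
`dark + autofluorescence + B(t)·(F_unbound + tonic(t) + phasic(t)) +
artifact + noise`. The bleach factor B(t) is a double exponential (τ = 60 s
and 6000 s, weights 0.05/0.95), i.e. near-linear loss over a 40-min session.
Dark offset (5 mV), autofluorescence (20 mV, pre-bleached patch cords) and
DA-independent sensor fluorescence (55 mV) are small against the DA-bound
tonic level (1.32 V), consistent with a starting voltage of ~1.4 V inside
the observed 0.7–2.0 V range and with most signal reflecting DA binding.
Condition gains on the tonic term — saline 1.0, raclopride 0.8, levodopa
1.5, lesion 0 — ramp in smoothly over 300 s of drug uptake (lesions apply
from t = 0); raclopride also halves transient amplitudes and a lesion
removes them. Phasic activity is reward-locked biexponential transients
(rise 80 ms, decay 250 ms, 40 mV) plus Poisson spontaneous transients
(1.2/s, log-normal amplitudes around 40 mV ≈ 3% of baseline) band-limited to
0.5–4 Hz; the rate and amplitude were calibrated once so the synthetic PSD
reproduces the qualitative spectrum of intact recordings — a pronounced
0.5–4 Hz excess over the 1/f-plus-white floor that vanishes after lesion
(an order of magnitude separation in the phasic index). Optogenetic light
artifacts are 4-ms additive spikes at each pulse, inside the ±6 ms blanking
window. All components are recorded per sample, and their sum reconstructs
the emitted trace exactly.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: hemodynamic and motion artifacts, sensor
kinetics and saturation, raclopride's DA-independent fluorescence shift
(deliberately uncorrected in the pipeline as well), multi-fiber geometry,
learning across days, and any biophysical model of DA release or diffusion.
Recovery tolerances (2% amplitude, 5% velocity) absorb the documented
filter-induced bias on the shortest presses; deflections within the 2%
measurement band around the 1.7-mm press threshold can legitimately
classify either way.

# Numerical choices

Integer sample arithmetic for all task timing; strict inequalities at the
reward window and the 2.5-mm overshoot (an overshoot of exactly 2.5 mm is
kept); odd-reflection padding around `filtfilt`; PCHIP inpainting with a
20-sample context window per gap and linear continuation at record edges;
the aperiodic PSD floor fitted by unweighted least squares on linear power
(unbiased for the mean level, so pure white noise yields an index of ~1)
with coefficients clamped at 0; one RNG stream per generator component,
derived from the session seed, so ablating one component leaves the others
byte-identical.

Problem sizes used by the test-suite and acceptance script — chosen to keep
a full run in the low minutes on one CPU while leaving every property
well-resolved: 100 60-s sessions for the controller oracle; one 900-s
session at 2 kHz (~200 presses) for kinematics recovery; four saline plus
two drug 30-min recordings at 50 Hz for the bleach ratio; 600-s records at
250 Hz for spectra; 500 replicates for the statistical calibrations.

# Limitations

The controller is validated against its own specification, not against
acquisition-hardware logs; the generator's press shapes are smooth pulses,
so detection performance on tremorous or compound movements is not
characterized; the multitaper single-window choice trades variance for
resolution at the 0.1-Hz end of the band; and the mixed-model p-values rely
on the Satterthwaite approximation at small cohort sizes.
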