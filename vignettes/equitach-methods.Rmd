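---
title: "equitach: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{equitach: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equitach)
```

## The analysis problem

Single-lead exercising ECGs from sport horses are routinely reduced to an
RR-interval tachogram: the series of intervals between successive QRS
complexes, with a per-beat readability mask where electrode contact was
lost. `equitach` detects and classifies premature complexes (PCs) in such
tachograms, aggregates them into per-workout arrhythmia categories and
heart-rate metrics, and models their association with horse- and
workout-level covariates across a cohort. A simulator with a ground-truth
ledger closes the loop: every stage of the pipeline is validated against
data whose arrhythmia content is known exactly.

## Premature-complex detection

A beat is a PC candidate when its RR interval is short relative to the
*surrounding RR reference*:

$$\frac{|RR_i - \mathrm{ref}_i|}{\mathrm{ref}_i} \ge \theta,
  \qquad \theta = 0.05,$$

with the sign retained (short deviations are premature; long ones are
return cycles or pauses). The threshold is boundary-inclusive: a
deviation of exactly 5% is flagged. Key choices:

- **Reference construction.** `ref_i` is the median of up to 11 nearest
  RR intervals, excluding the candidate itself, balanced before/after the
  candidate where the recording allows. The median is robust to adjacent
  ectopy and mirrors the behaviour of commercial HRV beat-correction
  filters; a mean is available via
  `detection.reference_statistic: mean`. The window of 11 spans roughly
  3–8 s at exercising heart rates — long enough to be stable, short
  enough to track rapid rate changes.
- **Iterative exclusion with block extension.** Beats flagged premature
  are removed from their neighbours' reference sets and references are
  recomputed until a fixed point (a manual reader likewise excludes
  obvious ectopy from the "surrounding average"). Inside a long run the
  balanced window is majority ectopy and the median sticks to the run
  value, so per-beat flagging alone stalls after the run edges; a
  detected beat's reference is therefore also applied to its immediate
  neighbours, which join the block when they too are ≥ 5% short of it.
  The next pass recomputes every affected reference with the block
  excluded, so the converged flags are self-consistent with their own
  references — a run of 8 equal shortened intervals is recovered in
  full without dragging the local median down to itself.
- **Long deviations.** A long interval immediately after a premature beat
  is its return cycle; an isolated long interval is a pause
  (second-degree AV block behaviour at rest). Neither contributes to
  nPC: the burden statistic counts premature complexes only.
- **Absolute mode.** An alternative operative rule — 5% of the RR at the
  recording's peak heart rate, applied as an absolute millisecond cut —
  is available (`detection.threshold_mode: absolute_at_peak`) but the
  relative rule is the default and the one used everywhere in the tests.
- **Artifacts.** An RR interval with an unreadable endpoint beat is
  excluded from references, never flagged, and labelled `artifact`.

Events are maximal runs of consecutive premature beats: 1 = single PC,
2 = couplet, 3 = triplet, > 3 = run. A return cycle is not premature, so
a premature–return–premature pattern is two single PCs, not a couplet.
nPC sums run lengths; couplets are deliberately *not* complex arrhythmia,
while triplets, runs and paroxysmal AF are (this follows the
human-athlete eligibility recommendations many equine studies adopt).

## Pause classification

For a single PC with coupling interval $c$ and return cycle $r$, let
$S = c + r$ and $T = 2\,\mathrm{ref}$ computed just before the event. The
pause is **compensatory** when $|S - T|/T \le 0.05$ (the sinus node was
not reset: the next sinus beat lands on schedule), **non-compensatory**
when $S < 0.95\,T$, and **indeterminate** otherwise (including events at
the recording end). "Equal or nearly equal" is not quantified in the
clinical convention, so the tolerance reuses the 5% granularity of the
detection rule; exact ties favour compensatory. Note a geometric
consequence: a non-compensatory pause with prematurity below 10% leaves
$S$ within 5% of $T$ and is therefore classified compensatory — the
closed-form acceptance constructions for the non-compensatory branch use
prematurity above 10%.

## Paroxysmal atrial fibrillation

AF during exercise shows an *irregularly irregular* rhythm: continuously
variable RR intervals with no repeating pattern. The detector marks a
stretch of at least 12 consecutive non-artifact beats as pAF when

1. every beat is covered by a 12-beat rolling window whose RR coefficient
   of variation exceeds 0.10 (sinus variability during exercise is an
   order of magnitude lower),
2. the lag-1 autocorrelation of RR within the stretch satisfies
   $|\rho_1| < 0.3$ — strict bigeminy (alternating 400/600 ms) has CV
   ≈ 0.2 but $\rho_1 \approx -1$ and is rejected, and
3. the irregularity is *sustained*: at least half of the successive RR
   differences exceed 5% of the segment mean.

Condition 3 was added after the recovery experiments showed that a
high-prematurity couplet, triplet or run raises the rolling CV of the
windows containing it (two or three level shifts produce a large
variance) and can satisfy conditions 1–2, which would silently reclassify
genuine ectopy as pAF and remove it from nPC. Fibrillation changes cycle
length at nearly every beat (for i.i.d. intervals uniform on
$(0.7, 1.4)\times$ base, ~85% of successive differences exceed the 5%
cut), whereas an ectopic run changes it two or three times, so the
fraction of large successive differences separates the two cleanly.
Beats inside detected pAF segments are relabelled and excluded from PC
logic; pAF raises the ARRHYTHMIA and ARRHYTHMIA_complex flags but adds 0
to nPC.

## Fast-deceleration segmentation

Arrhythmias during fast heart-rate deceleration are analysed separately
(autonomic rebalancing makes this phase mechanistically distinct), but
"fast deceleration" has no numeric definition in the exercise
literature. The operational default — reported alongside any result — is:
instantaneous HR (60000/RR) is resampled to 1 Hz and smoothed with a
10 s rolling median; a segment starts where HR, from a local maximum of
at least 120 beats/min, falls by ≥ 30 beats/min within 60 s (the start is
advanced past any peak plateau to the decline onset) and ends when the
smoothed downward slope first flattens above −0.1 beats/min/s. All four
constants are configuration parameters (`deceleration.*`). Events are in
the deceleration phase when their onset lies in a segment; segment
intervals are half-open `[start, end)`.

## Workout metrics and readability

- **HR_peak** = 60000 / mean of the 5 shortest RR intervals among beats
  labelled normal (premature beats, return cycles, pAF and artifact are
  excluded, so a burst of ectopy cannot masquerade as intensity). The
  mean is taken on the interval scale, then inverted once — the
  difference from averaging five instantaneous rates is second order.
- **HR_mean** = 60000 / duration-weighted mean RR
  ($\sum RR_i^2 / \sum RR_i$ in the denominator's numerator form): each
  interval is weighted by the time it occupies, so ten slow seconds count
  as ten seconds. Premature beats are included (the burden is part of the
  rhythm); artifact intervals are excluded by default
  (`hr_mean(exclude_artifact = FALSE)` reverses this, since whether
  commercial software excludes gaps is device-dependent).
- **Readability** is duration-weighted: the fraction of the recorded span
  covered by readable RR intervals, each interval inheriting the quality
  of its terminating beat. Artifacts destroy time spans, not beat counts,
  and the inclusion criterion ("95% or more of the recording") reads as
  recording time; a beat-count weighting is available
  (`readability.weighting: beats`). The gate is boundary-inclusive:
  exactly 95% is included.

## The synthetic cohort

The simulator emulates the cohort structure the pipeline is designed
for: 62 horses, 8 of them with previous cardiac signs, workout types
drawn with the observed frequencies (Flat and Gallop dominate), per-type
target peak heart rates at the observed group medians (e.g. ~192
beats/min for gallops, ~211–215 for cross-country competition), and
durations lognormal around 45 min. Defaults that the source cohort does
not pin down were chosen once:

| parameter | default | rationale |
|---|---|---|
| `base_pc_rate` | 0.1 /1000 beats | ~0.4 expected PCs in a 50-min workout, matching a ~26% per-workout arrhythmia prevalence in unaffected horses |
| `cardiac_rate_ratio` | 6.6 | the incidence-rate ratio reported for horses with previous cardiac signs |
| `complex_event_prob` | 0.01 (×2.5 cardiac) | complex arrhythmias are rare (~2% of workouts) |
| `paf_prob` | 0.003 | two AF paroxysms in ~737 workouts |
| `artifact_fraction_range` | [0, 0.07] | uniform draw puts ~71% of workouts above the 95% readability gate, near the ~74% observed |
| `workouts_per_horse` | [2, 30] | uniform range bracketing the observed mean of ~16 ECGs/horse (the real distribution is right-skewed with median 7 and maximum 97; a uniform range is a deliberate simplification) |
| `pc_propensity` | lognormal, sdlog 1 | arrhythmia burden concentrates in few horses; no per-horse distribution is reported, so this is a modelling choice |

**Sinus variability** is multiplicative lognormal noise on RR with
stationary CV `sinus_cv` = 0.02, generated as an AR(1) process on the
log scale with lag-1 correlation 0.99. The band-limiting matters: white
noise at CV 0.02 puts the 5% detection corridor at 2.5 σ and would
produce ~6 false PCs per 1000 beats, while physiological short-term
variability during exercise is small and slow (vagal withdrawal
suppresses respiratory arrhythmia; what remains is drift). With the
correlated model a beat deviates from its 11-beat local median by ~0.5%
(σ), the corridor sits at ~10 σ, and the false-positive rate is
effectively zero — which is also what makes the specificity criterion
(sub-threshold 3% injections never detected) achievable with margin
rather than by luck.

**Injections** use integer-millisecond arithmetic so the compensatory
identity is exact after serialisation: coupling = round(base × (1 − p)),
return = 2 × base − coupling, hence coupling + return = 2 × base exactly;
non-compensatory events return a plain base cycle. Runs shorten
`run_length` consecutive intervals and append one return cycle. pAF
episodes draw i.i.d. intervals uniform on (0.7, 1.4) × base (CV ≈ 0.19,
comfortably above the 0.10 detector threshold). Events are placed by
fractional onset, snapped to the nearest beat, and shifted forward on
collision; unresolvable events are recorded in the ledger as skipped.
Artifact windows are contiguous (contact loss destroys stretches, not
scattered beats) and avoid event spans so ground-truth recovery rates are
well defined.

**What the simulator does not model:** QRS/P/T waveform shapes (only a
relative width attribute per beat), supraventricular vs ventricular
origin, GPS/speed/stride channels, scattered single-beat artifacts,
device-specific QRS mis-triggering, and the long right tail of the
per-horse workout-count distribution. A green recovery test therefore
establishes that the detector recovers *cleanly injected* events under
realistic rate profiles and band-limited sinus noise — not that it
handles every failure mode of real field recordings.

## Cohort statistics

- **Summary tables** aggregate included workouts per group × type with
  medians/ranges and flag prevalences. Percentages are computed at full
  precision, reported to one decimal; the renderer drops a trailing
  ".0". One transcription quirk is documented in the acceptance
  materials: a source-table cell prints 26.3% where the underlying
  counts (141/535) give 26.355% → 26.4; the package reports the
  arithmetic, not the misprint.
- **Spearman screens** use average ranks for ties, a two-sided t
  approximation for p (exact permutation for n ≤ 9), and Chan's
  interpretation bands made right-open — None = 0, Poor (0, 0.2), Fair
  [0.2, 0.6), Moderate [0.6, 0.8), Strong [0.8, 1), Perfect = 1 — so
  each |ρ| maps to exactly one band. |ρ| within 1e−10 of 1 is clamped to
  ±1 before banding.
- **Mixed models** delegate to `lme4::glmer` (Laplace approximation) with
  a random intercept per horse; the package's contribution is the data
  pipeline: term construction, Flat as the workout-type reference,
  Wald 95% CIs on the ratio scale, the collinearity policy (any
  continuous term with R² > 0.8 against the remaining fixed effects —
  VIF > 5 — is dropped and reported; in this domain peak HR and duration
  track workout type too closely to coexist with it), a complete-
  separation guard, and a documented fallback: a singular random-effect
  fit triggers a warning and a pooled GLM with `pooled = TRUE`, which is
  also the exact zero-variance limit the tests verify. No overdispersion
  correction is applied to the Poisson model (matching common practice
  for these count models); users with overdispersed counts should treat
  the CIs as anti-conservative.

## Numerical and interface choices

- Beat times are stored as integer milliseconds (device precision), so
  tachogram CSV round-trips are exact and all derived arithmetic is
  full-precision — no decimal-rounding workarounds are needed anywhere.
- All constants live in one validated configuration object
  (`default_config()`); unknown keys are rejected by name, numeric
  parameters are bounds-checked, and YAML round-trips are stable.
- Seeds are mandatory for every stochastic path; a fixed (config, seed)
  pair reproduces simulated cohorts byte-for-byte, and the pipeline
  manifest records per-file checksums to make end-to-end determinism
  checkable.

## Known limitations

Single-lead logic only (no origin classification); the deceleration
thresholds are operational placeholders pending a field consensus; the
pAF detector is tuned for exercise tachograms and will not separate AF
from atrial flutter or frequent multifocal ectopy; morphology calls
depend on a device-supplied width channel and default to `unknown`
without one; and cohort-level odds/rate ratios from the simulator should
be read as recovery experiments, not as re-estimates of any published
cohort's effects.
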