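---
title: "Quantifying online compensation and sensorimotor adaptation to F1 feedback perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying online compensation and sensorimotor adaptation to F1 feedback perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fpl` implements the complete analysis methodology of a formant-feedback
perturbation experiment on sustained vowels: the five-session trial design,
within-trial quantification of online compensation to unpredictable first
formant (F1) perturbations, across-trial quantification of sensorimotor
adaptation to consistent perturbations, within-trial response dynamics during
adaptation, and the inferential layer tying them together. Because raw
recordings from such experiments are rarely shareable, the package also
ships a synthetic-cohort simulator — a feedback + feedforward control model
of the speaker — so that every stage of the pipeline can be exercised and
validated against known ground truth.

The expected inputs are per-trial F1 tracks on a uniform frame grid (3 ms
frames by default, roughly 2 s of sustained vowel per trial) with voice
onset/offset markers, joined to a trial schedule describing the word prompt,
session, phase, and perturbation (kind, signed magnitude, onset, duration).
Real-time audio processing, formant tracking from raw audio, and manual
screening GUIs are out of scope; tracks and markers are trusted as given.

# Experimental design

Five sessions of 165 trials. Sessions 1, 3 and 5 probe *online compensation*
with unpredictable perturbations: 432 perturbed trials spread over eight
conditions — mid-utterance (400 ms transient, onset jittered uniformly on
200–500 ms after voice onset) and whole-utterance (from voice onset, entire
trial) perturbations at −200, −50, +50 and +200 Hz — plus 48 unperturbed
trials, with 15 familiarization trials opening session 1. Sessions 2 and 4
probe *sensorimotor adaptation*: a 42-trial unperturbed baseline, an
81-trial hold phase with a constant whole-utterance ±200 Hz perturbation
(direction counterbalanced across participants between the two sessions),
and a 42-trial washout. Catch trials with the contrastive word ("hid"
against the analysed "head") are interleaved and excluded from every
analysis.

The per-condition allocation of the 432 perturbed trials is not fully
constrained by the published totals; the generator defaults to the equal
allocation (54 trials per condition: 45 "head" + 9 "hid"), which reproduces
the 360/72 head/hid totals exactly, and the allocation is configurable.
The jitter law is likewise unspecified beyond its bounds; we use a
continuous uniform distribution on [200, 500] ms. Familiarization trials
are sampled uniformly over the ten trial types and flagged; good "head"
familiarization trials are analysed by default (configurable), matching the
stated treatment of such trials.

# The speaker model behind the simulator

Each synthetic participant produces, for a trial with perturbation `p`
starting at `t_p`:

```
f1(t) = f1_baseline + trend_amplitude * exp(-t / trend_tau)
        + s + c(t) + eps_trial + eps_frame(t)
```

* `f1_baseline` (Hz): the participant's vowel target (population default
  600 ± 50 Hz, typical for /ɛ/).
* the exponential **onset transient** (default 30 Hz, τ = 80 ms) stands in
  for the articulatory settling at vowel onset that the trend-subtraction
  step is designed to remove.
* `s` (Hz) is the **feedforward adaptation state**, updated across trials by
  a single-rate learner `s[k+1] = r s[k] − β p[k]` with retention `r`
  (default 0.95) and learning rate `β` (default 0.00425 per Hz·trial).
  Under a constant perturbation the state converges to
  `s∞ = −β p / (1 − r)`, i.e. a plateau of `100 β / (1 − r)` percent of the
  perturbation (default 8.5%, within the range such experiments report).
  The experiment quantifies adaptation non-parametrically; the state-space
  learner is a fixture with known ground truth, not a scientific claim.
* `c(t)` is the **online feedback compensation**: zero until the sensory
  latency `L` (default 275 ms) has elapsed after perturbation onset, then a
  first-order rise toward `−g·p` with time constant `τc` (default 120 ms),
  where `g` is the compensation gain (`g_mid` = 0.03, `g_whole` = 0.05 by
  default, i.e. 3–5% opposition). After a transient perturbation ends the
  response decays back to zero with the same `τc`, *starting at offset + L*:
  the same sensory delay that gates the onset of the response must gate its
  release (were the decay anchored at the physical offset, any latency
  longer than the 400 ms transient would imply no response at all).
* `eps_trial ~ N(0, σt²)` (default σt = 18 Hz) models trial-to-trial
  variation in vowel posture; `eps_frame ~ N(0, σf²)` iid per 3 ms frame
  (default σf = 12 Hz) models formant-tracking jitter.

Population spreads default to what group-level SEMs in this paradigm imply
at n = 22: gain SDs of 0.03 (mid) and 0.045 (whole) — i.e. per-condition
compensation spreads of roughly 3–5 percentage points — and adaptation
plateau SDs around 11 points. These spreads deliberately place a minority
of simulated speakers at or below zero response, mirroring the observed
fact that not all participants compensate or adapt; responder selection
then has real work to do. Cohort draws couple `g_mid`/`g_whole`
(correlation `rho_mid_whole`) and `g_whole`/`β` (`rho_comp_adapt`), so
both correlated and independent regimes of the compensation–adaptation
relationship can be produced on demand. Gains may be negative under the default preset — some speakers
follow rather than oppose a perturbation — and a `"compensator"` preset
clips them at zero. A `"realistic"` preset randomly flags ~3% of "head"
trials as excluded to exercise screening. What the simulator does **not**
emulate: F2 and higher formants, pitch and loudness channels, somatosensory
feedback, vowel-quality differences beyond a fixed offset for catch trials,
non-Gaussian tracking error, or session-to-session drift. Passing tests
therefore demonstrate correctness of the *analysis machinery* under the
stated generative assumptions, not fidelity to any specific human cohort.

# Within-trial compensation analysis

Three linear normalization steps per analysable trial:

1. subtract the participant's **unperturbed response trend** — the average
   across good unperturbed "head" trials of the voice-onset-aligned track,
   itself re-referenced so F1(0) = 0 — removing the shared deterministic
   trajectory;
2. re-align time zero to the **perturbation onset** and subtract the mean of
   the first 50 ms of post-onset data (a window shorter than any
   compensatory latency), removing trial-level offsets;
3. average within non-overlapping **25 ms bins** anchored at the
   perturbation onset; frames join bins by half-open membership of their
   timestamps (8–9 frames per bin at 3 ms framing; only bins complete for
   every contributing trial are kept).

Trials are averaged within participant by condition, then across
participants (mean ± SEM). The **group onset latency** per condition is the
first bin, scanning forward, whose group mean lies beyond two standard
deviations of the onset pool — all group samples in the first 50 ms across
the four magnitudes of the same perturbation kind — *in the compensatory
direction* (opposite the perturbation's sign). Two numerical choices guard
this rule: the crossing must persist for four consecutive bins (100 ms),
and the threshold has a 1e−9 Hz floor. Direct null simulation shows why the
persistence term is needed: a literal single-bin 2 SD rule fires somewhere
on pure noise in most runs (the pool estimates the same noise scale the
series carries, so roughly 2% of the 60-odd scanned bins cross by chance),
whereas the 100 ms-sustained rule keeps the false-detection rate under 1%
while leaving genuine first-order responses — supra-threshold for hundreds
of ms — untouched. The floor makes zero-noise runs (where the pool is
degenerate) return the true latency instead of tripping on float jitter.

The **peak percent compensation** per participant and condition averages the
normalized time-course in a 200 ms window centred on the group peak-response
latency and converts it with
`response / |p| × 100 × compMult`, `compMult = −1` for positive and `+1`
for negative perturbations, so opposition is always positive. The group
peak latency is the extremum of the group mean in the compensatory
direction, searched from the onset latency to the perturbation offset +
300 ms (transient conditions) or to the end of common coverage less half
the window (whole-utterance conditions, so the centred window always
fits). Ties along a flat extremal run resolve to the run's middle bin,
which keeps the window inside the plateau for step-like responses. Each
condition is summarised with mean, SEM and a two-tailed one-sample t-test
against zero.

# Adaptation analysis

For each adaptation session, the feedforward response of each "head" trial
is the mean F1 over the first 75 ms from voice onset — before auditory
feedback can act. The trajectory is normalized by the participant's mean
over "head" trials 1–30 (the baseline phase), smoothed in non-overlapping
five-trial windows (a trailing remainder is dropped), and the **adaptation
percentage** converts the mean of "head" trials 76–90 (the last 15 hold
trials) with the same compMult formula. Windows are half-open and
voice-onset referenced (25 frames in [0, 75) ms at 3 ms framing).
Participants whose adaptation lies more than three standard deviations
(computed about the mean) from the cohort *median* are excluded in a single
pass, per direction, and the per-direction removals are unioned — the
centring/dispersion pairing is one reading of "standard deviations from the
median", chosen and flagged here.

**Within-trial dynamics**: for participants who both compensated (> 0%) for
the whole-utterance ±200 Hz unpredictable perturbation and adapted (> 0%)
to the matching consistent perturbation, within-trial time-courses are
averaged over four 15-trial phases (head ordinals 16–30, 31–45, 76–90,
106–120), normalized by the mean time-course over head trials 1–30, and
summarised in onset (O, 0–75 ms) and mid-utterance (M, 600–800 ms) windows
as percent compensation. The baseline reference is taken over the first 30
*head* trials, consistent with the across-trial analysis. A trial truncated
before a window contributes to the windows it covers and is dropped from
the rest (window-specific exclusion maximises data use; up to 3 of the 15
trials of a phase window may be missing). The O window of the late-hold
phase equals the across-trial adaptation statistic on the same trials by
construction, which the tests assert to 1e−9.

# Inferential layer

All mixed models are REML fits with a participant random intercept
(`lme4`/`lmerTest`), sum-to-zero contrasts and type-III F tests with
Satterthwaite denominator degrees of freedom. The source experiment mixed
two proprietary software conventions for denominator df; replicating their
df arithmetic bit-for-bit is explicitly not attempted — the model structure
is matched, and the df convention used here is recorded in each result.
Relationships between response types use random-intercept fixed-slope
regressions (`whole ~ 1 + mid + (1 | participant)`,
`adapt ~ 1 + unpredict + (1 | participant)`). With one observation per
participant the random intercept is unidentifiable and the fit reduces to
ordinary least squares, which is what the implementation then computes and
flags. Both forms are reported for the mid↔whole relationship: the
condition-level model (four observations per participant) and the
regression on participant-level mean compensations. The two answer
subtly different questions — when the coupling of interest lives entirely
between participants, the condition-level model's random intercept absorbs
most of that covariance and its fixed slope is driven largely by
within-participant contrasts, so the participant-level regression is the
more direct (and considerably more powerful) estimate of across-speaker
coupling; the calibration suite uses it for exactly that reason. Singular fits and degenerate variances are reported through flags,
never as silent NaN or exceptions. No multiple-testing correction is
applied by default (matching the source methodology); `adjust_fdr()` adds
Benjamini–Hochberg adjusted columns for users who want them. Session-order
checks use a classical repeated-measures ANOVA (participant error stratum)
on per-session median baseline F1, plus a mixed model on per-session peak
compensations reusing the pooled group latencies.

# Reproducibility and problem sizes

Every pipeline stage derives its RNG stream deterministically from one
top-level seed (`derive_seed()` folds participant ids, session numbers and
stage labels into child seeds), so a results bundle is a pure function of
its `run_config`, whose hash is recorded in every provenance block. All
artifacts are plain text (TSV tracks with full-precision floats and exact
strtod round-trip, CSV tables, JSON sidecars and model results).

The validation suite runs the full stack at the study's own scale — 22
participants, 165-trial sessions, 3 ms frames, 2 s trials — for single-run
checks, and uses 17–100 seeded replicates per property for the stochastic
calibration checks (latency recovery at 200/275/450 ms; gain recovery at
g = 0.05; plateau recovery at 8–10%; slope power at coupling 0.8; type-I
control at coupling 0, 1000 parameter-level replicates). Parameter-recovery
runs pin the recovered parameter across the cohort (population SD 0) while
keeping realistic frame- and trial-level noise: they are recovery
experiments against a single known truth.

# Limitations

* The simulator's response shapes (first-order rise/decay, single-rate
  learning) are the simplest forms consistent with published group
  time-courses; alternative dynamics would require new presets.
* Latency detection reports bin start times at 25 ms resolution; latencies
  are only meaningful to within one bin.
* The analysis trusts voice markers; no automatic onset refinement is
  attempted.
* Group SEM bands are computed over participant means (not trial-level
  pooling), one of two plausible readings of the source convention.

# A minimal session

```{r example}
library(fpl)

res <- run_pipeline(run_config(seed = 1, n_participants = 22))
res$compensation$summary   # per-condition peak compensation, t vs 0
res$compensation$latency   # group onset + peak latencies
res$adaptation$summary     # late-hold adaptation % per direction
res$stats$mid_whole        # whole ~ 1 + mid + (1 | participant)
make_report(res, "figures/")
```
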