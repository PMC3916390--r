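---
title: "Response-related contamination of the N400: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-related contamination of the N400: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpoverlap)
```

## The problem

In speeded-response semantic-priming experiments, subjects judge word-pair
relatedness with a button press while EEG is recorded. The stimulus-locked
ERP analysed for the N400 (a centro-parietal negativity around 300–500 ms,
larger for weakly associated targets) then also contains components tied
to the *decision and response* rather than to the stimulus: a P3 whose
latency tracks reaction time (RT), and motor-related potentials (MRPs)
around the button press. Because RT itself depends on association
strength (AS), these response-related components differ systematically
between AS conditions and can masquerade as — or mask — N400 effects.

`erpoverlap` provides the full chain needed to study this confound on
data with known ground truth: a component-based synthetic EEG generator,
the standard preprocessing chain, trial binning and ERP averaging,
single-trial P3-latency estimation by iterative Woody template matching,
and construction of latency/RT-matched trial groups in which the N400
can be read without P3 contamination.

## The generative model

Each subject × word-pair trial produces a behavioural record and a signal
segment inside a continuous multichannel recording (32-channel 10–20
montage plus an EOG channel; a reduced 9-channel posterior montage is
available for faster simulations).

**Stimulus list.** 800 word-pairs: 100 unrelated (AS = 0), 100 top
associates with AS uniform in 69–95, and 600 pairs whose log(AS) is
uniform between log 1 and log 69. AS is the count (out of 100 norm-study
participants) producing the target as first associate of the prime.

**Behaviour.** Speeded RT follows
`rt = a_s + b_s * log(max(AS, 1)) + e`, with subject-level intercepts
(`a_s ~ N(0.67, 0.05)` s) and slopes (`b_s ~ N(-0.04, 0.008)` s per
log-AS unit), trial noise SD 0.12 s, clipped to the 1 s response
deadline. These values are calibrated so that 8-way AS bins run from
roughly 0.49–0.51 s (strong associates) to 0.67–0.69 s (unrelated).
Delayed-condition responses are cued 1 s after target onset and drawn
around 1.26 s, independent of AS. The binary "related" judgement follows
a logistic in a *latent* log-AS predictor which maps AS = 0 to a finite
floor (−2) below log(1) = 0: unrelated pairs behave as weakly associable
rather than as log(0) = −∞, reproducing the sharp response-ratio break
between the AS = 0 block (~0.26) and AS = 1 pairs (~0.7) without
affecting the analysis models (which simply drop AS = 0 trials).
Misses occur at 3% (speeded) and 0.6% (delayed).

**Components.** Each component is a scalp topography × smooth waveform ×
amplitude rule × latency rule:

| component | latency rule | waveform | amplitude |
|---|---|---|---|
| P2 | stimulus + 0.20 s | Gaussian, SD 0.04 s | +5 µV, fronto-central |
| N400 | stimulus + 0.40 s | Gaussian, SD 0.09 s | −4.5 + 0.75·(latent log AS) µV, centro-parietal |
| P3 | RT + N(0, 0.05 s) | Gaussian, SD 0.09 s | +8 µV, posterior, slightly left |
| MRP ramp | response − 0.3 s → response | linear ramp | −2 µV, central |
| motor potential | response | Gaussian, SD 0.03 s | ±3 µV bipolar (left-posterior +, central-frontal −) |
| cue P2 (delayed) | cue + 0.30 s | Gaussian, SD 0.04 s | +4 µV, anterior-right |

Waveforms are smooth bumps because the analysis band is 0.5–15 Hz; the
P3 SD of 0.09 s (FWHM ≈ 210 ms) is mid-range for a P3b. The P3 latency
is *coupled to* but not equal to RT (50 ms Gaussian jitter), and no
decision-locked P3 is injected in the delayed condition by default. A
covert delayed P3 can be added through the `column` latency rule.

**Noise.** The background is an amplitude-modulated 10 Hz alpha rhythm
(8 µV RMS — the dominant ongoing rhythm at posterior electrodes, and the
very activity the matching pre-filter exists to remove) plus 1/f noise
normalized to 4.5 µV RMS within 0.5–50 Hz (≈3 µV of delta/theta-range
activity in the 0.5–6 Hz matching band, typical of awake task EEG). With
the default 8 µV P3 this puts the single-trial peak amplitude on the
order of the analysis-band (0.5–15 Hz) background RMS (~8.4 µV). Blinks
arrive as Poisson events (0.1/s, 120 µV) on the EOG channel and leak
into EEG channels with known frontal-dominant gains.

What the generator does **not** emulate: real electrode impedance
drifts, muscle and line noise, non-stationary alpha reactivity, latency
variability of the stimulus-locked components, subject fatigue, or any
linguistic structure beyond AS. Passing tests therefore demonstrate the
*methodology* on data satisfying the model's assumptions, not
performance on arbitrary real recordings.

## Preprocessing

The chain is fixed: 0.1–50 Hz 3rd-order Butterworth, applied forward and
backward ("two-way") so the net phase shift is zero → resample to 256 Hz
→ EOG regression (OLS leakage coefficients over the whole recording) →
0.5–15 Hz two-way Butterworth → epochs −0.1..1.5 s around target onset →
baseline correction (mean over the 0.1 s before onset) → rejection of
no-response trials.

Numerical choices the data formats leave open:

* **Edge handling.** Before filtering, signals are extended by odd
  reflection with padding ≥ 3× the filter's settling length (where the
  impulse response falls below 1% of its peak). Short-segment filtering
  with a 0.5 Hz high-pass is ineffective; see "Filtering before cutting"
  below.
* **Resampling.** The default 512 → 256 Hz step is integer decimation —
  the preceding 50 Hz low-pass already provides anti-alias protection.
  Non-integer ratios use polyphase resampling. Event indices are
  remapped by the rate ratio with round-half-away-from-zero.
* **Windows.** Epoch and baseline windows are half-open `[start, end)`
  in sample space; t = 0 is the sample at the lock event.

## Single-trial P3 latency: iterative template matching

On the Pz channel, filtered to 0.5–6 Hz to remove alpha:

1. take each trial's RT as the initial latency estimate;
2. cut ±0.5 s around the current estimates (edge-truncated cuts
   contribute their overlapping part) and average into a "P3-locked"
   template;
3. per trial, slide the template across every sample of the 0.35–0.9 s
   window and score the match;
4. find local maxima of the score sequence by derivative sign changes
   and take the largest positive one as the new estimate; trials with no
   positive local maximum keep their previous estimate, are flagged, and
   still feed the next template;
5. repeat 2–4 four times.

Design choices:

* **Alignment reference.** A score candidate marks where the template's
  own *peak* sits, so the estimate is the latency of the P3 peak itself.
  If the template were centre-referenced, a common offset between the
  initial estimates (RTs) and the true peaks would survive every
  iteration; peak-referencing absorbs it into the template. With
  noise-free single-bump data the estimator then recovers true latencies
  to within one sample even from biased initial estimates.
* **Score.** Normalized cross-correlation over the overlapping support
  (amplitude-invariant) by default; a raw sliding dot product (a matched
  filter) is available via `woody_config(score = "dot")`.
* **Filtering before cutting.** The 0.5–6 Hz filter is applied to the
  continuous signal (`woody_epochs()`), not to the 1.6 s epochs: a
  0.5 Hz two-way high-pass needs far more signal history than one epoch
  provides, and epoch-wise filtering measurably degrades recovery.
* **Ties** between equal maxima resolve to the earliest latency;
  plateaus are credited to their earliest sample.
* **Template re-use.** In the delayed condition RTs (~1.26 s) fall
  outside the search window and cannot seed the iteration, so the final
  speeded-condition template is used for the first matching pass, then
  refinement continues as usual. On that first pass, trials without a
  positive local peak fall back to the global score argmax (there is no
  previous estimate to keep) and are flagged.

Under the default noise model the estimator operates at the matched-filter
information limit: with the P3 amplitude equal to the analysis-band noise
RMS, an oracle given the *true* template and exhaustive search does no
better (in our validation runs, slightly worse) than the iterative
estimator. Accuracy is then limited by slow in-band noise, not by the
implementation; `p3_recovery_study()` reproduces this measurement.

## Matched trial groups

**Competition groups** select speeded trials where the N400 and the P3
latency pull oppositely: group 1 = low AS (≤1) *and* short estimated
latency (≤0.5 s); group 2 = high AS (≥18) *and* long latency (≥0.6 s);
groups 3–4 are the same subject/word-pair combinations from the delayed
condition. Combinations unavailable in the delayed condition are removed
from all groups *before* the seeded random discard that equalizes sizes,
so all four groups always end exactly equal. The AS and latency cutoffs
are package defaults (the reference values are not published) and are
arguments to `build_competition_groups()`.

**Fixed-latency groups** use the scoring function
`s = |rt − 0.65| + |p3 − 0.65|` (seconds; both targets late enough that
a P3 there no longer overlaps the 400–500 ms window). Per subject, the
75 lowest-scoring low-AS trials form the anchors; each anchor is then
greedily paired (ascending anchor score, without replacement, ties by
trial id) with the high-AS trial minimizing the score re-targeted to the
anchor's own RT and latency. The result is two groups of `10 × 75 = 750`
trials with closely matched RT/latency distributions, differing in AS.

A known limitation: because the high-AS pool is intrinsically *faster*
than the low-AS anchors (association speeds responses), score-minimizing
1:1 matching retains a small positive mean RT difference (typically
5–30 ms across seeds) — a support-mismatch property of the design that
no pairing algorithm can fully remove. The latency difference and the
N400 amplitude recovery are unaffected.

Because the whole chain is linear, the injected N400 contribution to a
windowed Pz mean equals the ground-truth peak amplitude times
`n400_window_factor()` — the window mean of the unit waveform passed
through the same filters. This is the reference against which the
matched-group contrast is validated.

## Statistics

All effects use one model family: `dependent ~ fixed` with by-subject
random intercepts *and slopes* and by-word-pair random intercepts,
fitted by REML. Group contrasts code membership ±1. t and p values use
the Satterthwaite degrees-of-freedom approximation (`lmerTest`); the
method is recorded in the result, and degenerate fits fall back
progressively (drop the subject slope → drop the item intercept → OLS),
with each fallback logged. Log-AS models exclude AS = 0 trials. Model
comparison is by log-likelihood on the identical trial subset.

## Problem sizes

The package's own validation (tests and `scripts/acceptance.R`) runs the
full behavioural design (10 subjects × 800 pairs, both conditions) and
simulates EEG on the reduced 9-channel montage at 512 Hz; the latency
recovery study uses 250 trials, and the group-contrast pipeline in the
test suite uses 6 subjects × 400 pairs. These sizes were chosen so a
complete validation runs on a laptop in minutes while keeping ≥ 500
trials per matched group in the full acceptance run.

## Worked example

```{r example}
library(erpoverlap)

pairs <- generate_stimulus_list(seed = 1)
profiles <- subject_profiles(10, "speeded", seed = 2)
behavior <- simulate_behavior(pairs, profiles, "speeded", seed = 3)
bin_trials(behavior[!behavior$missed, ], key = "as", n_bins = 8)$summary

# one subject end to end
tr <- behavior[behavior$subject_id == "S01", ]
sim <- simulate_eeg(tr, simulation_config("speeded",
                                          channel_names = default_montage(9)),
                    seed = 4)
rec <- bandpass_iir(sim$recording, 0.1, 50)
rec <- resample_recording(rec, 256)
rec <- regress_eog(rec)
epochs <- woody_epochs(rec, tr)
latencies <- estimate_latencies(epochs, epochs$trials$rt_s,
                                prefilter = FALSE)
cor(latencies$latency_s,
    sim$ground_truth$p3_latency_s[match(latencies$trial_id,
                                        sim$ground_truth$trial_id)],
    use = "complete.obs")
```
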