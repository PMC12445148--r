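---
title: "Measuring neural synchronization at nested auditory timescales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural synchronization at nested auditory timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisync)
```

## The paradigm

`multisync` implements a multiplexed auditory synchronization paradigm: a
single target stream that drives phase-locked EEG responses at several nested
timescales simultaneously, paired with melodic or spectrally matched noise
distractors, and the analysis chain that measures each response.

The target is a sequence of sinusoidally amplitude-modulated (SAM) tones
("tokens") on a 516.8 Hz carrier. Tokens are presented at 6.8 Hz; each token
carries one of five AM rates (27.2, 40.8, 54.4, 68, 81.6 Hz; nominally
27/41/54/68/82). Five tokens — one per AM rate, in some permutation — form a
cycle. A trial is a series of cycles that either stays random throughout
(*random–random*) or locks into one repeating permutation (*random–pattern*).
In the EEG the paradigm evokes:

* **FFR** — phase locking to the carrier's temporal fine structure
  (~517 Hz), which inverts with stimulus polarity;
* **EFR** — phase locking at each AM rate (27–82 Hz);
* **ECFR** — the *envelope change following response*, locking at the 6.8 Hz
  rate at which the AM rate switches between tokens;
* melody-beat and 19.5 Hz note-AM responses to the distractor;
* potentially, a sustained pattern-recognition shift after the transition
  from random to patterned context.

## Stimulus model and numerical choices

**Integer periods.** Every component frequency is an integer multiple of the
token rate: the carrier is 76 × 6.8 Hz and the AM rates are {4, 6, 8, 10, 12}
× 6.8 Hz. Each token therefore completes a whole number of carrier and AM
periods, which is what allows tokens to be concatenated without amplitude
discontinuities. We take the token duration to be exactly 1/6.8 s ≈ 147.06 ms;
a nominal "143 ms" would correspond to ~7.0 Hz and break the integer-period
arithmetic, so we treat the rate, not the rounded duration, as definitional.

**Digital realization.** A token is `n = round(fs / 6.8)` samples and all
phases are computed on the fractional grid `i/n`. The integer-period property
then holds *exactly* in the digital domain at any audio rate; effective rates
differ from nominal by under 0.005 % when `fs` is not a multiple of 6.8 Hz.

**Modulator phase.** The SAM modulator is cosine-phase starting at its
minimum, `(1 − cos 2πmf t)/2`, so every token begins and ends at zero
amplitude. Whether the original design used sine- or cosine-aligned
modulators is not determinable from the design constraints alone; the
endpoint-zero choice is the one that makes the click-free concatenation
guarantee structural rather than approximate. Concatenation quality is
audited by `concatenation_steps()`, which measures the jump between a token's
analytic endpoint (zero by construction) and the next token's first sample —
the quantity the integer-period design controls — rather than the one-sample
slope of the continuous signal across the boundary.

**Polarity.** Stimulus polarity alternates between cycles (sign inversion of
the rendered cycle). This deliberately splits the carrier line in the
long-term spectrum; `target_spectrum()` therefore undoes the per-cycle sign
before the FFT when verifying that the spectrum peaks at the carrier with
sidebands at carrier ± AM rates.

**Randomization.** Random cycles are uniform draws over the 120 permutations
of the five tokens, constrained so a cycle never opens with the previous
cycle's closing token (96 permutations when constrained). Pattern stimuli use
each of the 120 permutations once per context in a 240-trial block.

## Distractor design

The melodic distractor is a rule-based stand-in for a generative melody
source: a first-order Markov walk on the degrees of a C-major-pentatonic
scale, whole-beat note/rest durations, and a phrase filter that rejects any
melody in which a contiguous run of three or more notes occurs more than
twice. Design choices that were genuinely open:

* **Register.** Melodies must keep a 1/3-octave protected band clear around
  the target's outer sidebands: below (516.8 − 81.6)·2^(−1/3) ≈ 345.4 Hz and,
  after duplication three octaves up, above (516.8 + 81.6)·2^(1/3) ≈ 753.9 Hz.
  We additionally require the 19.5 Hz AM *sidebands* of every note to respect
  the band, and we restrict the low register to the top octave of the
  remaining range (~163–326 Hz). Below that, neighboring scale degrees sit
  ~12 Hz apart and a minor third nearly coincides with the 19.5 Hz sideband
  offset, so the melody and its matched noise could no longer share a
  magnitude spectrum bin-wise. The pentatonic scale (no semitone intervals)
  doubles the minimum line separation for the same reason.
* **Beat rate.** The melody beat rate is configurable with default 3.9 Hz, so
  each beat holds exactly five periods of the 19.5 Hz note AM, giving an
  integer number of SAM periods per note for any whole-beat duration.
* **Matched noise.** Each distinct note frequency (both registers)
  contributes a stationary sinusoid whose amplitude is the *proportion of
  note-carrying beats containing that note* — a linear amplitude rule. Linear
  scaling matches the linear magnitude spectrum (amplitude × coherent
  duration); it intentionally does *not* match total energy, which would
  require square-root weights and would break the spectral match for any
  melody with more than one distinct note. The melody's note/rest + SAM
  envelope is then imposed, so rests are exactly silent and the noise shares
  the melody's temporal envelope while its within-note frequency content is
  time-invariant.

## Behavioral session

Trials mix target and distractor at a requested SNR measured as broadband RMS
over the full stimulus (distractor rests included); an "active-portion"
reference is available as an option since the choice is not dictated by the
design. The speeded task's score counter starts at 1000 at audio onset and
reaches zero at the end of the response window; with only the endpoints
fixed, we spread the countdown linearly over stimulus duration + 1 s. The
no-response window is 1 s (configurable; descriptions of the task differ
between 1 and 1.5 s and we use the stricter value). Accuracy summaries use
rationalized arcsine units, RAU = (146/π)(asin√(X/(N+1)) + asin√((X+1)/(N+1)))
− 23, which maps X = N/2 to ≈50 and satisfies RAU(X) + RAU(N−X) = 100.

## The synthetic EEG generator

Because no public recordings accompany the paradigm, every analysis stage is
validated against a generator with known ground truth. It emulates:

* phase-locked sinusoids for each component, locked to their event class
  (FFR to carrier cycles with polarity sign, EFRs to token onsets at the
  token's AM rate, ECFR to token transitions, beat/note-AM components to the
  distractor beat grid — present only when a trial has a distractor);
* per-channel 1/f background noise with configurable spectral exponent
  (default 1) and RMS (default 1);
* a smooth random channel-gain topography (mastoids carry noise only);
* a per-trial attention state *g* ~ U(0, 1). Components can be coupled to
  attention: by default the target's ECFR scales with *g* and the distractor
  beat with 1 − *g*, while EFRs, the FFR, and the distractor's note-AM
  response are attention-independent — encoding, as a generative assumption,
  a target/distractor synchronization trade-off confined to the slow
  timescales. Response labels follow P(correct) = logistic(a + b·g) with
  defaults a = −1.5, b = 4 (≈60 % accuracy, comfortably above the 15 %
  error-rate inclusion threshold of the asymmetry analysis);
* graded distraction of the ECFR via per-condition gains (target-alone 1,
  matched noise 0.7, melody 0.45, following the observed ordering and rough
  ratio of the in-vivo effect);
* optional |ΔAM| scaling of the ECFR and an optional pattern-evoked sustained
  step for the corresponding recovery tests.

Component amplitudes default to 0.5 against unit noise — large relative to
genuine scalp responses, chosen once so that every peak is clearly supra-floor
at the epoch counts used here. What the generator deliberately does *not*
emulate: volume conduction from a forward head model, eye/muscle artifacts,
non-sinusoidal response morphology, latency jitter, or inter-subject
variability beyond the seeded topography. Passing recovery tests therefore
demonstrates correctness of the analysis arithmetic and of directional
inferences, not realism of effect sizes.

## Preprocessing

The fast pipeline band-passes 1–3000 Hz (zero-phase Butterworth, order 4) and
re-references to the mastoid average. Filters are realized as cascaded
second-order sections designed analytically from the pole layout
(`butter_sos()`): transfer-function coefficients of high-order Butterworth
filters are numerically unusable at cutoffs as low as 10⁻⁴ of the sampling
rate. Signals are extended by odd reflection over six time constants of the
slowest pole before `filtfilt`, so edge transients decay in the padding.

Bad channels are flagged by FASTER-style per-channel statistics — variance,
mean correlation with the other channels, and a rescaled-range Hurst
exponent — as robust (median/MAD) z-scores with threshold 3. Robust scoring
matters at small montage sizes: a gross outlier among eight channels inflates
a plain SD enough to hide itself. Flagged channels are excluded, not
interpolated.

Epochs are individualized per timescale: cycle-length (5/6.8 s) windows at
cycle onsets for the FFR; token-length (1/6.8 s) windows at the onsets of one
AM rate's tokens for that EFR; two-token windows for the ECFR; and beat-length
windows at distractor note onsets for the beat and note-AM responses.
Two-token windows are aligned to the starts of tokens 1, 3, 5, … (1-based), so
each window is centered on a token transition, windows never overlap, and a
60-token trial yields exactly 30 windows tagged with the signed AM jump they
span (8 classes: ±13.6, ±27.2, ±40.8, ±54.4 Hz, nominally ±14/27/41/54). An
option restricts analysis to the last six cycles of each trial, after the
pattern has repeated twice. Sample indices are 1-based with length-preserving
half-open windows.

## Phase-locking analysis

For each channel and FFT bin, PLV = |mean over epochs of the unit phasor of
the bin's phase|, aggregated as the RMS across retained channels. No taper is
applied: all component frequencies lie on (or within half a bin of) the
analysis grid by construction, and a rectangular window avoids leakage-phase
bias; a Hann option exists for imported data. For N uniformly random phases
E[PLV] ≈ √(π/4N), which the suite verifies at N = 50 and 300.

**Polarity handling.** The default FFR mode pairs consecutive
opposite-polarity cycle epochs and subtracts waveforms before the PLV:
envelope-locked activity cancels while carrier-locked activity survives. The
literal alternative — per-channel PLV(positive) − PLV(negative) — is also
implemented, but its expectation is near zero for any response with
polarity-symmetric statistics, so it cannot produce large carrier-locking
values and is kept for fidelity experiments only, not as the default.

**Noise floor.** The floor at a frequency of interest is the mean PLV over
unrelated bins within ±20 bins. "Related" frequencies are generated from the
paradigm arithmetic: the token rate and its first five harmonics, AM rates ±
two token-rate sidebands, the carrier and its AM sidebands ± two token-rate
sidebands, the beat rate and its first five harmonics (which include the
19.5 Hz note AM), and mains harmonics. Harmonic orders are bounded so that
even on the coarse token-window grid — where *every* bin is a token-rate
multiple — unrelated bins remain.

**Trial-count equalization.** Comparisons across conditions with unequal
trial counts subsample the larger sets to the smallest count over 600
bootstrap iterations and average the PLV across iterations, keeping noise
floors comparable. The ECFR-by-ΔAM analysis and the correct/incorrect
asymmetry index AI = (C − I)/(C + I) both run on equalized counts; a
participant contributes an AI only with ≥15 % error trials and at least one
category above their noise floor.

## Sustained response

The slow pipeline low-passes at 110 Hz (order 5) at the acquisition rate,
decimates to nominally 256 Hz (nearest integer factor), high-passes at 0.1 Hz
on the continuous decimated record — per-epoch high-passing at 0.1 Hz is
ill-defined when the corner period exceeds the epoch — re-references to the
scalp average, epochs each trial with a 1 s prestimulus baseline, rejects
trials whose average power exceeds the across-trial mean by two standard
deviations (single pass, upper tail only: the rejection exists to remove
movement artifacts, and low-power trials are not artifactual), low-passes at
30 Hz, and applies denoising source separation biased toward trial-repeatable
activity — whitening by the total covariance with a 10⁻⁹ relative rank
tolerance, eigendecomposition of the trial-average covariance in whitened
space, keeping the first five components. The sustained response is the RMS
across channels of the trial average.

The pattern statistic subtracts the mean over the two cycles before the
transition from the mean over the third and fourth cycles after it; its floor
is the distribution of the same statistic at 1000 uniformly drawn nominal
transition points (the count is our choice; only the procedure is fixed). The
step-recovery oracle injects a shift with zero-mean topography (a spatially
uniform shift carries no information past the average reference) and widens
the analysis band to 0.02–110 Hz, because a 0.1 Hz zero-phase high-pass
smears a sustained step over several seconds and the oracle is meant to test
the window arithmetic, not the filter's step response. The positive control
compares a random–pattern statistic against the bootstrap floor of a matched
random–random run, mirroring the paradigm's own control logic. With the
generator's default of *no* pattern-evoked shift, the statistic stays inside
its floor — the pipeline's null behaves as a null.

## Problem sizes

The test and reproduction scripts run the generator at 8 scalp channels plus
two mastoids, 2040 or 2048 Hz (multiples of the token rate, so analysis bins
fall exactly on component frequencies), 16–24 twelve-cycle trials per
condition, and 20 synthetic participants for the group-level asymmetry
recovery; class-structure checks that need a full 240-trial block run at
340 Hz with only the ECFR component active. These sizes are the package's
choices for a deterministic, quickly reproducible suite; all of them are
parameters, and nothing in the implementation assumes them.

## Known limitations

* The melody generator is a musical stand-in; it reproduces the distractor's
  *spectral* contracts, not the melodic statistics of a trained generative
  model.
* PLV floors assume the related-frequency list is complete; imported data
  with other periodic interference need the list extended.
* The simulator's sinusoidal, jitter-free responses make PLVs optimistic;
  absolute values are not comparable to scalp recordings.
* Absolute calibration (dB SPL), transducer compensation, and hardware
  timing variants are out of scope throughout.
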