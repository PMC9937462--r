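---
title: "Modeling speech motor control with divasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling speech motor control with divasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divasim)
```

## The model

divasim implements a DIVA-style model of speech motor control. Three ideas
define this model family:

1. **Targets are regions, not points.** A speech target specifies, for each
   moment of the production, per-dimension `[min, max]` bounds in auditory
   space (F0–F3, Hz) and somatosensory space (six place coordinates,
   pressure, voicing, each in [0, 1]). The error signal is the signed
   distance to the region — zero anywhere inside it — which gives the
   controller freedom within phonemically equivalent productions.

2. **Motor commands are articulator velocities.** The articulatory state is
   a 13-vector (10 vocal-tract shape parameters in [-1, 1], plus pitch,
   pressure and voicing source controls in [0, 1]) integrated by an Euler
   step `x + u * dt / 1000` and clamped to the state box *after*
   integration (the tie-break when a command pushes against a bound).

3. **Production combines feedforward and feedback control.** At each step
   the command is `alpha_ff * ff(t) + u_fb(t)`, where `ff` is the learned
   motor program and `u_fb` maps the *delayed* sensory errors through the
   damped pseudoinverse of the vocal-tract Jacobian, one solve per modality:
   `u_fb = alpha_fb_aud * pinv(J_aud) e_aud + alpha_fb_som * pinv(J_som) e_som`.
   Separate solves keep the two modalities' very different units (Hz vs.
   unitless) from fighting in a single least-squares problem.

The vocal tract itself is a *static forward fit*: formants and place
coordinates are squashed-affine functions of the shape parameters, with F0,
pressure and voicing passing through from their source controls. This is
not a physical (area-function) simulation; it preserves the contract a
pseudoinverse controller needs — a smooth, range-bounded map with an exact
closed-form Jacobian — while staying fully testable. The inverse map uses
the analytic Jacobian at the current state; there is no babbling phase.

## Learning

After each production the feedforward program absorbs the feedback:
`ff(t) <- ff(t) + lambda_learn * u_learn(t)`, where `u_learn(t)` is the
feedback command generated by the error measured *at* step `t`
(time-aligned), not the delayed command actually issued at `t`. The
distinction matters: commands issued during the first `tau_aud` = 100 ms of
a trial respond to no error at all, so crediting learning with the issued
trace would leave the start of every program permanently untrained and put
a hard floor of `tau/duration` on the achievable error. Assigning credit at
the time of the error — the standard delay compensation in feedforward
motor learning — lets the whole trajectory converge. A production that
stays inside its target region everywhere generates a zero trace, so a
well-learned program is a fixed point of the update.

`lambda_learn` defaults to 1.0: full incorporation of the iteration's
feedback, the simplest rule with the zero-error fixed point. Fractional
rates converge too, but they slow the elimination of the oscillatory
transients that the 100 ms feedback delay excites, enough that two of the
built-in targets only reach their error plateau near iteration 20.

With the default gains, resetting the weights and retraining for 20
iterations on any built-in target gives a mean auditory error that falls
monotonically over iterations 1–3, plateaus (successive change below 1% of
the initial error) before iteration 20, and ends below 10% of its
iteration-1 value. The early iterations converge fastest late in the trial
(where integrated corrections accumulate); the very first control steps
converge slowest, which is why the per-iteration error keeps creeping down
long after the production is perceptually on target.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `control_dt` | 5 | ms | control step of targets and programs |
| `alpha_ff` | 1.0 | — | feedforward gain |
| `alpha_fb_aud` | 1.0 | 1/s | auditory feedback gain |
| `alpha_fb_som` | 0.5 | 1/s | somatosensory feedback gain |
| `lambda_learn` | 1.0 | — | learning rate |
| `lambda_reg` | 1e-4 | — | pseudoinverse damping |
| `tau_aud`, `tau_som` | 100, 50 | ms | sensory delays (ring buffers; zero error before a delay elapses) |
| `sample_rate` | 11025 | Hz | audio rate (> 2 x highest formant bound) |
| `bandwidths` | 80/100/120 | Hz | F1–F3 resonator bandwidths |
| `jitter_sigma` | 0.01 | — | relative per-frame F0 perturbation (0 in deterministic mode) |
| `noise_floor` | 0.02 | — | aspiration noise amplitude |

The auditory ranges of the default forward fit are F0 75–240, F1 250–900,
F2 950–2800, F3 2850–4200 Hz: non-overlapping and ordered, roughly adult
speech. The feedback gains have units of 1/s because the pseudoinverse
output is a state-space displacement; a gain of 1.0 means "correct the
full error in one second", deliberately gentle relative to the 100 ms
delay so the delayed loop stays well damped.

## What the built-in targets are (and are not)

No numeric target bounds are shipped from any external source. Every
built-in target ('i', 'u', 'e', 'ae', the multi-segment 'happy', and
'example', which has no pretrained program) is generated from a fixed
prototype articulatory configuration pushed through the default forward
fit, with relative margins of ±6–12% around the resulting formants
(`make_reachable_target()`). This guarantees the region intersects the
forward map's image — the condition under which the learning-progress
properties are meaningful. The vowels are 1200 ms sustained postures,
matching sustained-phonation recordings and keeping the 100 ms sensory
delay a small fraction of the trial.

Consequently, passing tests demonstrate the *control and learning
machinery* on reachable region targets; they do not demonstrate fidelity
to any particular natural vowel system, to real articulatory-acoustic
mappings, or to consonantal dynamics. Pretrained programs for the built-in
targets are derived reproducibly at run time by the 20-iteration protocol
(`builtin_program()`, cached per session) rather than shipped as data.

## Audio synthesis and extraction

The synthesizer is a classic source-filter design. The voiced source is a
band-limited harmonic pulse train with 1/k rolloff (phase accumulated per
sample, so F0 changes are continuous and the spectral peak is the
fundamental); the unvoiced source is seeded white noise. Excitation is
`voicing * pulse + (1 - voicing + noise_floor) * noise`, scaled by pressure
and by a 20 ms linear onset ramp that prevents onset clicks. It is filtered
by three cascaded two-pole resonators at (F1, F2, F3), coefficients updated
per control frame and filter state carried across frame boundaries (a
chunked recursion that is sample-exact against a single-pass filter when
coefficients are constant). Waveforms are peak-normalized to [-1, 1].

Extraction reverses the path with standard signal processing: pitch by
normalized autocorrelation (40 ms frames, 10 ms hop, search 75–500 Hz,
voicing threshold 0.3, parabolic peak interpolation), formants by LPC
(resample to 11025 Hz, pre-emphasis 0.97, 25 ms Hamming frames, order 12,
roots kept when bandwidth < 400 Hz and frequency in 90–5000 Hz; frames
with fewer than three qualifying roots are invalid).
`build_target_from_audio()` turns the voiced-span medians into a
single-segment region of relative half-width `tolerance` (default 5%).

Numerical details that matter:

- The autocorrelation is unbiased (divided by `n - lag`) before peak
  picking so the taper does not drag the peak toward short lags; among
  near-equal peaks the *shortest* lag wins (a periodic signal peaks at
  every multiple of its period; preferring the shortest avoids
  octave-down errors).
- LPC coefficients come from a Toeplitz solve of the autocorrelation
  equations; degenerate frames (zero energy, singular systems) are flagged
  invalid rather than extrapolated.
- The damped pseudoinverse uses the `t(J) solve(J t(J) + lambda I)` form;
  with `lambda = 0` an SVD pseudoinverse with a numerical-rank cutoff is
  used instead. Sums over motor dimensions follow index order in double
  precision.

Round-trip accuracy through the package's own synthesizer is within ±2 Hz
(median pitch) and ±5% (median formants) — the basis of the
target-from-audio protocol: build a target from a recording, train 4
iterations, and the 5th production's median trajectory lies inside the
target bounds.

## Determinism and seeds

One master seed lives in `run_config()`; the pitch-jitter and noise
streams are derived from it (+1000, +2000) and evaluated with
save/restore of the caller's RNG state. `deterministic = TRUE` forces
`jitter_sigma = 0`. Two productions with the same configuration and seed
are bit-identical — traces, waveforms, and a motor-command normalized RMSE
of exactly 0% — which is the precondition for meaningful cross-run
comparisons.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 1200 ms
targets (240 control steps), 20 training iterations per target, 50–100
random draws for the Jacobian and pseudoinverse oracle suites, and 1–2 s
waveforms for the extraction checks. These sizes give stable statistics
(learning ratios change by < 0.1 percentage points across seeds) while
keeping a full run under ten seconds.

## Limitations

- The vocal tract is a static fit, not a time-domain acoustic simulation:
  no nasal tract, no consonantal constriction dynamics, no area functions.
- Inverse maps are analytic; the developmental (babbling) acquisition of
  inverse models is out of scope.
- Only sustained single-segment targets can be extracted from audio;
  connected speech segmentation is out of scope.
- Perceptual speech-quality models (PESQ and the composite CSIG/CBAK/COVL
  raters) are not implemented; `paired_stats()` accepts externally
  computed metric columns, and only segmental SNR is computed natively.
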