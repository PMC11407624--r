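---
title: "Stimulus design, simulation and frequency detection for SSVEP brain-machine interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus design, simulation and frequency detection for SSVEP brain-machine interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A steady-state visual evoked potential (SSVEP) brain-machine interface
presents several icons flickering at distinct frequencies; attending to one
of them entrains occipital cortex at that frequency and its harmonics, and
the interface decodes the attended icon from the EEG. `ssvepbmi`
implements the full chain for a four-target, low-frequency
(6.67/7.5/8.57/10 Hz) system of the kind used for in-vehicle control on a
head-up display: frame-exact stimulus design under a 60 fps refresh-rate
constraint, a synthetic EEG generator that reproduces the phenomenology
the analysis assumes, preprocessing and channel selection, frequency
detection by PSDA, CCA and FBCCA, and evaluation (accuracy curves,
confusion matrices, information transfer rate, paired condition tests).

Everything downstream of the generator is agnostic to where the recording
came from; the generator exists because no public recordings accompany
this class of experiment, and synthetic sessions with known ground truth
let every stage be tested quantitatively.

## Frame-based stimulus design

A display refreshing at $F$ frames per second can only realize a flicker
frequency $f$ as an integer number of frames per cycle, $m = F/f$; the
four target frequencies correspond to $m = 9, 8, 7, 6$ at 60 fps. Each
split of the cycle into $k$ leading ON frames and $m-k$ OFF frames
realizes a duty cycle $k/m$. Because the realizable duty cycles are
quantized, they are grouped into four bins ([14–25], [28–38], [45–57],
[62–72] percent), with membership decided on the percentage rounded
half-up — the half-up rule is required for splits such as $3/8 = 37.5\%$
and $5/8 = 62.5\%$ to land in their intended bins. Splits falling outside
every bin (e.g. $4/9 = 44\%$) are reported as unbinned. A small relative
tolerance (0.5%) is applied to the divisibility requirement because the
nominal frequencies are printed as rounded divisors (60/9 = 6.667 Hz is
labelled 6.67 Hz).

The spectral consequence of the duty cycle follows from the Fourier series
of a unit rectangular pulse with ON fraction $d$:

$$\mathrm{dc} = d, \qquad |A_n| = \frac{2\,|\sin(n\pi d)|}{n\pi}.$$

At $d = 1/2$ every even harmonic vanishes, concentrating energy at odd
multiples of $f$; at $d = 1/k$ the $k$-th harmonic vanishes. The
implementation is verified against a dense-FFT oracle of the sampled
waveform (65 536 samples per period, relative tolerance $10^{-6}$).

Viewing geometry is plain trigonometry: a length $s$ viewed frontally
from distance $d_1$ subtends $\arctan(s/d_1)$ degrees; for a square icon
of area $A$, $s = \sqrt{A}$. A 36 cm² icon at 95 cm subtends 3.6°. Icon
eccentricity uses the same formula with the icon's offset $d_2$ from the
fixation point. Only the degree values of the published icon sizes are
treated as normative; the accompanying arcminute figures are internally
inconsistent with the stated degrees and are ignored.

The quality of a rendered stimulus is summarized by
$\mathrm{SNR} = 10\log_{10}(P_{\text{signal}}/P_{\text{noise}})$ measured
on a photodiode-style luminance trace: periodograms of 4-s rectangular
segments (50% overlap) are averaged, giving an exact 0.25 Hz grid; signal
power is the target (or 2nd-harmonic) bin and noise power the mean of the
six neighbouring bins at ±0.25 k Hz, mirroring the EEG-side statistic.
With a noiseless tone the neighbourhood power is zero and the report is
capped at a documented ceiling of 200 dB. Traces are classified high-SNR
above 50 dB, midway between the nominal 30 dB (dirty) and 70 dB (clean)
rendering conditions.

## The synthetic EEG generator

`sim_config()` fixes the study conditions; `generate_session()` realizes
them. Defaults, chosen once as values a practitioner would call typical
for gelled scalp EEG:

| parameter | default | rationale |
|---|---|---|
| channels, rate | 16 ch (10–20 montage), 500 Hz | the headset the analysis targets |
| trial timing | 2 s cue + 1 s fade (idle), 5 s flicker, 1 s fade | 9 s trial pitch; every onset has 3 s of pre-onset idle |
| background | $1/f^{1.5}$, 10 µV RMS | scalp EEG broadband level and slope |
| alpha intrusion | 10 Hz, ~1 Hz bandwidth, 3 µV RMS | spontaneous posterior alpha; deliberately collides with the 10 Hz target |
| line noise | 60 Hz, 2 µV | removed by the notch; exercises the filter |
| SSVEP | 2 µV fundamental, decay 1 : 0.5 : 0.25 | few-µV steady-state responses with declining harmonics |
| topography | O* 1.0, PO* 0.8, parietal 0.3, frontal 0.05–0.15 | posterior dominance of visual responses |
| phase | random per trial; fixed per-channel lag ≤ 10 ms | volume conduction with small timing spread |

The SSVEP component is stored alongside the data so that attention
manipulations can rescale it exactly. An inattentive trial multiplies the
SSVEP amplitude by 0.2 — enough to make the response visibly weaker
without removing it entirely.

The low-stimulus-SNR condition adds, during stimulation only and with the
posterior topography: a 3 µV competing 10 Hz component (the classifier
confound — a persistent alpha-band distractor) and 7 µV sidebands at
jittered 1–2 Hz offsets around the fundamental and, at 70% amplitude,
around the 2nd harmonic (an imprecise rendering corrupts the harmonic as
well). Two calibration notes. First, the offsets sit at the *shoulder* of
the SNR statistic's ±0.75 Hz neighbourhood: with 1-s Hann Welch segments
the window mainlobe spans ±2 Hz, so components much closer than ~1 Hz
leak more power into the target bin than into its neighbourhood and would
*raise* the statistic rather than lower it; offsets of 1–2 Hz match the
spurious rendering peaks observed roughly 1 Hz from the target in practice.
Second, the sideband amplitude is set so the condition depresses the mean
spectral SNR by at least 2 dB — the margin the condition is defined to
produce — which the acceptance suite measures at ≈2.6 dB.

What the generator does **not** emulate: eye-blink and movement
artifacts, electrode drift and impedance changes, inter-subject
variability, non-stationary alpha reactivity, or any latency between
flicker onset and cortical entrainment. Passing tests therefore
demonstrate correctness of the pipeline's computations and its
qualitative behaviour under controlled signal/noise manipulations — not
performance on real recordings.

## Preprocessing

Filtering is zero-phase throughout (forward–backward application), since
CCA is phase-sensitive: a biquad notch at 60 Hz (Q = 35) followed by an
order-4 Butterworth band-pass, 4–40 Hz. The band-pass attenuates a 60 Hz
probe by well over 30 dB and passes 10 Hz within 5%.

Segmentation takes, per event, the 3 s ending at onset as the idle
baseline and up to 5 s from onset as the stimulation window. Trials
without enough surrounding data are skipped with a warning naming them; an
error is raised only when no trial survives.

Channel selection computes the spectral SNR statistic (below) per channel
and trial at each trial's own target frequency, for idle and stimulation
windows, then runs a one-sided paired t-test per channel and keeps
channels significant at α = 0.01 ranked by mean SNR increase, with a
top-8 cap applied after significance. α = 0.01 and k = 8 reproduce the
selection regime that retains the eight parieto-occipital/occipital
sites. Because the cap is applied after significance, an occasional
false-positive frontal channel cannot displace a genuinely responsive
posterior one.

## Detection

**Spectral statistic (PSDA).** Power spectra use Welch's method with 1-s
Hann segments and 50% overlap. The SNR statistic is defined on a 0.25 Hz
grid, which a 1-s segment does not natively provide; each segment is
therefore zero-padded fourfold before the transform, preserving the
stated window and overlap while interpolating the grid. The statistic at
target $f$ is

$$\mathrm{SNR}(f) \;=\; \frac{6\,y(f)}{\sum_{k=1}^{3} y(f{+}0.25k) + y(f{-}0.25k)}
\;+\; \frac{6\,y(2f)}{\sum_{k=1}^{3} y(2f{+}0.25k) + y(2f{-}0.25k)},$$

exactly 2 on a flat spectrum. One consequence of the 1-s segments is
worth stating plainly: the Hann mainlobe (±2 Hz) covers the entire
±0.75 Hz neighbourhood, so a tone's own leakage inflates the denominator
and each term saturates near ~1.4 even for a very strong response. The
statistic remains a valid *comparative* measure (stimulation vs idle,
condition vs condition, channel vs channel) — which is how it is used —
but its absolute increments are compressed relative to an estimator with
true 0.25 Hz resolution. Each term is capped at $10^6$ so ideal line
spectra stay finite. PSDA classifies by the argmax of the statistic over
candidates; it is the weakest of the three detectors here, as expected
from the compression.

**CCA.** For candidate $f$, the reference template stacks
$\sin(2\pi n f t), \cos(2\pi n f t)$ for $n = 1..N_h$ ($N_h = 3$;
fundamental, 2nd, 3rd harmonic) at $t = 1/f_s, \dots, N/f_s$. The first
canonical correlation ρ between the channel space and the template space
is computed by centring both sets, orthonormalizing with QR
decompositions and taking the largest singular value of
$Q_x^\top Q_y$ — the standard numerically stable route. Rank-deficient
inputs fall back to their effective rank with a warning. ρ is invariant
to per-channel affine rescaling, and the implementation is cross-checked
in the tests against an independent canonical-correlation routine. The
candidate with the largest ρ wins; exact ties resolve to the lowest
candidate frequency (deterministic and documented). Windows start at
stimulation onset; no visual-latency offset is applied.

**FBCCA.** Each window is decomposed by zero-phase Chebyshev Type I
band-passes; subband $n$ passes $n\,k$–40 Hz with a 2 Hz transition
margin added to both sides at design time (order 4, 0.5 dB ripple — a
small unstated ripple chosen for flat passbands). Defaults: 5 subbands,
$k = 6$ Hz, weights $w(n) = n^{-1.25} + 0.25$, all recorded in
`filter_bank_config()` and overridable. Scores combine as
$\tilde\rho_i = \sum_n w(n)\,\rho_{n,i}^2$. On harmonic-rich signals
FBCCA beats plain CCA, most visibly at short windows; on
weak-harmonic signals at long windows the extra subbands mostly add
noise and plain CCA can be the better choice — both behaviours appear in
the analysis scripts.

## Evaluation

Accuracy is summarized per method and window length, with dispersion
taken across blocks (one block = one presentation of all four targets),
and converted to an information transfer rate
$\mathrm{ITR} = \frac{60}{T}\left[\log_2 N + p\log_2 p +
(1-p)\log_2\frac{1-p}{N-1}\right]$ bits/min. $T$ is taken as the
analysis window length only — no cue or gaze-shift overhead is added; the
convention is recorded in the summary so alternative accounting can be
applied downstream. The $p\log_2 p$ term is 0 at $p = 0$; the formula is
0 at chance and, although it mathematically rises again below chance, it
is clamped to 0 there (the standard convention — a below-chance classifier
conveys no usable information without relabelling). The default window
grid is 0.5–5 s in 0.5 s steps.

Condition comparisons test the paired differences for normality
(Shapiro–Wilk at 0.05) and use a paired t-test when normal, a Wilcoxon
signed-rank test otherwise. Two degenerate cases are handled explicitly:
identical samples return p = 1 (no evidence), and a constant non-zero
shift — where the t statistic is undefined and normality untestable —
routes to the signed-rank branch with a warning. Stars follow the
reporting convention `*` for p < 0.01 and `**` for p < 0.05 (note the
inversion relative to the more common convention; it is kept for
consistency with the reporting style this package mirrors).

## Numerical and design choices

- Duty-cycle rounding is half-up (`floor(x + 0.5)`); base `round()`'s
  half-even rule would misplace 37.5% and 62.5%.
- ON frames lead each flicker cycle; only contiguous ON blocks are
  generated.
- The background generator shapes white noise in the frequency domain
  ($|H(f)| \propto f^{-\gamma/2}$, flattened below 0.5 Hz) and rescales
  to the target RMS; the alpha intrusion is white noise band-passed to
  ~1 Hz around 10 Hz.
- `generate_session()` seeds R's RNG; identical seed and configuration
  give bit-identical output, and the pipeline writes a 32-bit FNV-1a hash
  of its effective configuration into every output table.
- Sub-1 s windows are evaluated by CCA/FBCCA only; PSDA needs a full 1-s
  Welch segment.

## Problem sizes used by the test and acceptance suites

Simulated checks use sessions of 40–104 trials (10–26 blocks of four
targets): 52 trials per point for the amplitude sweep and condition
contrasts, 100 trials for the FBCCA/CCA pairing, 200 permutations for
the CCA null, 20 seeds for the stimulus-SNR recovery property. These
sizes put binomial/statistical error comfortably below the effect sizes
being asserted while keeping a full run in a few minutes.

## Known limitations

- The Eq.-style SNR statistic's absolute dB increments are compressed by
  the 1-s-segment Welch design (see above); comparisons are unaffected.
- PSDA accuracy is modest by construction; it is included as a
  comparative baseline, not a competitive detector.
- The simulator's idealizations (no artifacts, stationary noise, fixed
  latency) mean synthetic accuracies should not be read as predictions of
  human-subject performance.
- European Data Format input is not parsed; recordings enter either
  through the simulator or the delimited text container.
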