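---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model behind each module, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. No empirical claim is made
here that the test suite does not itself compute.

## 1. Signal model and convolutional unmixing

Dual-channel optical voltage recordings pair a GEVI channel `G(t)` with a
voltage-insensitive reference channel `R(t)`. Heartbeat and hemodynamic
fluctuations modulate both channels, but hemoglobin dynamics act as a linear
dynamical system between the two fluorescence bands, so the artifact in the
voltage channel is modeled as a *convolution* of the reference trace:

    G(t) = V(t) + H(t),  H = F * R.

`estimate_wiener_filter()` cuts both traces into segments of duration `tau`
(default 1 s; 0.5–2 s is the useful range — longer segments buy spectral
resolution at the cost of estimator variance), overlapping by 75%, tapers
each with a Hann window after per-segment mean subtraction, and forms

    f(w) = <g_k r_k*> / <r_k r_k*>

averaged over segments. Mean subtraction before tapering resolves an
ambiguity in the procedure (whether a DC term is excluded per segment); the
DC bin of a mean-subtracted, Hann-tapered segment carries no information, so
the choice is inert except for numerical hygiene.

**Amplitude clipping.** Where the reference spectrum is weak, the raw ratio
can explode. The filter amplitude is therefore capped at `alpha * |f(w0)|`,
phase preserved, where `w0` is the heartbeat fundamental — the frequency at
which the two channels are most strongly and reliably coupled, so `|f(w0)|`
acts as a data-driven scale for "plausible coupling". `alpha` defaults to
1.1 (1.0–1.3 reasonable). `w0` is the Welch-PSD argmax of the reference in a
configurable band (default 8–14 Hz, bracketing the murine heart rate); a
flat spectrum raises an error asking for a manual `w0` rather than guessing.
Zero-power reference bins get `f = 0` (counted in diagnostics) so sparse
spectra do not abort runs.

**Kernel and application.** The kernel is the inverse DFT of the clipped
`f`, re-ordered so zero lag sits at the center: hemodynamic lags between
channels can take either sign, so the filter is deliberately two-sided
(non-causal). `unmix_trace()` applies it by linear (non-circular)
convolution with odd-reflection padding and returns `V = G - H`; samples
within half a kernel of the edges are flagged. `V + H = G` holds to machine
precision by construction.

**Parameter selection.** `select_params()` follows the stated recipe
literally: estimate on the first half, apply to the second half, minimize
the variance of the unmixed test trace. That objective is slightly biased
against true signal variance; an alternative masked objective was considered
and rejected as an unprescribed complication. Ties break toward smaller
`tau`, then smaller `alpha`.

**Movies.** `unmix_movie()` runs two passes. Pass 1 estimates the filter
between spatially averaged channels (tiles of `prefilter_scale`, default
1 mm; the whole field when smaller) and removes the predicted artifact per
pixel — spatial averaging boosts reference SNR because hemodynamic artifacts
do not travel. Pass 2 unmixes each pixel's reference against its pass-1
residual, capturing vessel-to-vessel phase heterogeneity. Tiled averaging
with the global mean as degenerate case resolves the unspecified averaging
geometry.

## 2. Preprocessing

All recursive filters are Butterworth designs applied forward–backward
through second-order sections (quoted orders are single-pass), with
odd-reflection padding of three effective impulse-response lengths and
DC-matched initial conditions; symmetric pulses keep their peak sample
exactly. No DSP package in the target environment provides these, so the
design chain (analog prototype, band transforms, bilinear transform, SOS
pairing) is implemented in the package and validated by tone-response tests.

Baseline estimation (`estimate_baseline`) offers the 4th-order, 0.5-Hz
low-pass route and 1–3-term exponential fits. The exponential fits use
variable projection (amplitudes and offset solved linearly per candidate
time-constant set; only log time-constants are optimized, multi-start) —
materially more robust than joint nonlinear fitting for the very stiff
tri-exponential bleaching curves (time constants of ~26 s, ~300 s and
~5.5 h differ by three orders of magnitude). The half-life is solved
numerically from the full fitted curve including its offset.

Decrosstalking comes in the two forms the data need: fiber recordings
regress band-passed traces (3rd-order, 3–7 Hz cortical / 5–9 Hz hippocampal
defaults) and subtract the scaled raw donor; movies subtract a known
bleed-through fraction (defaults 0.07 for ASAP3, 0.095 for Ace-mNeon1,
selectable by name). Only the dominant crosstalk direction is corrected by
default; the reverse direction is configurable but off.

## 3. Spectral analyses and conventions

- **Coherence** is magnitude-squared (matching the conventional routine's
  semantics), 1-s Hann segments overlapping by 0.8 s. The phase convention
  is fixed by the delay test: `y` delayed by `d` gives slope `-2 pi f d`.
  For the independent-noise bias test the expectation `E[msc] = 1/K` holds
  for non-overlapping segments, so that test uses `overlap = 0`.
- **Wavelet spectrograms** use an analytic Morlet (center frequency 6 rad)
  on a log-spaced grid, normalized so a unit sinusoid's ridge magnitude is 1
  away from the cone of influence (one e-folding time from the edges). Any
  analytic wavelet meeting that tone calibration would be conformant.
- **Band envelopes** are either the mean spectrogram magnitude across the
  band (wavelet route, the default for CFC) or `|hilbert(bandpass(x))|`.
- **Event-related averages** drop and count events clipped by the record
  edge; confidence bands are percentile bootstrap (1000 resamples, seeded)
  or a normal approximation.

## 4. Cross-frequency coupling

The phase convention is **0° = carrier trough** (greatest hyperpolarization
for depolarization-positive traces); the analytic-signal phase is rotated by
180° accordingly, so the carrier peak sits at 180°. A "phase reset" — the
cycle boundary used to align cycles — is implemented as the wrap crossing of
the trough-referenced phase; the source procedure names the concept without
defining it. Per-bin averaging is over single cycles, tiled to 720° for the
two-cycle display (whether the original display averaged two-cycle windows
is unknowable from the text; tiling is the conservative reading). The phase
may be taken from a separate trace (e.g., an LFP) for optical-amplitude /
electrical-phase coupling. `amplitude_peak_offsets()` reports per-event
envelope-peak minus carrier-peak times with a signed-rank test.

## 5. Event detection

`find_peaks()` reimplements the conventional findpeaks semantics: plateau
middles, prominence to the higher flanking minimum (searched to the nearest
higher sample or the edge), widths at half prominence with linear
interpolation, greedy largest-first distance pruning. A brute-force oracle
in the test suite matches it exactly on randomized signals.

Ripples: 120–200 Hz 3rd-order zero-phase band-pass, squared, 20-ms moving
maximum, 20-ms centered moving average, min–max rescale to [0, 1], peaks
with prominence 0.1 / distance 10 ms / width 10–200 ms, 300-ms windows.
**Known limitation, deliberately left visible:** on ripple-free noise the
min–max rescale manufactures a unit-scale maximum and the smoothed noise
NSS fluctuates well above 10% of it, so the detector fires hundreds of times
per minute on pure white noise. That false-positive clause of the acceptance
criteria is therefore red, and the corresponding real-data workflow relies
on manual curation (out of scope here; exportable event snippets are the
substitute). Detection of genuine bursts (5x background RMS) is exact and
gain-invariant.

Ictal spikes use a 25-Hz 6th-order high-pass and 2–20-ms / 1000-µV peak
criteria; units must be declared. Locomotor state is the smoothed theta
envelope against an absolute or quantile threshold with short-bout merging.
Movie wave events threshold the field-mean trace at `mean + 3 sd`.

## 6. Traveling-wave velocimetry

Two routes, cross-validated against each other on noiseless waves:

**A. Seed-pixel delay maps.** Normalized cross-correlation of the seed
trace with every pixel, with *lag-dependent* normalization (energies of the
overlapping segments) — with global normalization the overlap shrinkage
biases peaks toward zero lag and inflates speeds by several percent, which
the tests demonstrated directly. Sub-sample lags via 3-point parabolic
interpolation. Delays below the correlation threshold `x_min` (default
0.75, range 0.6–0.9) are masked. A least-squares plane `tau = Ax + By + C`
yields the wavefront velocity in **two conventions**: the component-wise
reciprocal `v = (1/A, 1/B)` common in optical-mapping reports, and
plane-wave kinematics `v = (A,B)/(A^2+B^2)`. These
disagree off-axis (for `tau = 0.01x + 0.01y`: speeds 141 vs 71 mm/s); the
gradient convention is the package default for physical correctness; the
reciprocal convention is selectable for comparability with reports that
use it. This is the single most consequential convention choice in the
module.

**B. Space-time projections.** The movie is averaged over rows and over
columns; per position the time of the (first) maximum is robust-regressed
(IRLS, bisquare) on position, giving slowness components in s/mm; speed is
`1/|alpha|`, direction `atan2(a_y, a_x)`. Optional crest refinements —
a zero-phase moving average of about a quarter wave period and a
least-squares quadratic vertex around the maximum — recover sub-frame peak
times on noisy movies without biasing the crest; they are what lets a
300-frame, SNR-2 movie resolve 300-mm/s waves on an 8-mm field. Acceptance
of an event defaults to a joint chi-square test on `(a_x, a_y)` at
`p < 0.01`; the per-component rule (both individually significant), which
rejects axis-aligned waves, is available as a strict mode. Degenerate peak
times give `alpha = 0`, `p = 1`, rejected.

Harmonic-vs-CFC separability uses co-propagation: a band that is a true
harmonic travels with the carrier's speed and direction; an independently
propagating band does not. This is asserted on constructed movies.

## 7. Indicator-delay decomposition

Seven experiments, each assigning an ordered indicator pair to two cell
classes, yield apparent delays `d + delta(i1, class1) - delta(i2, class2)`.
The fit minimizes inverse-variance-weighted squared error plus
`lambda * P(delta)` with `delta >= 0` (projected L-BFGS-B, multi-start).
The source text calls the regression "L1-regularized" but describes the
Euclidean norm of the 6-vector; both are implemented, **euclidean is the
default** because it matches the described formula. `lambda = 0.01`.

Identifiability: shifting all class-1 deltas by `+c` and `d` by `-c` (and
the class-2 mirror) leaves predictions unchanged — a two-dimensional gauge.
The penalty plus nonnegativity pin the solution at the representative whose
per-class minimum delta is at the boundary, which is also how the
physiological delay becomes estimable in practice (one indicator's delay is
near zero). The synthetic generator therefore draws its default truth with
per-class minima at ~0; recovery tests would be meaningless otherwise.
Resampling draws each experiment's mean from `Normal(mean, sd/sqrt(n))`
(the sampling distribution of a mean); drawing with the printed sd is a
flag, since the source is ambiguous about which deviation its weights
describe.

## 8. The synthetic world

`gen_trace_pair()` builds both channels multiplicatively on a bleaching
baseline — `B(t)(1 + V + artifacts) + noise` — matching the small-signal
(≤1% dF/F) regime in which detrending linearizes artifacts additively.
Heartbeat artifacts enter through per-harmonic complex gains per channel, so
the implied transfer `h(w) = g_gevi/g_ref` is known exactly; the default is
a 10.5-Hz fundamental with three harmonics and a 60° inter-channel phase
lag, 1% amplitude, with 0.05% Gaussian noise per channel — the conditions
the acceptance criteria state. Voltage content is a 0.5% dF/F 40-Hz
oscillation by default, with optional phase–amplitude coupling
(`gamma * (1 + m cos(theta - phi0))`) and Gaussian-windowed 150-Hz ripple
bursts. Noise is Gaussian (a shot-noise approximation at these photon
budgets); a Poisson mode is not provided because no test discriminates it.

`gen_movie_pair()` evaluates plane waves `sin(2 pi f (t - a_x x - a_y y))`
on the pixel grid (the delay map is shifted so its minimum is zero — a pure
time-origin choice that keeps every pixel's first crest inside the movie for
all propagation directions), plus optional rank-k smooth backgrounds and
spatially patterned heartbeat artifacts in the reference channel. The
velocimetry grid uses 64 px at 0.125 mm/px — the instrument's ~8-mm field —
because a 3-mm field cannot resolve 300-mm/s waves at 300 Hz regardless of
estimator. What the generator does **not** emulate: photon-transfer
nonlinearity, motion, optical PSF blur, vessel-shaped artifact geometry
beyond two-region phase maps, and 1/f LFP backgrounds; green tests
establish estimator correctness under the stated model, not robustness to
everything real data does.

All generators are pure functions of (spec, seed), asserted byte-wise.

## 9. Numerical choices

- Single floating-point (32-bit) is the on-disk movie convention; in-memory
  computation is double throughout.
- filtfilt uses odd-reflection padding of 3 effective impulse-response
  lengths (from the slowest pole radius), capped at `n-1`, with DC-matched
  section states; this keeps constants exactly constant through narrow
  notches.
- The SVD denoiser's per-component cleaner is a contract
  (`function(image) -> image`); the shipped default is a deterministic 3x3
  median filter standing in for the pretrained network used upstream, which
  is out of scope. The algorithmic claim tested is the structure (segmented
  low-rank + coefficient-image denoising), not any particular network.
- Ties in per-position crest times take the first maximum; histograms of
  directions are treated circularly (tiled before mode picking).
- YAML replaces TOML for pipeline configs (no TOML parser in the target
  environment); HDF5 and CSV are the supported containers (no TIFF reader).

## 10. Limitations

The filter is stationary by design — recordings with drifting artifact
coupling need re-estimation over windows. The unmixing assumes the reference
carries no voltage signal; dual-GEVI crosstalk must be removed first
(`decrosstalk_fiber`). Ripple detection without curation over-triggers on
ripple-free noise (section 5). The crest-based velocimetry is unsuitable for
non-unidirectional waves; the delay-map route covers those cases at higher
SNR cost.
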