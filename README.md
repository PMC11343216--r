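# tempotools

Signal-processing toolkit for **dual-channel optical voltage recordings**:
experiments in which a genetically encoded voltage indicator (GEVI) is imaged
alongside a voltage-insensitive reference fluorophore, either through a fiber
(photometry) or as a widefield movie. The reference channel sees the same
heartbeat and hemodynamic artifacts as the voltage channel — but generally
with frequency-dependent amplitude ratios and phase lags — so a plain
regression of one channel on the other cannot remove them. `tempotools`
implements the frequency-dependent convolutional (Wiener) unmixing approach
together with the downstream analyses such recordings need: photobleach
detrending, decrosstalking, SVD movie denoising, coherence and wavelet
spectrograms, phase–amplitude cross-frequency coupling, sharp-wave-ripple
detection, traveling-wave velocimetry, and a penalized regression model that
separates indicator-kinetic delays from physiological delays between two
cell classes. A synthetic-data generator with exact ground truth closes the
loop for validation.

## The core model

The GEVI trace is modeled as voltage plus a linear, stationary transform of
the reference trace:

```
G(t) = V(t) + H(t),        H(t) = (F * R)(t)
```

The transfer is estimated per frequency from tapered, overlapping segments
(duration τ, overlap 1−γ, Hann taper):

```
f(ω) = ⟨ g_k(ω) r_k*(ω) ⟩_k / ⟨ r_k(ω) r_k*(ω) ⟩_k
```

a Welch-style cross-spectrum over auto-spectrum ratio — equivalently a
rank-constrained complex regression with one coefficient per frequency bin.
To forbid unbounded amplification where the reference has no power, the
amplitude is clipped at `α·|f(ω₀)|`, where ω₀ is the heartbeat fundamental
(located by Welch PSD peak in a configurable band, default 8–14 Hz) and
`α ≈ 1.1`; phases are preserved. The inverse transform gives a two-sided,
zero-lag-centered kernel `F(t)`; `H = F * R` is subtracted from `G`.
Defaults: `τ = 1 s`, overlap `0.75`, `α = 1.1`.

Because `f(ω)` is clipped relative to the *measured* channel coupling at the
heartbeat frequency, unmixing does not transfer broadband noise from a noisy
reference into the voltage trace — the property that distinguishes it from
naive spectral division.

## Worked example

```r
library(tempotools)

# 60 s, 500 Hz synthetic pair: 10.5 Hz heartbeat artifact with a 60-degree
# inter-channel phase lag + 40 Hz voltage oscillation (0.5% dF/F)
tp <- gen_trace_pair(trace_synth_spec(seed = 1))
g <- tp$trace$gevi - mean(tp$trace$gevi)
r <- tp$trace$reference - mean(tp$trace$reference)

res <- unmix_trace(g, r, fs = 500)
res$filter
#> <wiener_filter> 500 bins, w0 = 10.50 Hz, |f(w0)| = 1, 6/500 clipped
```

Band power before/after (Welch PSD integrated over 9.5–11.5 Hz):

```
artifact band 9.5-11.5 Hz: raw 5e-05, wiener 2.14e-07 (23.7 dB),
                           scalar regression 3.75e-05 (1.3 dB)
40 Hz signal power ratio V/truth: 0.996
```

The convolutional filter removes the phase-lagged heartbeat artifact by
~24 dB while leaving the 40 Hz voltage signal untouched; a
frequency-independent regression (the `scalar_regression_unmix` baseline)
manages 1.3 dB, because no single real coefficient can cancel an artifact
that arrives with a phase lag.

Traveling-wave velocimetry on a synthetic 8-mm-field movie (SNR 2, true
speed 120 mm/s toward 30°):

```r
mv <- gen_movie_pair(movie_synth_spec(
  n_frames = 300, height = 64, width = 64, fs = 300, pixel_pitch = 0.125,
  waves = list(list(slowness = c(cos(pi/6), sin(pi/6)) / 120, freq = 2,
                    amplitude = 1, t_on = 0, t_off = 0.5)),
  noise = 0.5, seed = 2))
fit_slowness(spacetime_project(mv$movie$gevi, 0.125, c(1, 150)), 300,
             smooth_s = 0.125, refine_s = 0.067)
#> <slowness_fit> alpha = (0.007376, 0.004109) s/mm, speed 118 mm/s, dir 29.1 deg
```

The slowness (wavenumber) vector is recovered within 2% in speed and 1° in
direction; the event is accepted because the joint test on `(α_x, α_y)` is
significant (`p_joint ≈ 0`).

## Command line

`inst/cli/tempo.R` provides a small CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","tempo.R",package="tempotools"))')" \
    synth --seed 3 --out trace.csv
Rscript .../tempo.R unmix --in trace.csv --out unmixed.csv
Rscript .../tempo.R run --config pipeline.yaml
```

Subcommands: `run` (YAML pipeline), `synth`, `bin`, `unmix`, `ripples`,
`coherence`.
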