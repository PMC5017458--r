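---
title: "Separating and tracking multiple breathing targets with respvmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating and tracking multiple breathing targets with respvmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(respvmd)
library(dplyr)
```

## The problem

A single-channel ultra-wideband (UWB) impulse radar watches a room through
a wall.  Every transmitted sub-nanosecond pulse comes back as a *fast-time*
profile over range bins; pulse after pulse stacks these profiles into a
slow-time × fast-time matrix `R[J, N]`.  A breathing chest at standoff
distance $d_0$ moves by a few millimetres, which modulates the round-trip
delay $\tau_v(t) = 2\,(d_0 + x(t))/C$ of its echo; the breathing waveform
is therefore written into the *slow-time* samples of the range bin the
chest occupies.

With one person per range bin the problem is easy.  The hard and practical
case is several people at the *same* distance: their echoes superimpose in
one range bin, and an FFT of that bin shows a mixture of peaks that cannot
be attributed to individuals, let alone followed through time when rates
drift.  respvmd implements a pipeline that separates the mixture into one
narrowband mode per person and tracks each person's instantaneous
respiration rate:

1. **Range-bin selection** — pick the bin whose slow-time samples have the
   largest variance over a 2048-sample analysis window.
2. **Band-limiting** — remove the mean (static clutter) and apply a
   zero-phase low-pass over the respiration band, 0–0.7 Hz
   (0.7 Hz = 42 breaths/min).
3. **Variational mode decomposition (VMD)** — split the slow-time signal
   into $K$ narrowband modes $\mu_k(t)$ with centre frequencies
   $\omega_k$; each breathing target contributes one mode.
4. **Instantaneous-frequency tracking** — Hilbert-transform each selected
   mode, differentiate the phase, gate out low-amplitude (breath-hold)
   segments, and smooth with a rectangular window three dominant periods
   wide.

## The decomposition model

VMD poses mode extraction as a variational problem: find modes that
jointly reconstruct the signal while each stays maximally narrow around
its own centre frequency, with the bandwidth penalty weighted by
$\alpha$.  The package solves it with the standard alternating scheme on
the one-sided spectrum of the mirror-extended signal.  Each mode update is
a Wiener filter of the current residual,

$$\hat\mu_k^{n+1}(\omega) =
\frac{\hat f(\omega) - \sum_{i \ne k}\hat\mu_i(\omega) + \hat\lambda(\omega)/2}
     {1 + 2\alpha\,(\omega - \omega_k)^2},$$

each centre frequency is the power centroid
$\omega_k = \int_0^\infty \omega\,|\hat\mu_k|^2 d\omega \big/
\int_0^\infty |\hat\mu_k|^2 d\omega$, and an optional dual ascent
$\hat\lambda \leftarrow \hat\lambda + \tau(\hat f - \sum_k \hat\mu_k)$
pushes the mode sum toward exact reconstruction.  Iterations stop when
$\sum_k \|\hat\mu_k^{n+1}-\hat\mu_k^n\|_2^2 / \|\hat\mu_k^n\|_2^2 <
\varepsilon$.

Key property for this application: at the exact centre frequency of a
competing mode the Wiener numerator has already had that mode subtracted,
so two tones are attributed correctly even when the filters are much wider
than the tone separation.  That is what lets $\alpha = 20000$ (half-gain
half-width ≈ 0.76 Hz at a 152.6 Hz slow-time rate, on the internal
cycles/sample grid) separate breathing rates only 0.15 Hz apart.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | targets (+1 if noisy) | — | number of modes; one per breathing target, plus one mode to absorb clutter/noise for measured or noisy records |
| `alpha` | 20000 | — (cycles/sample grid) | bandwidth penalty; larger = narrower modes |
| `tau` | 0 | — | dual ascent step; 0 = denoising (no exact-reconstruction constraint), use ~1 for clean signals when reconstruction matters |
| `epsilon` | 1e-6 | — | convergence tolerance on relative mode change |
| `cutoff` | 0.7 | Hz | respiration-band low-pass edge (42 breaths/min) |
| `window_length` | 2048 | samples | slow-time window for bin selection (~13.4 s at 152.6 Hz) |
| `band` | 0.1–0.7 | Hz | centre-frequency band accepted as respiration |
| `energy_fraction` | 0.05 | — | minimum share of mode energy to count as a target |
| `gate_threshold` | 0.25 | — | envelope fraction below which a segment is not valid breathing |

### Choices the method leaves open, and what this package does

**Centre-frequency initialisation.**  The alternating scheme is only
locally convergent.  Starting the first iteration from zero modes, the
first centroid lands near the centre of mass of the whole band regardless
of where $\omega_k$ began, and occasionally (a few percent of noisy
realisations at −10 dB SNR) the iteration settles into a local minimum in
which one mode holds two targets and another holds a noise hump.  The
default `init = "peaks"` therefore starts the modes on the `k` tallest
local maxima of the input spectrum — deterministic, data-adaptive, and
the default of the most widely used VMD implementation.  Combined with one
extra noise-absorbing mode this removed every such failure we observed;
`"uniform"`, `"zero"`, `"random"`, and explicit start frequencies remain
available.

**How many modes.**  For clean simulations `k` = number of targets.  For
noisy or measured records use one more: the extra mode collects drift and
broadband residue that would otherwise contaminate a respiration mode.
`select_respiration_modes()` then keeps the modes that look like
breathing: centre frequency in 0.1–0.7 Hz and at least 5% of total mode
energy, de-duplicated if two modes correlate above 0.98.

**Filter realisation.**  The low-pass is a purely real FFT-domain gain —
unity to 0.7 Hz, raised-cosine to zero over 0.2 Hz — applied to the
mirror-extended signal.  It is exactly zero-phase (any phase distortion
would bias the instantaneous-frequency traces downstream), and the narrow
transition matters: noise left between the nominal band edge and a slow
roll-off is precisely where a spare VMD mode likes to park.  A
forward-backward IIR realisation was rejected because a Butterworth sharp
enough to meet the passband/stopband contract at a normalised cutoff of
0.0046 cycles/sample is numerically fragile.

**Hilbert edge handling.**  The analytic signal is computed by the FFT
one-sided-spectrum construction.  The circular transform sees the record's
two ends as adjacent, and a bare record (or an even mirror extension,
which distorts a sinusoid into $|\sin|$-like content) leaves
instantaneous-frequency ripple far above tolerance.  Each mode is instead
continued at both ends by an AR(2) Burg linear prediction — which extends
a narrowband oscillation phase-coherently — with the outer half of each
continuation tapered to zero; raw IF of a pure tone is then exact to
~1e-5 Hz in the interior.  Phase is differentiated wrap-free as
$\mathrm{Arg}(z_{i+1}\bar z_{i-1})/2$, one-sided at the ends.

**Smoothing and gating.**  Raw IF is gated first (samples whose amplitude
envelope is below 25% of the normal-breathing reference are set missing),
then smoothed by a centred rectangular window of width $T = 3/\omega_k$
seconds, truncated and renormalised at the edges; missing samples are
excluded from their windows.  The normal-breathing reference defaults to
the median envelope over the most active third of the record, overridable
when a calibrated amplitude is known.  The first/last $T/2$ seconds of a
trace are edge-dominated and should be read with caution.

**Numerical conventions.**  Mirror extension doubles the record by
reflecting each half outward; its seams fall exactly at the trim
boundaries, so decomposed modes taper over the outermost few percent of
samples (interior correlation with ground-truth components is ≥ 0.999,
full-record ≈ 0.98).  Modes are updated on the non-negative half of the
spectrum and inverse-transformed under conjugate symmetry, so time-domain
modes are exactly real.  A mode whose spectrum goes identically to zero
keeps its previous centre frequency rather than dividing 0/0, and a
zero-energy previous iterate contributes `Inf` (not 0/0 = `NaN`) to the
convergence residual, so a degenerate run cannot report convergence
spuriously.  Ties in bin selection break to the lowest index.

## What the simulator emulates — and what it does not

`generate_echo_matrix()` builds the echo cube from first principles:
sinusoidal (or ramped, or amplitude-scheduled) chest displacement
$x_i(t)$, round-trip delay $2(d_0 + x_i(t))/C$, a first-derivative
Gaussian pulse whose −10 dB band spans ≈0.85–9.55 GHz (scale
3.674e-11 s), fast-time sampling at 39 GHz over 512 range bins
(3.8 mm spacing), slow-time sampling at 152.6 Hz, a static random
fast-time clutter profile repeated across slow time (the wall and
furniture), and white Gaussian noise calibrated in SNR against the target
echo.  Chest excursions default to ~5 mm with distinct per-target
amplitudes, typical of seated adults.

Not emulated: electromagnetic wall propagation (the wall is attenuation
folded into the reflection amplitude plus static clutter), multipath,
antenna patterns, hardware ringing of the pulse, walking targets, and
heartbeat.  Passing tests on this simulator therefore demonstrates the
*signal-separation* machinery under the stated signal model; it does not
certify performance against hardware artefacts or moving people.

The named scenarios (`make_fixtures()`, `scenario_spec()`) pin down the
benchmark situations: two targets at constant 0.2/0.37 Hz; two targets
breathing alternately (one holds breath for half the record); rates
ramping 0.2→0.3 Hz against 0.5→0.4 Hz over 30 s; three targets at
0.12/0.34/0.45 Hz; and the bare 0.2 + 0.35 Hz two-tone signal.  Scenario
records are 30–50 s (4578–7630 slow-time samples) with 10 dB SNR and
clutter amplitude 0.5 — sizes chosen so a full scenario runs in seconds
on one core while giving the decomposition several breathing cycles to
work with.

## A worked run

```{r pipeline}
cfg <- pipeline_config(
  targets = list(target_spec(1.5, rate = 0.2),
                 target_spec(1.5, rate = 0.35, amplitude_m = 0.004)),
  clutter = clutter_spec(amplitude = 0.5, snr_db = 10, seed = 7))
report <- run_pipeline(cfg)
report$summary
```

Two people 1.5 m away, same range bin (391), breathing at 12 and 21
breaths/min; the pipeline re-finds the bin, separates the modes, and the
tracked mean rates land on the simulated ones.

```{r plots, fig.height = 4}
autoplot(report$vmd)
autoplot(report$tracks)
```

The classic sanity check — an FFT of the raw bin shows both peaks mixed,
while each mode's spectrum carries exactly one:

```{r fft, fig.height = 3}
library(ggplot2)
baseline_fft_spectrum(report$signal, modes = report$vmd) |>
  dplyr::filter(frequency_hz <= 1) |>
  ggplot(aes(frequency_hz, amplitude)) +
  geom_line() +
  facet_wrap(~series, scales = "free_y")
```

## Known limitations

- Two targets breathing within ~0.1 Hz of each other merge into one mode;
  the method has no way to split them (the de-duplication rule will
  report one mode, honestly).
- Targets are assumed stationary in range over the record; there is no
  range-migration tracking.
- Mode–target assignment is by centre frequency, so two targets *crossing*
  rates would swap identities.
- The first/last half smoothing window of each IF trace, and the
  outermost few percent of each mode, are edge-affected.
- Heart rate is out of scope; the band and gating rules are tuned to
  respiration.
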