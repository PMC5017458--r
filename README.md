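# respvmd

Non-contact respiration monitoring of **multiple people at the same
distance** from a single-channel ultra-wideband (UWB) impulse radar.

A breathing chest at standoff $d_0$ shifts the round-trip delay of every
radar pulse by $\tau_v(t) = 2\,(d_0 + x(t))/C$, where $x(t)$ is the
millimetre-scale chest displacement.  Stacked pulse returns form a
slow-time × fast-time matrix `R[J, N]`; the breathing of everyone at one
distance is superimposed in a single range bin's slow-time signal.  An
FFT of that bin shows a tangle of peaks that cannot be attributed to
individuals or followed as rates drift.  respvmd untangles it:

1. **Range-bin selection** — choose the bin with the largest slow-time
   variance, $V_j = \sum_n (x_{j,n} - \bar x_j)^2$, over a 2048-sample
   window.
2. **Band-limiting** — demean and zero-phase low-pass to the respiration
   band, 0–0.7 Hz (42 breaths/min).
3. **Variational mode decomposition (VMD)** — split the signal into $K$
   narrowband modes by the alternating scheme: Wiener-filter mode updates
   $$\hat\mu_k \leftarrow \frac{\hat f - \sum_{i\ne k}\hat\mu_i + \hat\lambda/2}
   {1 + 2\alpha(\omega - \omega_k)^2},$$
   power-centroid centre frequencies
   $\omega_k = \int_0^\infty \omega|\hat\mu_k|^2 \big/ \int_0^\infty |\hat\mu_k|^2$,
   and dual ascent $\hat\lambda \leftarrow \hat\lambda + \tau(\hat f - \sum_k\hat\mu_k)$,
   iterated until $\sum_k \|\Delta\hat\mu_k\|^2/\|\hat\mu_k\|^2 < \varepsilon$.
   One mode per breathing target (plus one noise-absorbing mode for noisy
   records), $\alpha = 20000$, $\tau = 0$, $\varepsilon = 10^{-6}$.
4. **Instantaneous-frequency tracking** — Hilbert transform each
   respiration mode, differentiate the phase, gate out segments whose
   amplitude envelope falls below 25% of normal breathing (breath holds),
   and smooth with a rectangular window three dominant periods wide.

The package also contains a full synthetic-radar generator (delay-
modulated first-derivative Gaussian pulses, 512 range bins at 39 GHz fast
time, 152.6 Hz slow time, static clutter, SNR-calibrated noise) with
ground-truth sidecars, so every stage is testable against known truth.

## Worked example

Two people seated 1.5 m from the radar — the *same* range bin — breathing
at 12 and 21 breaths/min, with static clutter and 10 dB SNR noise:

```r
library(respvmd)
cfg <- pipeline_config(
  targets = list(target_spec(1.5, rate = 0.2),
                 target_spec(1.5, rate = 0.35, amplitude_m = 0.004)),
  clutter = clutter_spec(amplitude = 0.5, snr_db = 10, seed = 7))
report <- run_pipeline(cfg)
report
#> <vital_report> range bin 391 selected; 2 respiration mode(s)
#> # A tibble: 2 × 6
#>    mode center_frequency_hz rate_bpm energy energy_fraction mean_rate_bpm
#>   <int>               <dbl>    <dbl>  <dbl>           <dbl>         <dbl>
#> 1     2               0.202     12.1  3399.           0.498          12.1
#> 2     3               0.352     21.1  3112.           0.456          21.0
```

Range bin 391 is exactly where a 1.5 m target belongs
(bin spacing $C/2f_{\text{fast}} \approx 3.8$ mm).  The two respiration
modes land at 0.202 and 0.352 Hz — 12.1 and 21.1 breaths/min against the
simulated 12 and 21 — and the per-sample smoothed rate traces
(`report$tracks`) average 12.1 and 21.0 breaths/min.  `autoplot(report$vmd)`,
`autoplot(report$tracks)`, and `baseline_fft_spectrum()` reproduce the
standard mixed-spectrum-vs-separated-modes comparison.  Time-varying
rates work the same way; see the `two_timevarying` scenario in
`make_fixtures()` and the vignette.

A thin command-line front end over the same functions lives at
`inst/cli/respvmd.R`:

```sh
Rscript inst/cli/respvmd.R fixtures --scenario three_constant --seed 1 --dir out/
Rscript inst/cli/respvmd.R run --input out/three_constant_radar.csv --k 4 --dir out/
```

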