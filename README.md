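# sensorscreen

Analysis toolkit for the quantitative side of engineering genetically
encoded fluorescent neurotransmitter sensors (GABA, glutamate and similar
single-fluorophore indicators). It covers the three measurement regimes
such projects rely on:

1. **High-throughput field-stimulation screening** of sensor variants in
   cultured neurons: 96-well plates imaged at 50 Hz while trains of 1, 10
   and 40 electrical pulses (≈83 Hz within a train) evoke synaptic
   release. Per pixel, a two-sided Mann–Whitney U test compares the 1.5 s
   before each stimulus onset with the 0.4 s after it; pixels with
   p < 0.01 for *any* epoch are **responsive**, and their count proxies
   sensor expression. Photobleaching is removed by fitting
   F_b(t) = A·exp(−t/τ_b) + C to the start and end of each recording
   (avoiding response windows) and dividing it out. The ΔF/F₀ trace
   pooled over responsive pixels yields peak ΔF/F₀, rise/decay time
   constants (τ_on, τ_off) from exponential fits, and a d′ sensitivity
   index. Plate QC (wells with < 4 responsive pixels discarded, variants
   with < 3 surviving replicates retested, plates with failed control
   wells rejected, variants with < 1800 responsive pixels per plate
   eliminated), in-plate control normalization, and a two-stage joint
   selection on sensitivity *and* expression produce the ranked winner
   list.
2. **Biophysical curve fitting**: Hill titrations
   F = Fmin + (Fmax−Fmin)·cⁿ/(EC50ⁿ + cⁿ) for purified protein and
   on-cell perfusion protocols (5 s application / 9 s wash step
   extraction), the pH sigmoid F = Fmin + (Fmax−Fmin)/(1+10^(pKa−pH)),
   and stopped-flow monoexponential relaxations
   F(t) = F∞ + (F₀−F∞)·exp(−k_obs·t) with a residual-autocorrelation
   biphasicity diagnostic.
3. **Direction-selectivity statistics** for imaging of inhibitory release
   in the retina: response amplitude index RAI = (r_s−r_b)/(r_s+r_b),
   trial-to-trial reliability Var[⟨C⟩_r]_t / ⟨Var[C]_t⟩_r, motion SNR
   (R_p−SD_b)/(R_p+SD_b), and the doubled-angle circular variance
   CV = |Σ_d R_d·e^{i2θ_d} / Σ_d R_d|.

Every analysis stage is paired with a **synthetic data generator with
known ground truth** (well movies with photobleaching, evoked transients
of either polarity and signal-dependent noise; Hill titrations;
stopped-flow traces; direction-tuned trial matrices), so the whole
pipeline is testable end to end without any external data.

## Worked example

Simulate one well of a strong candidate variant (10-pulse peak ΔF/F₀
0.77, τ_on 43 ms, τ_off 73 ms, 45% of pixels expressing) and run the
per-well pipeline:

```r
library(sensorscreen)

gt <- variant_ground_truth(
  "candidate",
  amplitude_by_pulses = c(`1` = 0.2, `10` = 0.77, `40` = 1.0),
  tau_on = 0.043, tau_off = 0.073, expressing_fraction = 0.45)
spec <- plate_spec(frame_shape = c(24, 24), frame_rate = 250, seed = 61)
movie <- simulate_well(gt, spec, well_seed = 4242)
res <- analyze_well(movie)

res$well[, c("n_responsive", "fraction_responsive", "polarity", "bleach_tau")]
#>   n_responsive fraction_responsive polarity bleach_tau
#> 1          265           0.4600694        1   60.29412
print(res$epochs[, c("pulses", "peak_signed", "tau_on", "tau_off", "d_prime")], digits = 3)
#>   pulses peak_signed tau_on tau_off d_prime
#> 1      1       0.200 0.0431  0.0738    1.71
#> 2     10       0.764 0.0432  0.0731    1.71
#> 3     40       0.989 0.0431  0.0731    1.71
```

The detector marks 265 pixels responsive (46% of the frame — the 45%
expressing fraction plus the expected false positives), the bleach time
constant (ground truth 60 s) comes back as 60.3 s, and the per-epoch
peaks and time constants recover the generating values within a few
percent. `round(fold_change(res$epochs$peak_abs[2], 0.19)$ratio, 1)`
compares the measured 10-pulse peak with a reference sensor's 0.19 and
prints `4` — a fourfold-improved variant.

Plate-scale runs use `simulate_screen()` (writes multi-page TIFFs plus
layout/ground-truth sidecars) and `analyze_screen()` (per-well metrics
CSV, variant summary CSV, JSON screen report, QC log). A thin
command-line wrapper with the same entry points is installed at
`inst/cli/sensorscreen.R`.

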