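# shoalkin

Analysis pipeline for the ontogeny and thermal sensitivity of shoaling
in small forage fish (zebrafish, *Danio rerio*). From digitized swimming
videos, shoal trajectories and closed-respirometry oxygen traces it
computes, per shoal and flow speed:

- **midline kinematics** — tail-beat frequency (TBF, Hz), head and tail
  oscillation amplitudes (BL), body-wave speed and wavelength
  (BL s⁻¹, BL) from the phase propagation of the local three-point
  curvature κ = 1/R, and maximum body curvature (BL⁻¹) at 5% BL chord
  spacing;
- **shoal cohesion** — mean separation distance (per-fish mean
  inter-individual distance, BL) and position-switch rate (streamwise
  rank inversions s⁻¹ with a 0.05 BL hysteresis band);
- **energetics** — resting routine and peak post-exercise oxygen
  consumption rates (OLS slopes of the O₂ decline, mg O₂ L⁻¹ h⁻¹ per
  5-fish shoal), factorial scope MO₂peak/MO₂rest, and thermal
  sensitivity Q₁₀ = (K₂/K₁)^(10/(T₂−T₁)) per stage between 28 °C and
  32 °C acclimation;
- **inference** — permutation ANOVA (exact label permutation for
  one-way designs, Freedman–Lane residual permutation for stage ×
  temperature models), applied within each tested speed.

A synthetic-data generator (traveling-wave swimmers, station-keeping
shoals with Poisson position switches, exponentially decaying EPOC
oxygen traces) reproduces the full experimental design — 29 shoals of 5
fish across 3 ontogenetic stages × 2 temperatures — with known ground
truth, so every estimator is validated by parameter recovery. See the
methods vignette (`vignettes/shoaling-analysis.Rmd`) for the models,
estimator details and design rationale.

## Worked example

Generate one fish swimming at 10 Hz with a 0.95 BL body wave and recover
its kinematics:

```r
library(shoalkin)

p <- wave_model_params(tbf_hz = 10, wavelength_bl = 0.95,
                       head_amp_bl = 0.02, tail_amp_bl = 0.10,
                       body_length = 36.8)          # adult-sized, mm
g <- generate_midline_sequence(p, n_cycles = 3, fish_id = "a1")
analyze_midline_sequence(g$seq)
#>   tbf_hz head_amp_bl tail_amp_bl head_tail_ratio wave_speed_bl_s wavelength_bl
#> 1 10.034        0.02      0.0985          0.2033          9.3753        0.9344
#>   max_curvature_per_bl n_cycles_used
#> 1                4.206             3
g$truth$wave_speed_bl_s        # 9.5  (f * lambda)
g$truth$max_curvature_per_bl   # 4.645 (chord estimator reads <= truth)
```

TBF is recovered to 0.3%, amplitudes to ~1%, wave speed and wavelength
to ~1.5%; the 5% BL chord curvature reads 9% below the analytic maximum
because it cannot see the final tail segment — a one-sided bias the
tests assert.

The full study runs as one pipeline:

```r
res <- run_pipeline(pipeline_config("results/run", seed = 1))
res$q10
#>      stage rate_type        k1        k2    t1    t2      q10 n1 n2
#> 1    larva      rest 1.1867750  1.585310 28.06 32.04 2.069876  5  5
#> 3 juvenile      rest 0.8060567  1.948442 28.02 32.10 8.699901  5  4
#> 5    adult      rest 1.9150511  2.789628 28.06 32.00 2.597971  5  5
#> ...
```

Resting Q₁₀ lands near the typical ~2 for larvae and adults but ~9 for
juveniles — the injected thermal hypersensitivity of juvenile resting
metabolism, recovered through the whole chain (trace simulation → slope
fitting → cell means → Q₁₀). The summary file reports the headline
contrasts (separation distance 3.6 → 2.4 → 1.2 BL across ontogeny, TBF
falling, switch rate doubling) and the permutation tests flag the
injected stage effects at every shared speed.

The numbered scripts under `analysis/` run the same workflow step by
step (design → kinematics → shoal metrics → respirometry → permutation
tests), writing tables under `results/`.

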