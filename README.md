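# mixotracer

Analysis toolkit for controlled coral feeding-gradient experiments, for
trophic ecologists and ecophysiologists who want to quantify coral
mixotrophy — how much nutrition a symbiotic coral draws from prey
capture versus photosynthate — from fatty-acid (FA) biomarkers and bulk
C/N stable isotopes measured on separated host and symbiont tissue
fractions.

The package covers four connected analyses:

1. **Prey capture.** Tank-level consumption from before/after nauplii
   densities, biomass conversion (3.2 µg nauplius⁻¹), surface-area and
   time normalisation, and logarithmic saturation curves
   *r* = *a* + *b* ln(*d*) fit per treatment.
2. **FA trophic biomarkers.** Classification of each FA as a
   heterotrophic or autotrophic biomarker (exact Wilcoxon rank-sum
   between source profiles) and typing of each host FA's response across
   the feeding gradient into four patterns (positive with heterotrophy,
   negative, bleaching effect, no effect) via colony-blocked permutation
   contrasts.
3. **Two-endmember isotope mixing.** Percent elemental turnover

   %turnover = 100 · (δ_fed − δ̄_control) / (δ̄_prey − δ̄_control)

   computed per fragment against per-colony control means (zero trophic
   discrimination assumed), the Δ¹³C < −2 ‰ heterotrophy-capture rule,
   and the preferential nitrogen-incorporation factor
   (f_N / f_C) × C:N_source.
4. **Synthetic experiments.** A hierarchical generator (colonies ×
   treatments × tanks × fragments, endmember mixing with
   element-selective incorporation, colony/tank random effects, known
   ground truth) so the whole pipeline runs and is tested with no
   external data.

## Worked example

```r
library(mixotracer)

cfg <- simulation_config(seed = 1)
ex  <- generate_experiment(cfg)
ex
#> <coral_experiment> 210 fragment x fraction rows, 126 feeding events, seed 1

tt <- turnover_table(ex$fragments, heterotrophic_endmember())
preference_table(tt, CN_source = 4.48)
#>   treatment fraction   f_N    f_C factor factor_rounded
#> 1      F_2x     host 0.225 0.0620   16.3             16
#> 2      F_6x     host 0.404 0.0521   34.8             35
#> 3    B_F_6x     host 0.339 0.1023   14.8             15
#> 4      F_2x symbiont 0.192 0.0180   47.6             48
#> 5      F_6x symbiont 0.315 0.0582   24.2             24

cap <- consumption_from_densities(ex$feeding_events)
fit_feeding_curves(cap)
#>   treatment      a     b r_squared  n
#> 1      F_2x -295.4 56.52    0.6619 18
#> 2      F_6x -243.5 46.07    0.6493 54
#> 3    B_F_6x -154.1 30.53    0.3367 54
```

Reading the output: under this seed the F_6x corals replaced ~40 % of
host nitrogen but only ~5 % of host carbon with heterotrophic material
(true configured values 38.1 % and 9.5 %; carbon estimates are noisy
because the carbon endmembers differ by only ~4.4 ‰) — heterotrophic
nitrogen is preferentially retained over carbon by a factor of ~35 here,
far above the prey's own C:N of 4.48. The fitted feeding curves recover
the configured coefficients (F_6x truth: a = −209.1, b = 41.0) within
event-level noise.

The same stages run from CSV files via the CLI (installed at
`exec/mixotracer` inside the package):

```sh
mixotracer simulate --out data --seed 1
mixotracer report --fragments data/fragments.csv \
    --events data/feeding_events.csv --sources data/sources.csv \
    --batches data/nauplii_batches.csv --out results
```

Exit codes: 0 success, 2 validation/configuration error, 3 computation
error.

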