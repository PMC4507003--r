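# searchkin

Quantifying how DNA-binding proteins find their target sites in the
mammalian nucleus, from single-molecule tracking and single-cell
association data.

A site-specific protein such as the Tet repressor reaches a multi-site
target locus by facilitated diffusion: 3D excursions through the
nucleoplasm (mean duration τ<sub>3D</sub>) alternate with transient
nonspecific DNA binding (mean duration τ<sub>1D</sub>), during which the
protein can slide locally over ℓ<sub>SL</sub> = √(4 D<sub>SL</sub>
τ<sub>RS</sub>) base pairs. `searchkin` implements the complete analysis
chain for this picture:

* **Mobility**: per-trajectory MSD, instantaneous diffusion coefficients
  (free-intercept fit over lags 2–5, D = slope/4), and Gaussian-mixture
  classification of log<sub>10</sub> D into fast/intermediate/quasi-immobile
  populations.
* **Nonspecific binding**: running-window detection of transient binding
  events in continuous imaging; the apparent dwell rate is the sum of the
  dissociation and photobleaching rates (competing exponentials), so
  τ<sub>RS</sub> = 1/(k<sub>app</sub> − k<sub>bleach</sub>).
* **Survival analysis**: the full dwell-time survival probability merged
  from continuous and time-lapse protocols (dark gaps 0.1/0.5/1 s) with
  anchor renormalization, finite-observation (span-availability)
  correction, power-law exponent fitting, and numerical integration to
  τ<sub>1D</sub>.
* **Association kinetics**: per-cell locus-filling rates
  k<sub>obs</sub> = k<sub>a</sub>·c + k<sub>off</sub>, FCS
  amplitude-to-concentration conversion, and the concentration regression
  yielding the association rate constant k<sub>a</sub>.
* **Search-rate models**: Smoluchowski absorbing sphere
  (k<sub>a</sub> = 4πDr<sub>t</sub>), uniformly reactive sphere
  (4πDr<sub>t</sub>(1 − tanh x / x)), the reaction-limited limit
  k<sub>a</sub> ≈ (4π/3)λNa³, sliding length, and the
  facilitated-diffusion rate p·N<sub>i</sub>·ℓ<sub>SL</sub>/(c<sub>DNA</sub>(τ<sub>1D</sub>+τ<sub>3D</sub>)).
* **Synthetic data**: a two-state diffusion/binding trajectory simulator
  with imaging protocols, localization noise and exposure-driven
  photobleaching; locus-filling time courses; random genomes with planted
  motifs, plus an exhaustive contiguous-match motif scanner with analytic
  random-genome expectations.

Everything is tidyverse-shaped: functions take data frames first, return
tibbles, and fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(searchkin)

# Bleach-corrected residence time on random sequences:
# apparent event decay 6.7 1/s, bleaching 0.34 1/s
correct_bleaching(6.7, 0.34)
#> [1] 0.1572327

# Kinetic partition from the 75% mobile fraction and tau_1D = 2 s
partition_times(2, 0.75)
#> # A tibble: 1 x 3
#>   tau_1d tau_3d visit_rate
#>    <dbl>  <dbl>      <dbl>
#> 1      2      6      0.125

# Every derived search-model quantity in one table
search_model_report()
#>                     quantity    value  units
#> 1                      d_eff 6.00e+00 um^2/s
#> 2                 visit_rate 1.25e-01    1/s
#> 3       k_a_absorbing_sphere 1.59e+10  1/M/s
#> 4                     lambda 1.90e+00    1/s
#> 5        lambda_regime_ratio 3.17e-07
#> 6             sliding_length 2.51e+02     bp
#> 7                 p_specific 1.46e-01
#> 8         search_time_single 3.27e+06      s
#> 9         nonspecific_visits 4.09e+05
#> 10 diffusion_limited_ns_time 2.08e-05      s
```

The table reads: intermittent nonspecific binding slows the effective
diffusion to 6 um²/s; a perfectly absorbing 350-nm locus would capture at
1.6×10¹⁰ /M/s, more than five orders of magnitude above the measured
9.2×10⁴ /M/s, so the search is reaction-limited (per-site binding
efficiency λ ≈ 1.9 1/s, λa²/D ≈ 3×10⁻⁷ ≪ 1); a single molecule in a
500-µm³ nucleus needs ~3.3×10⁶ s to bind, visiting ~4×10⁵ nonspecific
sites on the way.

Simulation-based pipeline, end to end:

```r
kin <- kinetics_config() # two-state kinetics, exponential dwell 6.36 1/s
tracks <- simulate_tracks(kin, protocol_continuous(),
  n_tracks = 400, duration_s = 6, seed = 42
)
events <- detect_binding_events(tracks, interval_s = 1 / 197)
fit_event_rate(events)
#> # A tibble: 1 x 4
#>    rate    se n_events method
#>   <dbl> <dbl>    <int> <chr>
#> 1  6.67 0.642      108 mle
correct_bleaching(6.67, 0.34)
#> [1] 0.1579359
```

The detected apparent rate (6.67 1/s) is the generative dissociation rate
plus the bleaching rate; the correction recovers the ~158-ms mean
residence time.

See `vignettes/target-search-kinetics.Rmd` for the models, estimator
choices and their rationale.

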