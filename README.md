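# cotsdetect

Abundance and detectability estimation for crown-of-thorns starfish
(CoTS, *Acanthaster* spp.) surveys.

CoTS outbreaks strip coral from Indo-Pacific reefs, and control programs
cull or remove individual starfish — but CoTS are cryptic, and a
substantial fraction of animals evades even intensive searches of small
belt transects. Management decisions therefore need *detectability*: the
proportion of the true local population sighted during a single survey
pass. That in turn needs an independent estimate of the total sample
population N on each transect. This package is for reef ecologists and
monitoring programs who run (or simulate) such intensive surveys.

## What it implements

* **Closed-population abundance** per transect:
  * depletion (removal) sampling — N̂ is the cumulative removal total
    over successive passes;
  * Lincoln–Petersen mark–recapture — N̂ = MC/R from M animals marked,
    C sighted in a later survey, R of them marked; the Chapman form
    (M+1)(C+1)/(R+1) − 1 is available as an option. Transects with
    R = 0 are flagged inestimable, never silently substituted. With a
    multi-survey schedule, every consecutive survey pair is estimated and
    the **max-N rule** takes the largest estimable value as the
    transect's total sample population.
* **Detectability**: per transect × survey proportions C/N̂ (with the
  declining-denominator convention for successive removal passes), pooled
  proportions Σfound/ΣN̂, per-transect means ± SE, size-class
  detectability from pooled MC/R within diameter bins (≤20, 21–30,
  31–40, >40 cm), and density conversions (per 200 m² and per hectare).
* **Binomial-logit GLMM** `cbind(found, missed) ~ covariates + (1|site)`
  fitted by maximum likelihood with **adaptive Gauss–Hermite quadrature**
  (15 nodes default; 1 node = Laplace), AICc model ranking with Akaike
  weights, Type-II Wald χ² tests, and a Pearson dispersion check.
* **Survey simulator**: negative-binomial per-transect populations,
  logit-linear detection (size, night, zone, aspect, site random
  intercept), depletion and mark–recapture schedules with tag loss —
  used throughout the tests to validate the estimators by parameter
  recovery.

## Worked example

The package ships the pooled three-pass removal series of a published
depletion study (96, 25, 11 animals removed over 40 transects of
200 m²):

```r
library(cotsdetect)
surveys <- read_surveys(example_fixture("depletion_pooled.csv"),
                        design = "depletion")
ab   <- estimate_abundance(surveys, "depletion")     # n_hat = 132
recs <- detectability_records(surveys, ab, "depletion")
pooled_detectability(recs, by = "survey_index")[,
  c("survey_index", "found", "n_hat", "proportion_2dp", "percent")]
#>   survey_index found n_hat proportion_2dp percent
#> 1            1    96   132           0.73    72.7
#> 2            2    25    36           0.69    69.4
#> 3            3    11    11           1.00   100.0
```

132 animals were present in total; 73% of them were sighted (and
removed) on the first pass. The second pass is scored against the 36
animals still present, of which 69% were found — the survivors of pass
one were harder to detect.

A full simulated mark–recapture analysis, from population to model
selection:

```r
cfg <- sim_config(n_sites = 4, transects_per_site = 2,
                  mean_abundance_per_transect = 20, rng_seed = 424)
rep <- run_pipeline(cfg, "markrecap")
rep$models[, c("model", "k", "aicc", "delta", "weight")]
#>                                                      model k     aicc     delta     weight
#> 1          cbind(found, missed) ~ time_of_day + (1 | site) 3 119.7567 0.0000000 0.43873213
#> 2 cbind(found, missed) ~ time_of_day + aspect + (1 | site) 4 119.9897 0.2329664 0.39049136
#> 3 cbind(found, missed) ~ time_of_day * aspect + (1 | site) 5 121.8035 2.0467979 0.15766777
#> 4                    cbind(found, missed) ~ 1 + (1 | site) 2 126.7780 7.0212196 0.01310874
rep$best_fit
#> Binomial random-intercept GLMM (adaptive Gauss-Hermite, 15 nodes)
#>   formula: cbind(found, missed) ~ time_of_day + (1 | site)
#>                  estimate     se       z      p
#> (Intercept)       -0.3228 0.2821 -1.1443 0.2525
#> time_of_daynight   0.6464 0.2097  3.0821 0.0021
#>   sigma_u (site): 0.5053
#>   logLik: -56.278369   AICc: 119.75674   n: 24
```

AICc prefers the time-of-day model: detection is higher at night
(+0.65 on the logit scale, Wald p ≈ 0.002), recovering the effect the
simulator injected (`beta_night = 0.6`).

## Documentation

The methods vignette (`vignettes/cots-detectability-methods.Rmd`) gives
the full account: model assumptions, estimator conventions (R = 0
handling, max-N, rounding of fractional denominators), the adaptive
quadrature and boundary handling, what the simulator does and does not
emulate, and known limitations.
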