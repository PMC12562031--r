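---
title: "Estimating crown-of-thorns starfish detectability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crown-of-thorns starfish detectability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotsdetect)
```

## The problem

Crown-of-thorns starfish (CoTS, *Acanthaster* spp.) are cryptic: even
intensive SCUBA searches of small belt transects miss a substantial
fraction of the animals present, which biases density estimates and caps
the proportion of starfish that culling or removal programs can ever
reach. Quantifying *detectability* — the proportion of the true local
population sighted during one survey pass — therefore requires an
independent estimate of the total sample population \(N\) on each
transect. This package implements the two classical closed-population
routes to \(N\), the detectability summaries built on them, and a
binomial mixed model for asking which factors (time of day, reef zone,
aspect, body size) drive detection, together with a survey simulator that
makes every stage testable by parameter recovery.

## Abundance estimators

**Depletion (removal) sampling.** With \(K\) successive passes in which
every detected animal is removed, the total sample population is the
cumulative removal total \(\hat N = \sum_k r_k\). This assumes closure and
that every animal is eventually detected; animals that evade all \(K\)
searches inflate the apparent detectability. `depletion_abundance()`
implements exactly this sum, so `estimate_abundance()` on a removal series
of 96, 25 and 11 animals gives \(\hat N = 132\).

**Lincoln–Petersen mark–recapture.** With \(M\) animals marked before a
recapture survey that sights \(C\) animals of which \(R\) carry a mark,
\(\hat N = MC/R\). We keep the estimate at full precision and round only
at report time. When \(R = 0\) the estimator is undefined;
`lincoln_petersen()` flags the transect *inestimable* rather than
substituting \(\infty\) or silently switching to a bias-corrected form,
and downstream summaries drop such transects with a counted warning. The
Chapman form \((M+1)(C+1)/(R+1) - 1\) is available (`chapman()`,
`use_chapman = TRUE`) but off by default so that default output matches
the plain \(MC/R\) convention. Exhaustive enumeration of all detection
outcomes for tiny populations (used as a test oracle) shows the expected
trade-off: conditional on \(R > 0\) the Lincoln–Petersen mean is biased —
upward at moderate/large \(N\), and at high per-survey detection
(\(p \approx 0.8\)) the Chapman mean is markedly closer to the truth for
\(N \ge 4\). At low detection and very small \(N\) the conditioning
itself distorts both estimators and neither dominates; this is why the
package reports inestimable transects explicitly instead of averaging
over them.

**Survey pairs and the max-N rule.** A three-survey schedule (day, night,
follow-up day) yields two consecutive pairs. For pair \((i, i+1)\), \(M\)
is the cumulative number of animals marked before survey \(i+1\) — the
analyst's view; tag loss, applied in the simulator at the configured
retention (default 0.941), is a real source of upward bias the estimator
does not correct. The transect's total sample population is the maximum
estimable \(\hat N\) over pairs (`transect_sample_population()`). Field
write-ups rarely state which pairs produced their per-transect estimates;
computing all consecutive pairs and taking the maximum is our declared
convention and is recorded in the output's `survey_pair` column. The
pooled all-transect population is the *sum of per-transect max-N values*,
not a Lincoln–Petersen fit on pooled counts, because closure is assumed
per transect.

## Detectability

`detection_proportion(found, n_hat)` returns \(C/\hat N\), clamped to
\([0, 1]\) with a warning if a count exceeds its estimate. Two
conventions matter and are applied uniformly:

* **Averaging universe.** Per-transect means include only records with
  \(\hat N \ge 1\) (at least one animal presumed present); a transect
  where nothing was ever found, and nothing was estimated to be present,
  carries no information about detection.
* **Integer complements for the GLMM.** The mixed model needs integer
  (found, missed) pairs, but \(MC/R\) is fractional. We set
  `missed = round(n_hat) - found` (half-up rounding, floored at zero).
  This choice is invisible for depletion data (integer by construction)
  and perturbs mark–recapture denominators by at most one animal.
* **Depletion denominators decline.** For removal pass \(k\) the
  denominator is the population still present,
  \(\hat N - \sum_{j<k} r_j\): the second pass of the 96/25/11 series is
  scored against 36 animals, not 132.

Pooled detectability over any grouping is
\(\sum \text{found} / \sum \hat N\), which is identically the
\(\hat N\)-weighted mean of per-record proportions. Standard errors of
per-transect means are reported on the proportion scale
(\(\mathrm{sd}/\sqrt{n}\)), with the percent scale printed alongside,
explicitly labeled, since published summaries mix the two scales.

Size-class detectability (`size_class_table()`) pools individual
sightings across all transects within the conventional diameter bins
(\(\le 20\), 21–30, 31–40, \(> 40\) cm; right-closed, matching
integer-cm field measurements). The day estimate for a class uses marks
from the initial day survey recaptured at night; the night estimate uses
everything marked through the night survey recaptured on the follow-up
day. Published tables of this kind can contain cells inconsistent with
their own \(M/N\) arithmetic; this package always reports the computed
ratio.

Density conversions (`density_report()`) report both field scales:
animals per 200 m² transect-equivalent and per hectare
(\(\text{count}/\text{area} \times 10^4\)).

## The binomial GLMM

The detection records feed a binomial-logit mixed model
\[
  \text{found}_i \sim \mathrm{Bin}(n_i, p_i), \qquad
  \mathrm{logit}(p_i) = x_i'\beta + u_{s(i)}, \qquad
  u_s \sim \mathcal N(0, \sigma_u^2),
\]
with a single site-level random intercept. The marginal likelihood
integrates \(u\) out per site; `glmm_binom()` maximizes it over
\((\beta, \log\sigma_u)\).

**Quadrature.** The integral is evaluated by *adaptive* Gauss–Hermite
quadrature: each site's integrand is re-centered at its conditional mode
(found by a vectorized, clipped Newton iteration — the integrand is
log-concave) and re-scaled by the local curvature before applying the
Hermite rule. Fifteen nodes are the default; one node gives the Laplace
approximation exactly, and \(\sigma_u = 0\) short-circuits to the plain
GLM likelihood. On test fixtures the 15- and 31-node values agree to
better than \(10^{-6}\), and the whole fit matches `lme4::glmer`
(`nAGQ = 15`) coefficients and standard errors to \(10^{-4}\) and
`glmmTMB`'s Laplace likelihood at one node. Nodes and weights come from
the Golub–Welsch eigendecomposition of the Hermite Jacobi matrix,
computed in-package and cached.

**Boundary handling.** \(\sigma_u\) is optimized as \(\log\sigma_u\) with
a soft floor at \(e^{-10}\). When the optimum sits on the floor the fit
is flagged `boundary`, the fixed-effect covariance is computed
conditional on \(\sigma_u \approx 0\) (the information for
\(\log\sigma_u\) is degenerate there), and `se_sigma` is `NA`. The
likelihood profile is continuous at 0, so data generated without site
variance reproduce the independent IRLS logistic fit (`stats::glm`) to
\(10^{-3}\) — and exactly (to \(10^{-6}\)) when \(\sigma_u\) is fixed at
0 via `fix_sigma`.

**Inference.** Standard errors come from the inverse observed information
(central-difference Hessian at the optimum). `aicc()` applies
\(-2\ell + 2k + 2k(k+1)/(n-k-1)\) with \(k\) counting fixed effects plus
the variance; `model_selection()` ranks candidate fixed-effect
structures and reports \(\Delta\)AICc and Akaike weights.
`wald_test()` tests a term's coefficient block with
\(\chi^2 = \hat\beta' V^{-1}\hat\beta\); Type-II marginality is applied,
so a main effect appearing in an interaction is tested after refitting
without that interaction, while interactions are tested in the full
model. Coefficient signs depend on the treatment-contrast reference
level (first level alphabetically), so directions — not signed
magnitudes — are the comparable quantity across analyses. Goodness of
fit is summarized by a Pearson dispersion statistic
(`dispersion_check()`); full simulation-based residual diagnostics are
out of scope.

## The simulator and what passing tests mean

`sim_config()` fixes the study conditions; `simulate_population()`,
`simulate_depletion()` and `simulate_mark_recapture()` generate data.
Default choices, made once:

* **Layout**: 5 sites × 2 transects, aspects alternating across sites,
  crest (250 m²) and slope (500 m²) transects alternating within sites —
  the shape of an intensive mark–recapture study on an outbreaking
  mid-shelf reef.
* **Abundance**: negative-binomial, mean 30 per transect, size 2. Removal
  studies report per-200 m² densities from 0.2 to 7.2 across transects;
  the NB size-2 dispersion reproduces that strong clumping, while the
  mean reflects transect totals on an outbreak reef (hundreds of animals
  over a dozen transects).
* **Detection logit**: baseline `beta0 = 0` is a very small starfish, by
  day, on the crest of a windward site at an average site (p = 0.5 — very
  small classes hover near 0.5 even at night). Size offsets (1.0, 1.1,
  1.3) are the day logits of the published size-class detectabilities
  relative to the very-small class; `beta_night = 0.6` gives the observed
  day-to-night rise; `beta_zone = -1.2` matches the magnitude of the
  reported zone fixed effect; `beta_aspect = -0.7` encodes lower
  detection at leeward sites; `sigma_site = 0.5` is a moderate among-site
  spread. Tag retention is 0.941, the published double-tag estimate.
* **Reproducibility**: one integer seed; every transect (and site) draws
  from a substream derived by stable string hashing, so identical
  configurations give byte-identical tables and enlarging the layout
  never perturbs existing transects.

The simulator deliberately matches the analysis assumptions: detection is
independent across individuals and surveys, populations are closed, and
the detection logit is exactly linear with a single site intercept. That
makes it the right tool for checking *estimator correctness* (the GLMM is
correctly specified; recovery failures would indicate bugs) and the wrong
tool for claiming *field robustness*: real starfish hide for multiple
days, move (published mean displacement ~1 m, but up to ~23 m), and
violate equal-catchability. Passing recovery tests say the arithmetic and
the optimizer are right, not that the estimators are unbiased on real
reefs.

## Numerical choices and problem sizes

* Newton mode-finding tolerance \(10^{-11}\) (step-clipped at 10);
  optimizer `nlminb` with relative tolerance \(10^{-12}\), started from
  the GLM fit with \(\sigma_u = 0.1\) and, if needed, \(\sigma_u = 1\).
* Half-up rounding everywhere an estimate becomes an integer or a
  printed 2-dp value, so results do not depend on banker's-rounding
  parity.
* Validation collects *all* violations of a survey table (negative
  counts, \(R > C\), non-consecutive survey indices) before failing.
* The test-suite simulation sizes were chosen as the smallest that make
  the Monte-Carlo noise negligible against the tolerance being asserted:
  \(10^4\) transects for the abundance law-of-large-numbers check,
  \(10^3\) replicates for estimator-consistency (1–2% tolerances), 200
  datasets of 40 sites × 5 transects for GLMM coverage, 500 null
  replicates for Wald calibration.

## Known limitations

* Only one random-effects level; no crossed/nested effects, non-logit
  links, zero-inflation, or Bayesian fitting.
* No maximum-likelihood removal estimators (Zippin / Carle–Strub) and no
  open-population (Jolly–Seber) models; closure is assumed throughout.
* No spatial movement model and no coral-community structure beyond a
  scalar cover covariate slot in the survey schema.
* Wald inference is asymptotic; with few sites the random-intercept SE
  is poorly determined (and reported `NA` at the boundary).
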