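---
title: "Scoring habitat redevelopment: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring habitat redevelopment: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groundscape)
```

`groundscape` estimates the net change in average biodiversity when a small
site's habitat composition is redeveloped. This vignette is the package's
account of the science behind each stage: the models, their assumptions, the
tunable parameters, and the choices we made where the design was genuinely
open.

## From species richness to species density

Comparative surveys report within-sample species richness over sampled
areas that differ by orders of magnitude, so the first stage standardizes
every record to a common 10 m² reference frame using power-law
species–area scaling:

$$S_{10} = S_s \left(\frac{10}{A_s}\right)^{z}.$$

The exponent `z` is a configuration value, not estimated from the collated
data: for the species *density*–area relationship, theory puts it near
0.10 (the difference between the island SAR, z ≈ 0.25, and the continental
SAR, z ≈ 0.15), while an empirical synthesis estimated 0.07 with a 95% CI
of 0.048–0.11. The default is `sar_params(z = 0.10, reference_area_m2 =
10)`; `z = 0.07` is wired into the pipeline as the supplementary
sensitivity value. We use the power-law form rather than the equivalent
log-space identity so that a richness of exactly 0 maps to a density of 0
without evaluating `log(0)`; for positive richness the two forms agree to
machine precision, and the form is invariant to the logarithm base. Because
the scaling of species *density* with area is less settled than the SAR
itself, the pipeline also carries a second response — raw within-sample
richness — through an otherwise identical model.

## The habitat model

Per-habitat expected counts are estimated by a Poisson mixed model with log
link:

$$\log \lambda_i = \beta_{\text{habitat}(i)} \;[+\; \gamma_{\text{taxon}(i)}]
\;+\; b_{\text{study}(i)}, \qquad b_{\text{study}} \sim N(0, \sigma^2).$$

* **Rounding.** Standardized densities (and figure-digitized richness
  values, which may be fractional) are rounded to integers so a Poisson
  error structure applies. Rounding is half-away-from-zero (2.5 → 3), done
  only inside the fitting stage; the raw table keeps full precision.
* **Random intercept.** Each source publication (split by methodology) is a
  "study"; its intercept absorbs between-study differences in method and
  effort. The variance is estimated by maximum likelihood with `lme4`'s
  Laplace approximation; a boundary fit (σ² = 0) is legal and reported,
  and with a single study (or `fix_sigma_zero = TRUE`) the model reduces
  to a plain Poisson GLM — which is also the closed-form oracle the test
  suite compares against.
* **Fixed effects.** Habitat is always present (coded without an intercept,
  so each coefficient is directly a log expected count — the reference
  level affects nothing reported); the taxon group (invertebrates vs
  plants) enters additively in the maximal model. No interaction is
  permitted: the collated datasets are far too sparse for one.
* **Simplification.** The taxon term is dropped when its likelihood-ratio
  p-value exceeds 0.01. The LRT statistic is `2(LL_full − LL_reduced)`
  clipped at zero; an inversion beyond 0.01 log-likelihood units errors,
  since for nested models it can only indicate optimizer failure. The
  habitat term's own LRT is always computed and reported, never silently
  assumed.
* **Predictions.** Per-habitat expectations are taken at random-effect zero
  and (when taxon is retained) at the reference taxon level, with
  delta-method standard errors on the response scale
  (`SE = estimate × SE_link`) and normal-theory 95% intervals built on the
  link scale. Whether predictions should be taken at a specific taxon level
  matters only if the taxon term survives simplification; for data
  resembling the reference conditions it does not.

When the zone inventories of a wildlife-garden database are included as
sites, we treat the whole database as a single study: its records share one
recording methodology, which is exactly what the random intercept models.

## Completing the coefficient set

Six habitats (plus hard-standing) typically lack usable comparative data.
`default_transfer_rules()` completes them:

* hard-standing → exactly (0, 0), "assumed-zero";
* ferns/cycad planting ← introduced shrubs; Paleogene Asteraceae ←
  short/perennial vegetation; Neogene grass ← amenity grass/turf (copies);
* species-poor hedgerow ← species-rich hedgerow, introduced shrubs ←
  broadleaved woodland, Cretaceous angiosperm shrubs ← broadleaved
  woodland (multiplicative ratios).

"Adjusted" transfers are implemented as a ratio on the response scale: a
ratio preserves non-negativity and scales the standard error coherently.
The adjustment values themselves come from single comparative studies and
are user-supplied configuration; they ship as 1.0 (plain copy) with a loud
warning until study-derived values are provided. Note that the rule table
is *chained one level*: the ferns/cycad coefficient is the
introduced-shrubs coefficient, which is itself adjusted from broadleaved
woodland. `apply_transfers()` therefore resolves rules iteratively within
one application — a rule may source a habitat completed by an earlier rule
in the same set — and errors only if a source never becomes available.
Modelled entries are never overwritten and reapplication is a no-op.

## Scoring layouts: the three area-scaling assumptions

A layout is a habitat → area map; its score is the area-weighted sum
Σₕ scoreₕ·areaₕ. The three assumptions bracket the uncertain area-scaling
of species density:

| | coefficient | output rescaling |
|---|---|---|
| A1 | density (per 10 m²) | rescaled to patch area via `z` |
| A2 | density (per 10 m²) | none |
| A3 | within-sample richness | none |

Under A1 each habitat type's total area is treated as one effectively
contiguous patch — the layout table supplies per-type totals, not patch
polygons. This flatters fragmented layouts (their score is computed as if
contiguous), a conservative direction when the fragmented layout is the
baseline. A1 with `z = 0` reduces exactly to A2, which the tests exploit.
Percent change is `100·(proposed − current)/current`; a zero current total
is reported as undefined rather than infinite, since empty baselines are
legal inputs. The scores are unitless index values for comparing layouts,
not absolute species counts for the site.

## Monte Carlo sensitivity

Coefficient uncertainty is propagated by drawing each habitat's
coefficient independently from `N(estimate, SE)` — with the SE multiplied
by 1.5 for transferred habitats, reflecting their extra uncertainty —
while assumed-zero habitats stay at exactly 0. Three deliberate choices:

* **One draw per replicate feeds both scenarios.** Each replicate compares
  "before" and "after" under the same coefficient realization; independent
  per-scenario draws would manufacture spurious variance in habitats the
  two layouts share.
* **Negative draws are kept by default.** Truncation at zero
  (`clip = TRUE`) is available and exercised by the tests, but clipping
  biases totals upward, so the default reports the untruncated normal.
* **Draws are independent across habitats.** The fitted model's
  between-coefficient covariance is small relative to the transferred-SE
  inflation, and habitat-by-habitat draws keep the procedure transparent.

Because every total is linear in the coefficient vector, replicates are
computed as a draws-matrix product with precomputed area weights; 10⁵
replicates take well under a second. The seed is recorded in the result
object and report, and a rerun with the same seed is bit-identical.

## Compositional similarity

From zone-level occurrence records (zone, habitat, species, year), species
are unioned per habitat over a year window — 2013–2015 by default, a
multi-year window because species can be missed in any single survey year
while older records become unrepresentative. The similarity entry
`M[x, y] = 100·|S_x ∩ S_y| / |S_x|` is the percentage of habitat x's
species also present in habitat y; the denominator is the row habitat's
own count, so the matrix is deliberately asymmetric. Rows for habitats with
no in-window records are reported as missing, not 0 — an empty list is no
evidence of dissimilarity. Species-name standardization is delegated to an
optional synonym table (national checklist databases are not bundled), and
the zone → habitat mapping is an input, not a constant. Symmetric indices
(Sørensen and relatives) are deliberately not part of the headline output.

## The synthetic-data generator

Every stage is testable without downloads because the generator emulates
all three inputs with known ground truth:

* **Literature tables.** Sites follow the fitting model exactly:
  `λ = D_h (A/10)^z exp(b_study + γ·1[invertebrates])`, richness ~
  Poisson(λ), `b_study ~ N(0, σ²)`. Defaults mirror the reference study
  conditions: 14 studies, study-level sd 0.4, sampled areas log-uniform on
  [7, 6 250 000] m². (A log-uniform on that range has median ≈ 6 600 m²,
  larger than the ≈1 500 m² median of real collated surveys; the shape of
  the area distribution does not enter the model, so we kept the simpler
  law.) The default true densities span 3–32 species per 10 m², high for
  calcareous and neutral grassland and low for ponds and fen, the ordering
  seen in urban-habitat surveys. Embedding the SAR exponent in the mean
  structure makes the convert → round → fit chain consistent by
  construction, so parameter recovery tests the whole pipeline, not just
  the fitter.
* **Occurrence tables.** Each habitat retains every species of a shared
  pool independently with probability `p_h`, giving the closed-form
  expected similarity `E M[x, y] ≈ 100·p_y` for `x ≠ y`. Arbitrary
  *pairwise* overlap targets are not jointly satisfiable by independent
  sets, so the per-habitat retention vector is the supported
  parametrization.
* **Layouts.** A fixed total area is split by scenario weights, so the A2
  percent change has the analytic form `analytic_percent_change()`
  provides.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: overdispersion beyond the study intercept,
taxonomic misidentification, non-independence of sites within a study
beyond the shared intercept, habitat misclassification in the source
papers, and digitization error in figure-extracted richness. Fits to real
collated tables should expect some lack of fit that the synthetic world
cannot show.

## Numerical choices and test calibration

* Rounding: half-away-from-zero via `floor(x + 0.5)` (base `round()` is
  half-to-even).
* `0^0`-safe rescaling: a zero-area patch scores 0 whenever `z > 0` and is
  the identity when `z = 0`.
* LRT inversion tolerance: 0.01 log-likelihood units.
* Singular-fit and convergence messages from the mixed-model backend are
  captured into the fit's `notes` rather than printed; a genuine
  convergence failure flags the fit, and predictions from a flagged fit
  are refused.
* Parameter-recovery conditions in the acceptance tests: 100 replicates of
  a crossed design — 20 studies each sampling all 8 habitats once
  (160 sites) — with σ = 0.4 and z = 0.1. The crossed design is the plain
  reading of "20 studies × 8 habitats"; we verified the coverage property
  is stable across independent seed blocks before freezing the test seeds.
  The end-to-end tolerance was calibrated from 100-replicate runs at
  exactly these conditions (percent-change error sd ≈ 1.8 points): the
  test requires the mean estimate within 1 point of the analytic truth and
  mean absolute error below 2.5 points, both several standard errors wide
  of the calibrated behaviour rather than hard-coded optimism.
* Problem sizes throughout the suite (112–320-site tables, 10⁵-replicate
  sensitivity checks, 50-set similarity oracles) were chosen so the whole
  test run completes in about a minute on a single core while leaving
  Monte Carlo margins of at least three standard errors.

## Limitations

Habitat age, edge effects, connectivity and abundance structure are out of
scope: comparative data sufficient to model them are generally not
available at this spatial scale, and the package makes no attempt to
extrapolate them. The similarity analysis is presence-only (no rarefaction
or abundance weighting). Scores compare layouts of the *same* site under a
common coefficient set; they are not transferable biodiversity valuations
across sites. Finally, transferred coefficients inherit the cited single
studies' idiosyncrasies — which is precisely why their uncertainty is
inflated in the sensitivity stage and their ratios are explicit, overridable
configuration.
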