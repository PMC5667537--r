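# groundscape

Estimating the net biodiversity impact of redeveloping a small urban site.

When the habitat composition of a site — a museum garden, a campus, a park —
is about to change, planners need a number: will the redevelopment gain or
lose biodiversity overall? `groundscape` implements a transparent,
data-driven answer for sites described as a table of habitat types and
areas. It combines (i) species richness collated from comparative surveys in
the primary literature, (ii) species–area theory to put samples of wildly
different sizes on a common footing, and (iii) a mixed-effects meta-analysis
to score each habitat type, so that two layouts of the same site can be
compared as area-weighted sums.

## The model

**Species density.** Within-sample species richness grows with the sampled
area, so raw counts from different surveys are not comparable. Each site's
richness *S*ₛ sampled over area *A*ₛ is standardized to the expected species
density in a 10 m² reference frame using the species(-density)–area
relationship

&nbsp;&nbsp;&nbsp;&nbsp;*S*₁₀ = *S*ₛ · (10 / *A*ₛ)^*z*,

with *z* = 0.10 by default (the theoretical value for the species
density–area relationship; the empirical alternative *z* = 0.07 is available
for sensitivity runs).

**Habitat coefficients.** Standardized densities (rounded to integers) are
modelled as Poisson counts with a log link:

&nbsp;&nbsp;&nbsp;&nbsp;log *λ*ᵢ = *β*_habitat(ᵢ) [+ *γ*_taxon(ᵢ)] + *b*_study(ᵢ),
&nbsp;&nbsp;&nbsp;&nbsp;*b*_study ~ N(0, σ²),

where the study-level random intercept absorbs methodological heterogeneity
between source publications. The additive taxon-group term is dropped by
likelihood ratio when *p* > 0.01. A parallel model of raw within-sample
richness is fitted separately. Habitats without usable survey data are
completed by transfer rules (copying or ratio-adjusting the coefficient of
an ecologically similar modelled habitat); hard-standing is assumed to hold
zero species.

**Scenario scores.** A layout's biodiversity score is Σₕ (habitat score ×
areaₕ), computed under three assumptions about how within-sample diversity
scales with habitat area: A1 rescales the density coefficient to the patch
area via *z*; A2 uses the density coefficient as-is; A3 uses the richness
coefficient. The headline result is the percent change between the current
and proposed layouts, with uncertainty propagated by Monte Carlo resampling
of the coefficients (normal draws; transferred habitats get their standard
errors inflated ×1.5). An asymmetric percent-shared-species matrix built
from zone-level occurrence records summarizes how plant composition
overlaps between habitats.

## Worked example

Everything is testable without any field data: the package ships a
generator that simulates literature tables from the same model the fitter
assumes.

```r
library(groundscape)

sim <- simulate_literature(seed = 2026)         # 14 studies, 112 sites
fit <- simplify_habitat_model(sim$studies, response = "density10")
fit$lrt
#>   term         chisq    df  p_value dropped
#> 1 taxon_group   2.48     1 1.15e- 1 TRUE
#> 2 habitat     453.      11 3.85e-90 FALSE
```

The taxon effect is not significant at the 0.01 threshold and is dropped;
species density differs strongly between habitats. Completing the
coefficient set and scoring the two shipped grounds layouts:

```r
coeffs <- apply_transfers(habitat_predictions(fit$model))
rich   <- simplify_habitat_model(sim$studies, response = "richness")
coeffs_r <- apply_transfers(habitat_predictions(rich$model))

assess_layouts(coeffs, coeffs_r,
               grounds_layout("current"), grounds_layout("proposed"))
#> Layout assessment: current -> proposed (z = 0.1)
#>   assumption total_current total_proposed percent_change
#> 1 A1               227490.        273116.           20.1
#> 2 A2               135801.        164509.           21.1
#> 3 A3               278693.        333867.           19.8
```

Under every area-scaling assumption the proposed layout scores higher: a
net gain of ~20% in average biodiversity for this synthetic coefficient
set, driven by the expansion of high-density habitats (woodland,
grasslands). How robust is the sign of that change to coefficient
uncertainty?

```r
run_sensitivity(coeffs, grounds_layout("current"), grounds_layout("proposed"),
                assumption = "A1", n_reps = 1000, seed = 1)
#> Sensitivity analysis (A1, 1000 reps, seed 1)
#>   fraction of replicates with net loss: 0
#>   percent-change quantiles:
#>  2.5%   25%   50%   75% 97.5%
#> 11.78 16.89 20.19 23.23 29.83
```

No replicate loses biodiversity: the estimated gain is robust. The same
stages run end to end via `run_full_pipeline()`, which also emits a
traceable JSON+CSV report bundle, and each result type has `tidy()`,
`glance()` and `autoplot()`/`plot_*()` methods (coefficient forest plot,
sensitivity histogram, similarity heatmap).

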