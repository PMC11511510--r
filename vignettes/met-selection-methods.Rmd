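---
title: "Models and methods behind the metsel trial-analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the metsel trial-analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsel)
```

## The trial and its two models

metsel analyses two-year multi-environment trials (METs) of quinoa
accessions laid out as randomized complete blocks with column effects:
every accession appears once per block, three blocks per year, and the
plots of a block are grouped into four columns so that accessions expected
to mature together can be harvested together. The default dimensions — 48
accessions x 2 years x 3 blocks = 288 plots — are those of the reference
field trial in northern Germany whose published summary statistics seed
the package's defaults.

Two single-trait models drive everything else.

**Fixed-G×Y model** (inference on accession means):

$$y_{ijk} = \mu + g_i + a_j + (ga)_{ij} + b_k + e_{ijk},$$

with fixed accession ($g_i$), year ($a_j$) and accession-by-year
($(ga)_{ij}$) effects and random blocks ($b_k$). Residuals are by default
heteroscedastic by year and correlated across years within an
accession-by-block cell — the only physical unit shared between the two
re-randomized years. When that structure is not estimable the fit falls
back automatically to per-year variances only, then to iid residuals, and
records which structure was used. All reported quantities (cell means,
contrasts, ANOVA F statistics) are functions of the accession-by-year cell
means and therefore invariant to the reference-level coding used
internally.

**All-random model** (variance components for heritability):

$$y_{ijkl} = \mu + g_i + a_j + (ga)_{ij} + b_k + (ba)_{kj} + c_l + e_{ijkl},$$

where additionally $(ba)_{kj}$ is the block-by-year interaction and $c_l$
the column effect. Columns are treated as nested in block-by-year (4
columns x 3 blocks x 2 years = 24 levels). A flat 1..48 column indexing
sometimes seen in field-book conventions is ambiguous about the intended
level structure; nesting in block-by-year is the only reading consistent
with "four columns within each block" of a re-randomized two-year trial,
so that is what both the generator and the model use.

The all-random model is fitted by REML through lme4's modular interface.
Because the profiled REML deviance is extremely flat near its optimum, the
default optimizer result is polished with Nelder–Mead restarts,
coordinate-wise Brent steps and finite-difference Newton iterations
(`refine = TRUE`): on balanced data an interior REML optimum must
reproduce the closed-form expected-mean-squares (Henderson method 3)
estimators, and the polish brings agreement from roughly 1e-3 to better
than 1e-7 relative. Components that the optimizer pins at zero are
reported with a boundary flag rather than being dropped. `refine = FALSE`
skips the polish in large simulation loops where the last digits are
irrelevant.

The Wald ANOVA uses residual (containment) denominator degrees of freedom,
$n - p = 192$ at the default design. Kenward–Roger or Satterthwaite
refinements would change nothing material in a balanced 288-plot trial and
are deliberately out of scope.

**Pseudo-R².** The conditional pseudo-R² is the squared Pearson
correlation between observed values and fitted values including predicted
random effects. Several estimators circulate under this name; the
conditional squared correlation was chosen because it is well defined for
every residual structure the pipeline can select, and it is the quantity
users informally expect ("how much of what I saw does the model track").

## Heritability

Entry-mean broad-sense heritability uses the variance components of the
all-random model:

$$h^2 = \frac{s_g^2}{s_g^2 + s_{ga}^2/J + s_r^2/(JK)},$$

with $J$ years and $K$ blocks per year — divisors 2 and 6 at the default
design. The divisors are parameters (`n_years`, `n_blocks`) rather than
hard-coded constants, defaulting to the reference design.

A desk check worth knowing about: applying the formula to the reference
trial's published (rounded) components reproduces the published $h^2$ at
two decimals for ten of twelve traits. Thousand kernel weight recomputes
to 0.88 against a printed 0.86, and panicle shape to 0.28 against 0.29.
Both discrepancies are exactly what rounding the inputs to two decimals
does to a ratio of small numbers (TKW's components are 0.06/0.01/0.02),
so the package treats them as input-rounding artifacts, asserts the ten
matches, and documents the two exceptions rather than forcing them.

## Multiple contrast tests

Grand-mean contrasts compare each accession's cell mean in a year with the
average over all accessions in that year (the *grand mean difference*,
GMD); year contrasts compare each accession's two yearly means. Both
families are adjusted with the single-step max-|t| procedure: the adjusted
p-value of hypothesis $i$ is $P(\max_j |T_j| \ge |t_i|)$ under the joint
multivariate t distribution of the family with the correlation implied by
the fit. The integral is estimated by seeded Monte Carlo (default 100,000
draws), making every adjusted p-value reproducible from the run seed;
Šidák and Bonferroni are available as conservative fallbacks for
non-positive-definite correlation inputs. For a single hypothesis the
adjusted p-value is the exact two-sided t probability, and the adjusted
values are never allowed below the raw ones (the analytic relation that
Monte-Carlo noise could otherwise violate). The test suite checks the
Monte-Carlo integration against an independent Gauss-quadrature oracle in
the equicorrelated case, and against multcomp's `glht` on an identical
fit.

The significance ladder is fixed at 0.05/0.01/0.001, matching the star
conventions of field-trial reports. An accession is *stable* when the
family-wise adjusted p-value of its between-year index contrast is at or
above 0.05 — stability here is strictly "no evidence of a year effect on
the selection index", not an Eberhart–Russell-style regression statistic.

Pearson correlations between traits are computed per year on accession
means by default (each accession contributes one value per trait per
year), with Fisher-z 95% confidence intervals. Plot-level correlation is
available as an option; accession means are the default because several
of the scored traits are recorded once per plot on coarse ordinal scales,
where plot-level product-moment correlations are hard to interpret.

## Selection index and selection rule

For the index traits (default: thousand kernel weight, seed yield, days to
flowering, plant height, downy mildew susceptibility, saponin content),
accession-by-year adjusted means — the model cell means, equal to
arithmetic means under balance — are z-scored within year across
accessions (sample SD, $n-1$), sign-flipped for lower-is-better traits so
that larger is always better, and combined as

$$I = \sum_m h^2_m\,\tilde y_m,$$

the heritability-weighted sum of oriented standardized values. One
two-year $h^2$ per trait weights both years identically. Accessions are
ranked by descending index per year; ties break by accession label order.

To test the index for year stability it is rebuilt at plot level: each
plot's trait values are standardized with the *accession-level*
within-year constants, oriented, weighted and summed, which makes the
plot-level index's cell means reproduce the accession-level index exactly
under balance. The plot-level index then runs through the fixed-G×Y model
like any other trait, giving its own ANOVA, GMD tests and year contrasts.

The final selection is a narrative rule made explicit so it can be audited
or reweighted: each criterion trait (the six index traits plus the index
itself) contributes the number of years with a significant favorable GMD,
provided the other year shows no significant unfavorable GMD — a trait
with conflicting significant directions across years contributes the
negative of its unfavorable count instead. Accessions are ordered by total
score, then index stability, then mean index rank, then label, and the top
$k$ (default 10) are selected, each with a one-line rationale naming the
traits that carried it.

## The synthetic-data generator

No plot-level data are deposited for the reference trial, so the generator
is a first-class module, not a fixture: it draws from the all-random model
with, by default, the reference trial's published genotype, year, G×Y and
residual components and published trait means. Block, block-by-year and
column variances default to zero because the reference report does not
print them — they are nuisance strata the models must handle, not
quantities the simulation needs to emulate. Days to maturity, absent from
the published component table but needed for the correlation structure,
uses mean 130 d, $s_g^2 = 20$, $s_{ga}^2 = 8$, $s_r^2 = 4$ — plausible for
accessions pre-selected to mature within 160 days in northern Germany.

Genotype effects are drawn jointly across traits from a correlation matrix
emulating the published per-year correlation pattern (DTF–DTM–plant-height
cluster at 0.5–0.8; yield positively tied to TKW, DTF, DTM and panicle
density; mildew and lodging negatively tied to yield; saponin higher in
later, higher-yielding material). Residuals can be heteroscedastic by year
and correlated across years; the correlation is attached to the
genotype-by-block cell, the only unit shared across years, defaulting to
zero. All randomness flows from one seed through a fixed draw order, so a
seed fully reproduces a dataset. Bounds (percentages to [0, 100], scores
to their 1–9 / 1–5 scales) and rounding grids (integer days for DTF/DTM)
are applied after all effects are summed.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: spatial row–column autocorrelation beyond the
column stratum; genuinely ordinal scoring (scores are clamped Gaussians,
not threshold variables); multi-location structure; and non-Gaussian
year effects. One visible consequence: a trait with a large year variance
and a floor at zero (saponin: year SD ≈ 5.4 mm on a mean of 10.7 mm) will
occasionally draw a year that clamps nearly all its plots to zero,
collapsing the within-year genetic signal in a way no real trial year
would. That is a faithful rendering of the stated variance magnitudes
under a Gaussian year effect, and it is left visible rather than patched,
but simulated heritabilities for floor-limited traits should be read with
this in mind.

## Numerical choices and validation sizes

* REML polish as described above; tolerance for declaring a component at
  the boundary is 1e-8 of the component total.
* Monte-Carlo max-|t| with 100,000 draws by default (standard error on an
  adjusted p near 0.05 is about 0.0007); simulation studies inside the
  test suite use 10,000–20,000 draws, where the extra noise is immaterial
  against their own replication error.
* The validation suite uses: 500 replicate trials for the
  method-of-moments check of the generator; 200 replicate trials for
  parameter recovery of the DTF components (mean $\hat h^2$ within 0.05,
  mean $\hat s_g^2$ within 10%); 1000 null trials for family-wise error
  control of the grand-mean procedure; 300 trials for Fisher-z coverage;
  and 50 trials for planted-signal selection recovery, with ten accessions
  shifted favorably by two genetic SDs on every index trait. These sizes
  put the Monte-Carlo error of each check well below the tolerance it
  asserts while keeping the whole suite comfortably desk-scale.
* Degenerate inputs fail loudly: zero-SD traits cannot be standardized,
  missing index traits are never imputed, all-zero variance components
  make $h^2$ undefined, non-PSD correlation inputs name the Šidák
  fallback.

## Known limitations

Single-location trials only; no spatial covariance models; no multi-trait
REML (the genetic correlations in the generator are a simulation device,
not an estimation target); no economic-weight or desired-gains indices; no
step-down or FDR multiplicity control; heritability is broad-sense on an
entry-mean basis with no standard errors. The exact pseudo-R² estimator
and residual correlation object used in any given published analysis of
this design are rarely stated precisely; where this package had to choose,
the choices above are documented and the code paths are small enough to
swap.
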