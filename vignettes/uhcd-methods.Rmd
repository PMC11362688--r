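---
title: "Methods: constructing and analysing a district-level UHC index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and analysing a district-level UHC index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhcd)
```

## The model

`uhcd` measures district health-system performance with a composite
index on the 0–100 scale. Twenty-four tracer indicators — each a
district-level percentage — are arranged in a fixed hierarchy of 17
tracer areas inside 5 tracer domains (RMNCH, infectious diseases,
NCDs, service capacity and access, financial risk protection). Two
indicators, the incidences of catastrophic health expenditure and of
impoverishment by health spending, run the wrong way and are
complemented (`100 − x`) before any aggregation.

Aggregation is a geometric mean at every level: indicators into their
area, areas into their domain, and the five domains into `UHC_d`. The
geometric mean is deliberately intolerant of weak components — a
district cannot compensate for collapsed cancer screening with good
immunization — and it makes the index multiplicative:
`UHC_d = (SC⁴·FRP)^{1/5}`, where the service-coverage component SC is
the geometric mean of the four non-financial domains. Equal weights are
applied *within each level*, which is what the hierarchy implies; a
consequence worth knowing is that an indicator that is alone in its
area (e.g. the TB treatment success rate) carries more influence than
one of four indicators sharing an area. This is a property of the
hierarchical design, not a bug, and the flat-geometric variant
(equal weight on all 24 indicators) is provided for comparison.

### Assumptions

- Indicator values are comparable percentages in \[0, 100\]; the package
  validates but does not reweight for survey design (weights belong to
  the upstream estimation that produced the district percentages).
- All 24 indicators must be present before the index is computed;
  imputation is an explicit prior stage, never silent.
- District and state identifiers are opaque strings; nothing is
  inferred from them.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `floor` | 0.1 | percentage points | A single true zero would annihilate every geometric mean above it. 0.1 is below any plausibly measured non-zero coverage (screening coverages below 1% occur in practice) yet keeps `log` finite. Configurable and logged. |
| aggregation `method` | `geometric` | — | Headline construction; `arithmetic` and `flat_geometric` serve the sensitivity battery. |
| tercile rule | remainder to lowest groups | — | 687 divides evenly into 229/229/229; for general `n` the remainder goes one-per-group to the lowest groups (7 → 3/2/2), ties broken by lexicographic district id. Stated so outputs are reproducible. |
| quantile convention | linear interpolation (type 7) | — | Medians/IQRs in summary tables are reproducible against R's default. |
| achievement aversion `v` | 2 | — | The canonical choice, under which `A = μ(1 − C)` exactly. |
| hot-deck strata | state | — | Survey gaps are geographic; state is the natural donor pool. Configurable. |
| regression covariates | insurance coverage + state intercepts | — | The financial-risk incidences are imputed from the one indicator in their domain that is widely observed, plus state fixed effects. Configurable. |

## Equity

Subgroup indices use a ratio construction: the geometric mean of the
14 equity-subset indicators in the subgroup, divided by the same
geometric mean for the district population, multiplied by the
district's `UHC_d` (capped at 100, since advantaged subgroups can
exceed the district average). The flat geometric mean over the subset
is used rather than the area/domain hierarchy: the subset covers only
some areas, so a hierarchical version would re-weight arbitrarily; the
hierarchy-free ratio is also homogeneous of degree 1 (halving every
subgroup value exactly halves the subgroup index), which the tests
assert. The shipped equity subset (all RMNCH, WASH, all NCD, health
insurance — the household-survey indicators) is a documented default
and can be replaced in the registry YAML.

The concentration index uses midpoint fractional ranks
`R_i = (i − 0.5)/n` (worst-off first, ties share the mean of their
positions) and `C = (2/(nμ))·Σ x_i R_i − 1`. Under this rank
convention no extra small-sample correction is needed: `C` is exactly 0
for constant values and the Wagstaff identity `A(2) = μ(1 − C)` holds
to machine precision, which the test suite uses as an independent
oracle. The district-level achievement analysis ranks districts by
multidimensional poverty (poorest first); in the sensitivity variant
the achievement mean replaces the plain mean at the tracer-area level
over a district's five wealth-quintile profiles, falling back to the
baseline area score where quintile data are missing (fallbacks are
recorded).

## Variance partition

The two-level null model `y_ij = β₀ + u_j + e_ij` is fitted by REML
(`lme4`), the standard estimator for variance components; a one-way
ANOVA method-of-moments estimator with the unbalanced-design correction
(`n₀ = (N − Σn_j²/N)/(J−1)`, negative estimates truncated at 0) ships
alongside as an independent cross-check, and the two are required to
agree within 2 percentage points of between-share on balanced designs.
Confidence intervals come from the profile likelihood on the SD scale
and are squared; the reported SE is the large-sample width
approximation. Single-district states stay in the model fit (they
inform the intercept and, weakly, the between variance) but are omitted
from coefficient-of-variation tables, where a sample SD of one value
does not exist.

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the *statistical structure* the analysis
consumes, with defaults fixed once to the published world: 687
districts over 33 states using the published per-state counts
(including a single-district state), state effects
`N(0, 31.5)` and district effects `N(0, 13.9)` in percentage-point
variance (between share 69.4%), domain targets at the published domain
medians (RMNCH 64.8, infectious 82.8, NCD 9.8, capacity 54.9, FRP
66.6), a 7-point poorest-quintile shortfall with a linear gradient
across quintiles (so the quintile mean matches the district), smaller
shortfalls for rural residence (3), religious minority (2) and
social group (4) — values chosen once as plausible relative magnitudes,
wealth being the dominant axis — and a multidimensional poverty index
whose correlation with latent quality is tuned to −0.5 by bisection on
the signal-to-noise mixing weight.

Every indicator of a district shares one latent quality
`q = state effect + district effect`; by default there is **no**
independent per-indicator noise (`sigma_indicator = 0`), which is the
simplest model consistent with a variance-components analysis. Three
consequences a user should understand:

- All districts in a domain differ only through `q`, so alternative
  aggregations are near-monotone transforms of one latent score and the
  sensitivity battery's Spearman correlations sit near 1. This makes
  the rank-stability machinery *testable* (ordering of variants,
  AM–GM bounds, exact identities) but the published, data-specific rho
  values (0.86–0.99) are not targets and are not asserted. Setting
  `sigma_indicator > 0` produces a non-degenerate battery.
- The index is a nonlinear (log-scale) monotone transform of `q`, so
  the between-state variance share of the *index* is mildly deflated
  relative to the latent 69.4% (measured ≈ 65–66% over 200
  replicates). The acceptance suite therefore checks REML parameter
  recovery within ±3 points on data drawn directly from the two-level
  model, and within ±6 points through the full simulate → index route.
- A green synthetic test establishes correctness of the *computation*,
  not of any substantive claim about real districts: the generator has
  no survey sampling error, no real marginals beyond domain medians,
  and no spatial structure beyond state clustering.

Values are clamped to \[0.1, 99.9\], so the generator never produces
the exact bounds and never produces missing cells; missingness is a
separate, explicit operation (cell-wise MCAR, or whole
service-capacity blocks per district, mimicking facility-survey gaps).

## Imputation

Three mechanisms, applied in a fixed order by `impute_all()`:

1. **Parent inheritance** for redistricting: a child district copies
   its missing values from its mapped parent, single-step only (a
   parent that is itself missing the value is an error, not a chain).
   This is a deliberate approximation of redistricting-imputation
   procedures whose exact published rule is not reproduced here.
2. **Hot-deck** within state strata for the service-capacity block:
   each recipient draws one complete donor district uniformly (one
   donor per recipient, so a donor's profile stays internally
   coherent); imputed values are always members of the observed donor
   support. No cross-stratum fallback unless explicitly enabled.
3. **Regression** for the financial-risk incidences: OLS on configured
   covariates plus state fixed intercepts over complete cases, fitted
   values clamped to \[0, 100\].

A single draw (not multiple imputation) is used because the pipeline
produces one point estimate per district; no imputation uncertainty is
propagated. Provenance flags for every imputed cell are carried into
the run log.

## Numerical choices and degenerate inputs

- Geometric means floor their inputs at `floor` before `log`; results
  therefore live in \[floor, 100\].
- Tercile ties are broken by district id; the remainder rule is stated
  above.
- Fractional ranks use `(i − 0.5)/n` with tie-averaged positions — a
  two-way tie at sorted positions 2 and 3 of four units yields 0.5.
- `spearman_rho` of two *fully tied* rankings is defined as 1 (the
  orderings are identical); one-sided constancy is an error.
- Variance estimates are truncated at zero; a single state is an
  identification error, not a zero.
- The MPI bisection stops at |r − target| < 0.005 or 60 iterations;
  with constant latent quality the MPI degenerates to pure noise.

## Known limitations

- The equity subset and the hot-deck stratification are documented
  assumptions, user-overridable, not published facts.
- The achievement-adjusted variant is one defensible placement
  (area-level, wealth-quintile profiles) of an underspecified
  adjustment; a district-level alternative (achievement summary over
  districts ranked by MPI) is available through
  `achievement_index()` + `fractional_rank()` directly.
- Reported medians/ranges of the synthetic scenario are properties of
  the generator, not reproductions of survey results.
- No population weighting, choropleth mapping, or survey microdata
  parsing.
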