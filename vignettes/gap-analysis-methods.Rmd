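---
title: "Methods: protected-area representativeness of plant gamma diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protected-area representativeness of plant gamma diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagap)
```

## The question

A protected-area network is *representative* of a region's flora when the
species richness recorded inside it approaches the region's gamma diversity
— the total species richness beyond any single site. `pagap` implements a
gap-analysis pipeline that asks, for a network of protected polygons overlaid
on a network of vegetation plots: what share of the regional species pool is
recorded at least once inside the protected network, how does that share vary
across analysis units (country × biogeographical region), and does protected
land host more species than unprotected land once area is taken into account?

The pipeline has five analytical stages, each exposed as ordinary functions
and composed by `run_gap_analysis()`:

1. **Eligibility and classification** — plots are filtered on location
   uncertainty (≤ 10 km), survey year (≥ 1994, the network's formal
   establishment year) and habitat (human-made EUNIS level-1 class V
   excluded), then classified inside/outside by the share of a circular
   buffer (radius = location uncertainty) overlapping the protected layer,
   with a strict > 50 % rule.
2. **Richness estimation** — per-unit incidence summaries feed the Chao2
   estimator, with Michaelis–Menten and asymptotic-regression asymptotes
   fitted to exact sample-based rarefaction curves as robustness companions.
3. **Partitioning** — species observed inside only, outside only, and shared,
   with percentages against the observed union (native mode) or an external
   reference list (priority mode).
4. **Species–area contrast** — power, extended-power and Kobayashi curves
   fitted to per-unit Chao2 estimates inside and outside, selected by AICc,
   contrasted by bootstrap CIs.
5. **Validation** — deviation-coded binomial GLMs flag units departing from
   the network-wide mean while controlling for sampling effort, and
   propensity-score matching re-runs the comparison on an environmentally
   balanced plot subset.

## Models and formulas

**Chao2.** For a stratum sampled by `m` plots with observed richness
$S_{obs}$, $Q_1$ species in exactly one plot and $Q_2$ in exactly two,

$$\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1^2}{2 Q_2} \quad (Q_2 > 0),
\qquad
\hat S = S_{obs} + \frac{m-1}{m}\,\frac{Q_1 (Q_1 - 1)}{2} \quad (Q_2 = 0),$$

i.e. the small-sample factor and the bias-corrected branch, matching the
convention of the standard incidence-based toolchains. Chao2 is a lower
bound: it equals $S_{obs}$ exactly when $Q_1 = 0$ (or $Q_1 = 1$ on the
bias-corrected branch) and otherwise exceeds it, but it generally
underestimates the true pool under strong rarity, which is why the pipeline
cross-checks it against two saturating-curve asymptotes.

**Rarefaction.** The expected richness in `t` of `m` plots is computed
exactly, $E[S(t)] = S_{obs} - \sum_i \binom{m-f_i}{t}\big/\binom{m}{t}$,
evaluated through `lchoose` differences so large `m` does not overflow. The
Michaelis–Menten model $S(t) = S_{max} t/(B+t)$ and the asymptotic-regression
model $S(t) = a - b e^{-kt}$ are fitted to that curve by Levenberg–Marquardt
least squares and their asymptotes ($S_{max}$, $a$) reported as alternative
richness estimates.

**Species–area relationship.** Areas enter in units of 100 km², so the power
model's constant `c` is the expected richness of a 100 km² patch — the
smallest scale at which the analysis units are comparable — and extrapolation
below the observed range is avoided. Candidate models are the power curve
$S = cA^z$, Tjørve's first extended-power form $S = cA^{zA^{-d}}$ (the
extended family has several parameterizations; this one nests the power
model at $d = 0$ and is recorded as a swappable configuration choice), and
the Kobayashi logarithmic curve $S = c\ln(1 + A/z)$. All are fitted on the
untransformed richness scale so that non-nested models are comparable by a
single least-squares AICc,

$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2K + \frac{2K(K+1)}{n-K-1},
\qquad K = k + 1,$$

where the error variance counts as a parameter. Ties within $10^{-9}$ go to
the model with fewer parameters and then to the plain power model, mirroring
the practice of preferring the simplest, most interpretable curve when AICc
differences are negligible. Parameter uncertainty uses a nonparametric case
(pairs) bootstrap — resample units with replacement, refit, take the
2.5/97.5 percentiles — with `B = 1000` by default; replicates that fail to
converge are dropped and counted, and more than 20 % failures raises a
warning (an error in strict mode). Two groups are contrasted by whether
their 95 % intervals overlap.

**Deviation GLM.** The per-unit proportion of species recorded inside the
network (successes = species inside including shared, trials = species
total) is modelled as an aggregated binomial with logit link. The unit
factor (country or bioregion) is *sum-to-zero coded*, so each coefficient is
a departure from the network-wide mean and the implicit last level is
recovered as minus the sum of the others with variance $\mathbf 1' V
\mathbf 1$ over the coefficient block. Plot density inside the network
(plots/km²) enters as a linear effort covariate; a quadratic term is kept
only when it improves AICc by more than 2 *and* its 95 % Wald CI excludes
zero. Explained deviance is $D^2 = 1 - D_{res}/D_{null}$ (defined as 0 when
the null deviance is 0). Levels whose 95 % CI lies entirely above (below)
zero are flagged as hosting a higher (lower) share of their unit's species
than the network-wide average. Wald rather than profile intervals are used:
at aggregated-binomial counts in the hundreds they are essentially
identical and much cheaper. No overdispersion adjustment is applied, and no
multiplicity correction across levels.

**Matching.** Propensity scores are fitted by logistic regression of INSIDE
status on five continuous covariates (mean annual temperature, annual
precipitation, temperature and precipitation seasonality, elevation) plus
bioregion and country factors. Matching is greedy 1:1 nearest neighbour
without replacement on the *logit* of the score — the standard scale for
caliper matching — with the caliper at 0.25 SD of the logit scores. Treated
plots are processed in decreasing score order with ties broken by plot id;
these two choices are deterministic conventions, recorded here rather than
inferred from any authority. Balance is summarized by standardized mean
differences using the pre-matching pooled SD, so before/after values share a
scale; categorical covariates are expanded to per-level proportion
differences.

## Geometry

No polygon-geometry package is assumed: the classification needs only a
small set of exact planar primitives, implemented directly. Buffers are
regular 64-gons (the inscribed-polygon area deficit at 64 segments is
≈ 0.16 %, far below the 50 % decision threshold; the half-disc test in the
suite bounds the end-to-end error at 1 %). Overlap fractions are computed by
Sutherland–Hodgman clipping of each protected polygon against the convex
buffer, summing per-feature intersection areas — exact when protected
features have disjoint interiors, which the synthetic landscapes guarantee
and the function documents as an input assumption. A zero-radius buffer
degrades to a point-in-polygon test. Self-intersecting input rings are
repaired by noding at proper intersections and splitting into simple
sub-rings (even-odd semantics: a bow-tie becomes two triangles, both
counted). Unit assignment is point-in-polygon against the region layer with
pre-existing labels taking precedence and boundary points going to the first
containing feature in file order. Coordinates are assumed planar equal-area
in metres throughout; reprojection is upstream of the package.

## The synthetic world

`synth_config()` / `generate_world()` produce landscapes with the structure
the analysis assumes, plus ground truth: a rectangular grid of country ×
bioregion units (columns = countries, rows = bioregions) whose widths and
heights are drawn log-uniformly; per-unit protected strips covering a share
drawn from 7–38 %, the range reported for national networks; stratum species
pools of size $\mathrm{round}(c\,(A/100\ \mathrm{km^2})^z)$ with per-group
truths; pool overlap within units (`shared_pool_frac`, default 0.75 of the
smaller pool) and between consecutive units (`neighbor_share`, default 0.3),
so aggregation across units is non-trivial; a log-series abundance
distribution parameterized by Fisher's alpha (the series parameter is
$x = 1 - e^{-S/\alpha}$ for realized pool size $S$, capped at 0.9999);
priority flags on the rarest `priority_fraction` (default 4 %) of the global
pool, mirroring the observation that legally protected species are the ones
vegetation plots under-record; uniform plot placement within strata with
log-normal location uncertainties (median 10 m, capped at 10 km); and smooth
climate/elevation fields with observation noise for the matching stage. An
optional elevation offset for inside plots (`confound_elevation_m`) creates
the covariate confounding that matching tests need, and
`richness_boost_inside` scales expected plot richness inside the network to
emulate preferential sampling — a stand-in mechanism, not an estimate, since
no quantitative model of archive sampling bias is available.

**Scale.** The defaults are a deliberately scaled-down study: the
species–area exponents keep the reported inside/outside contrast
(z = 0.33 vs 0.22), while the richness constants are reduced to 150 vs 125 —
about one eighth of the continental values, preserving their ≈ 1.2 ratio —
and sampling densities (0.15 and 0.05 plots/km², counts bounded to
[30, 300] per stratum) were chosen so that per-stratum incidence coverage is
near-complete (≈ 0.95) and Chao2 operates in the regime where it tracks the
pool. At full continental pool sizes no tractable plot count reaches that
regime: coverage stalls near 0.5 and the fitted exponents are visibly biased
by effort, which is a property of undersampling, not of the method. The
default world therefore validates the *machinery* — partition arithmetic,
estimator concordance, the sign and separation of the z contrast, deviation
flags, matching balance — and absolute richness constants are reported as a
ratio, not as continental values. Passing tests on this world show the
pipeline recovers known structure under its own assumptions (uniform
within-stratum placement, independent plots, no spatial autocorrelation in
occupancy, climate fields that are smooth gradients); they do not show
robustness to the preferential, spatially clustered sampling of real
archives.

**Seeding.** Every run is driven by one integer seed: the generator derives
its landscape and community streams from it, and the pipeline hands
deterministic offsets of it to the two bootstrap calls, so module-level
results are reproducible independent of execution order. Identical
configuration and seed give byte-identical outputs, including written CSVs
and GeoJSON.

## Numerical choices and degenerate inputs

- Chao2 requires `m ≥ 2` plots and errors otherwise; empty strata error at
  incidence construction.
- Rarefaction uses `lchoose` differences; terms with $m - f_i < t$ are
  exactly 0.
- SAR fits initialize from log–log OLS (power parameters), $d = 0$
  (extended power, keeping the nesting seed) and the median area
  (Kobayashi), with a small multiplicative multi-start on failure; bounds
  keep `c` positive and `z` non-negative (strictly positive for Kobayashi).
- Asymptote fits initialize the asymptote just above the last curve value
  and the half-saturation from the curve; bounded Levenberg–Marquardt keeps
  parameters positive.
- The buffer-overlap threshold is a strict inequality, so a buffer exactly
  half inside is OUTSIDE; this knife-edge is measure-zero and excluded from
  translation-invariance guarantees.
- Plots missing a habitat class are retained (the exclusion rule names
  specific classes) but counted in the filter report.
- Units with an empty stratum, or inside/outside plot counts differing by
  more than a factor of 10, are excluded before any model sees them; the
  imbalance rule treats an undefined ratio as infinite.
- Occurrence de-duplication keeps the first row; priority implies native at
  load and violating rows are rejected.
- Zero pooled SD in balance statistics reports SMD 0 with a `degenerate`
  flag rather than NaN.

## Open design points, resolved

- **Observed vs estimated GLM response.** The binomial likelihood needs
  integer successes/trials, so the GLM consumes observed species counts;
  Chao2-based proportions are emitted alongside in the richness table for
  users who prefer the estimated response.
- **Overlap with multiple protected polygons.** The buffer's overlap is
  taken against the union of protected features (computed as a sum under
  the disjoint-interiors assumption), not against any single polygon.
- **Aggregation levels** (unit, country, bioregion, network-wide) are
  computed independently from the occurrence data rather than by summing
  unit results, because species sets overlap across units.
- **Priority reference list.** Coverage of the priority flora is measured
  against an external reference list supplied by the user (ground truth in
  synthetic runs); species in the data but absent from the reference are a
  reporting gap of the reference, and the partition keeps them in the
  observed sets.

## Problem sizes used by the test suite

The suite validates each stage at sizes chosen for tight oracles rather than
realism: enumeration oracles at `m ≤ 6` plots, matcher-vs-brute-force at
≤ 10 plots, Monte-Carlo recovery and contrast studies at 30 units per group
with 5 % multiplicative noise over 100 seeds (bootstrap `B = 199` inside
simulations, 1000 in production), bootstrap coverage at 60 replicates of
`B = 99`, and full-pipeline direction checks on 12-unit worlds over 10
seeds. The default 24-unit world (≈ 4000–6000 plots, ≈ 10⁵ occurrences)
runs end-to-end in well under a minute.

## Known limitations

- Protected features with overlapping interiors would double-count buffer
  overlap; dissolve such layers upstream.
- The region layer used for unit areas is clipped per feature against
  protected features assuming convex region outer rings (true for the
  synthetic rectangles); highly concave real-world regions would need a
  general polygon-intersection routine.
- No spatial autocorrelation, detection covariates, or abundance
  information: everything is incidence-based.
- Chao2 analytic variances, coverage-standardized comparisons and
  abundance-based estimators are out of scope.
- Greedy matching is order-dependent by construction; optimal matching is
  not implemented.
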