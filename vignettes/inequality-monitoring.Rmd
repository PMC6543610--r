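---
title: "Measuring health inequality when the socio-economic composition shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality when the socio-economic composition shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqshift)
```

## The measurement problem

Public-health surveillance routinely summarises the social gradient in an
outcome — here, premature mortality stratified by educational level (EL) —
with a small set of indices. `ineqshift` implements the three most common
ones for ordered groups, plus the machinery needed to study a subtle
pitfall: what these indices do when the *composition* of the population
(the share of people in each educational level) changes, even while the
level-specific rates stay exactly the same.

The inputs are minimal: an ordered vector of population shares
\(p_1, \dots, p_n\) (lowest level first) and an aligned vector of event
rates \(y_1, \dots, y_n\) per 100,000 person-years. Rates are never
rescaled internally, so slopes and differences stay in the input units.

## The indices

**Ridits.** Each group is placed on a relative-rank axis by the midpoint of
its cumulative share range: \(x_i = (c_{i-1} + c_i)/2\) with
\(c_i = \sum_{j \le i} p_j\). The axis runs from 0 (bottom of the social
hierarchy) to 1 (top). The share-weighted mean ridit is exactly 0.5 for any
valid distribution — an algebraic identity the test suite asserts to
`1e-12`, and a useful canary for share-validation bugs.

**SII.** The slope index of inequality is the slope of the weighted
least-squares regression of rates on ridits with weights equal to the
shares:
\[
SII = \frac{\sum_i w_i (y_i - \bar y_w)(x_i - \bar x_w)}
           {\sum_i w_i (x_i - \bar x_w)^2}.
\]
It is computed from this closed form; a test verifies equality with a
generic WLS solver (`lm(..., weights = )`) to `1e-9` relative on randomised
instances. The SII is negative for adverse gradients (higher mortality at
the bottom) and scales with the rates: adding a constant to every rate
leaves it unchanged, multiplying by \(k\) multiplies it by \(k\).

**RII.** The relative index (Kunst–Mackenbach ratio) extrapolates the same
line to the ends of the rank axis and reports
\(RII = b_0 / (b_0 + b_1)\), the ratio of the fitted rate at the very
bottom to the fitted rate at the very top. For steep gradients the fitted
top rate can reach zero or below; that is an extrapolation failure of the
linear model, and `rii()` reports it as an error rather than clamping —
`inequality_indices()` records `NA` for the bundled value.

**PAF.** The population attributable fraction compares the share-weighted
mean rate with the rate of the best-off (reference) level:
\(PAF = (\bar y_w - y_{ref}) / \bar y_w\). The reference defaults to the
last level but is an explicit argument, so the indices generalise beyond
four levels without changing default behaviour.

**Pairwise differentials.** Rate differences and rate ratios versus the
reference level complete the picture; unlike the three summary indices they
do not depend on the shares at all.

All computation is carried out in full precision. Display rounding (SII to
integers, RII and PAF to two decimals) lives only in `format()`,
`indices_json()` and the report writers.

```{r}
shares <- c(0.40, 0.25, 0.25, 0.10)
rates  <- c(750, 550, 450, 300)
inequality_indices(shares, rates)
```

## The composition-shift simulation

`generate_eld_grid()` enumerates every four-level distribution whose first
three shares run over a 5-percentage-point lattice between 5% and 50%, with
the top share the complement to 100% and the same bounds applied — 633
admissible combinations under the defaults. Shares are handled as exact
integer percents during enumeration and family extraction, which removes
floating-point set-membership hazards; they become fractions only at
evaluation time. The enumeration is cross-checked against an independent
brute-force triple loop in the tests.

`evaluate_grid()` attaches the SII, RII and PAF to every combination at a
fixed rate schedule — by default the Belgian male premature-mortality rates
from the 2001 census (733.8, 552.1, 450.1, 313.9 per 100,000 person-years,
`belgium_rates_2001()`). `extract_family()` then pulls out the curve
families of interest: hold two of the first three shares fixed and follow
an index as the top share \(p_4\) grows, the remaining share varying as the
complement.

Two regularities emerge, and the test suite asserts both:

- along every family with \(p_1\) fixed, the RII strictly increases and the
  PAF strictly decreases as \(p_4\) grows; |SII| also increases strictly in
  every such family with \(p_1 \ge 15\%\) — which covers all the curves a
  surveillance report would plot. At extreme low \(p_1\) (5–10%) with
  \(p_2\) varying, the |SII| curve is unimodal: it rises, peaks, and
  declines late. Nine of the lattice's families behave this way; the
  package characterises them as unimodal rather than asserting a false
  universal monotonicity.
- along the families where \(p_1\) shrinks as the complement of \(p_4\),
  both |SII| and RII follow reversed-U curves; with \(p_2 = p_3 = 25\%\)
  fixed, the RII peaks at \(p_4 = 35\%\) (i.e. where
  \(p_2 + p_3 + p_4 = 85\%\)), much later than the |SII| peak at
  \(p_4 = 20\%\). Extremum ties are broken toward the smaller \(p_4\),
  a documented convention.

The upshot for monitoring: an upward shift of the educational distribution
— unambiguously good news — is frequently translated by the RII, and
sometimes by the SII, into an apparent *worsening* of inequality, while
the PAF consistently moves in the intuitive direction.

```{r}
g <- evaluate_grid(generate_eld_grid(grid_spec()), belgium_rates_2001())
fam <- extract_family(g, "fixed_p2p3", c(25, 25), index = "rii")
find_maximum(fam)
```

## Scenario decomposition

`decompose_change()` splits the change of each index between two scenarios
into a mortality-differential component (new rates, old distribution) and a
composition-shift component (new distribution, new rates), both as percent
of the baseline index, so they add exactly to the total. The decomposition
is deliberately path-dependent — rates move first, then the distribution —
because that is how the two formulas are defined; offering the reverse path
would produce different components and a false air of symmetry.

Components are computed from full-precision index values. This choice is
not innocent: percent changes recomputed from display-rounded values can
differ by a point (e.g. a PAF change of −19.7% prints as −20% from full
precision but −19% from two-decimal values). Full precision preserves
additivity and reproducibility, which we weight above matching every
rounded cell of a printed table.

`reference_scenarios()` bundles the six study scenarios: three rate
schedules (baseline; lower rates with smaller differentials; higher rates
with larger differentials) crossed with a left-skewed distribution (ELD1,
\(p_1 = 40\%\), \(p_4 = 10\%\)) and an upward-shifted one (ELD2,
\(p_1 = 20\%\), \(p_4 = 30\%\)).

```{r}
s <- reference_scenarios()
decompose_change(s$A, s$C, s$D)
```

The headline paradox is visible above: moving from scenario A to D improves
every level-specific rate *and* the educational distribution, yet the RII
rises 6% — a −15% rates component overwhelmed by a +21% composition
component. Known discrepancy: for the scenarios with the third rate
schedule (and one RII cell of the second), our recomputation of the
composite indices from the stated inputs differs by 1–4% from some
published values of the same quantities; those cells are internally
inconsistent with their own inputs and are not used as test anchors.

## Synthetic populations and confidence intervals

The stochastic layer exists so that interval estimation can be exercised
without any external data. `expected_counts()` builds the deterministic
population implied by shares, rates and a person-years total; indices
computed on it reproduce the closed forms exactly (a parameter-recovery
test). `sample_population()` replaces the expected death counts with
Poisson draws — the standard model for rare-event counts over person-years
at risk; overdispersion, age structure and competing risks are deliberately
out of scope. Sampling is seed-explicit and restores the ambient RNG state.

`indices_with_ci()` provides the interval method, chosen and documented
here because the underlying formulas are a free design point: the SII
interval uses the analytic standard error of the WLS slope with
Poisson-rate variances (\(\mathrm{var}(y_i) = y_i \times 10^5 / py_i\) on
the per-100,000 scale), and the RII interval is a delta-method interval on
\(\log RII\) using the propagated variances and covariance of the fitted
intercept and slope. The strategy sits behind a `ci_method` argument so an
alternative (e.g. a bootstrap) can be swapped in without touching callers.
A 1,000-replicate simulation in the test suite checks ~95% empirical
coverage for the SII and RII at 2 million person-years, within binomial
Monte-Carlo error.

`filter_by_significance()` reproduces, in mechanism, the study's filter
that kept only distributions whose SII interval excludes 0 and RII interval
excludes 1. The person-years behind the original filtered count were never
disclosed, so the filter takes them as an explicit argument and no attempt
is made to reproduce that count.

## What the synthetic data does and does not show

The generator emulates exactly the study conditions: four ordered groups,
fixed rate schedules, share lattices, Poisson event counts. It does not
emulate real vital-statistics complications — age standardisation,
misclassification of education, migration between censuses, or extra-Poisson
variation. Green tests therefore demonstrate correctness of the estimators
and the simulation machinery under the stated model, not robustness of the
indices on real registry data.

## Numerical choices and problem sizes

Tolerances: share sum-to-one at `1e-9`; algebraic identities asserted at
`1e-12`; oracle equivalences at `1e-9` relative. Degenerate inputs:
single-level distributions are rejected; two-level ones are allowed (the
slope reduces to the weighted two-point slope); a zero mean rate makes the
PAF undefined (error); a non-positive fitted top rate makes the RII
undefined (error, or `NA` in the bundled result). The test suite runs the
full 633-point grid, 300-replicate unbiasedness and 1,000-replicate
coverage simulations — sizes chosen so the whole suite completes in well
under a minute while keeping Monte-Carlo error small relative to the
asserted tolerances.
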