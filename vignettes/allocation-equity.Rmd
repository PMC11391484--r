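---
title: "Measuring the level and equity of health workforce allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the level and equity of health workforce allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrequity)
```

## The problem

A health system that staffs its disease-control agencies strictly in
proportion to population looks perfectly fair per resident — and can still
leave vast, sparsely populated territories with almost no geographically
reachable staff. `hrequity` operationalises both views of fairness for
long-format provincial panels: one row per (province, year, staffing
category) with headcount, resident population in thousands, and land area
in square kilometres. The motivating application is China's provincial CDC
workforce over 2016–2020 (31 provincial units grouped into Eastern, Central
and Western economic regions of 11, 8 and 12 provinces), but every function
takes an arbitrary panel and region scheme.

## The measures

**Allocation level: the health resource density index.** For province $i$,

$$\mathrm{HRDI}_i
  = \sqrt{\frac{HR_i}{A_i}\cdot\frac{HR_i}{P_i}}
  = \frac{HR_i}{\sqrt{A_i P_i}},$$

the geometric mean of the geographic density (staff per km²) and the
demographic density (staff per thousand residents). It is linear in the
headcount, lies between the two densities, and penalises a province that is
well staffed on one axis but not the other. Units follow the published
convention — population in thousands, area in km² — so published density
columns can be fed directly into `hrdi_from_densities()`. Regional
aggregates (`regional_hrdi()`) apply the index to *pooled* regional sums of
staff, population and area rather than averaging provincial indices; the
pooled form is the index of the region treated as one unit, is invariant to
how a region is partitioned into identical provinces, and is the natural
reading of the index's definition.

**Equity per person or per km²: Lorenz curve and Gini coefficient.**
Provinces are sorted ascending by staff per unit weight (population or
area); cumulative weight shares $X_i$ and staff shares $Y_i$ trace the
Lorenz curve from $(0,0)$ to $(1,1)$, and

$$G = 1 - \sum_{i=0}^{n-1} (X_{i+1}-X_i)(Y_{i+1}+Y_i)$$

is twice the area between the curve and the equality diagonal, by the
trapezoid rule. Two numerical choices matter here. First, the sum *must*
include the segment leaving the origin — dropping it (as a naive reading of
the index range $1..n-1$ would) makes even perfect equality come out
positive, contradicting $G \in [0,1)$. Second, provinces with identical
staff-to-weight ratios are merged into a single segment before cumulating;
this leaves the trapezoid sum unchanged but makes the point set canonical.
The conventional equity bands are applied by `classify_gini()`: below 0.3
"best average state", 0.3–0.4 "normal", 0.4 (the warning line) through 0.6
"warning", above 0.6 "highly unequal"; the boundary values 0.3, 0.4 and 0.6
fall to the band whose description quotes them ("below 0.3", "above 0.4"),
so 0.4 and 0.6 are both "warning".

**Decomposable equity: the Theil index.** With weight shares $\xi_i$
(population or area) and staff shares $\eta_i$,

$$T = \sum_i \xi_i \ln\!\frac{\xi_i}{\eta_i},
\qquad
T = \underbrace{\sum_j \xi_j \ln\!\frac{\xi_j}{\eta_j}}_{T_{inter}}
  + \underbrace{\sum_j \xi_j T_j}_{T_{intra}},$$

where $j$ indexes regions, $T_j$ is the Theil index within region $j$ on
group-renormalised shares, and $\omega_{intra} = T_{intra}/T$,
$\omega_{inter} = T_{inter}/T$ are the contribution rates. The natural
logarithm is used throughout: it is what makes the decomposition an exact
algebraic identity (verified to $10^{-10}$ relative tolerance on every
decomposition, and mirrored by the published component tables, whose rows
sum to the printed totals within one print-rounding unit). Note the index
is *not* bounded by 1 — geographic weightings of strongly
population-tracking allocations routinely push it towards 0.8 and beyond —
so no clamping is applied, whatever a nominal "0 to 1 range" convention
suggests.

**Zero-headcount provinces.** A province with positive weight and zero
staff makes $T$ infinite. The package refuses to smooth this away with an
epsilon: `theil()`/`theil_decompose()` raise an explicit error, and
`drop_zero = TRUE` removes such provinces with a warning and renormalised
shares. Silent smoothing would make reported indices depend on an arbitrary
constant.

**Ranking.** `density_table()` ranks provinces by descending HRDI; exact
ties (which occur in rounded published tables, not in raw headcounts) are
broken by ascending province name, so ranks are always a permutation of
$1..n$ and stable across runs.

## Published reference tables

Three published summary tables are shipped as fixtures: the 2016–2020
national/regional headcount grid with chain growth rates
(`cdc_staff_totals()`), the 2020 per-province density/HRDI/rank table for
all four staffing categories (`cdc_hrdi_2020()`), and the Theil component
grid (`cdc_theil_components()`). They serve as worked inputs: growth rates
recompute from the levels, HRDI cells recompute from the density columns,
and the Theil components satisfy the additivity identity.

One caveat is inherited from print precision. The density columns are
printed at 4 decimal places, so an HRDI recomputed from them carries a
propagated rounding error of up to
$\tfrac12(5\cdot10^{-5}/p + 5\cdot10^{-5}/q)\cdot\mathrm{HRDI}$; for
coarsely printed cells (e.g. an area density of 0.0001) this reaches a few
units in the fourth decimal. The test suite therefore checks every cell
against that propagated bound, and exact 4-dp agreement only for
well-conditioned cells. (The published area-density column header nominally
reads "per 10³ km²", but the printed values are only consistent with staff
per km² — e.g. Shanghai's 0.3557 for ≈2,200 healthcare staff on 6,340 km² —
so the per-km² reading is used.)

The published *national* Gini series, the regional HRDI levels and the
absolute Theil components all derive from province-level headcounts that
are not part of the published record; they are treated as context, not as
reproduction targets. What is enforced is everything structural: additivity,
contribution-rate identities (the within-region shares recomputed from the
printed components reproduce the printed contribution ranges), and the
qualitative ordering that geographic inequality exceeds demographic
inequality.

## The synthetic panel generator

`generator_config()` + `generate_panel()` produce panels whose equity
properties are controlled, so every statistic is testable without external
data. Populations and areas are log-normal across provinces and constant
over years; staffing follows a noisy power law,

$$HR_i = \rho \, P_i^{\gamma} e^{\varepsilon_i},
\qquad \varepsilon_i \sim N(0, \sigma_e^2),$$

drawn independently per year and category, rounded to whole persons by
default (disable `round_personnel` when a test needs *exactly* proportional
allocation).

Defaults, chosen once to emulate the motivating panel's scale: 31 provinces
in an 11/8/12 split; `pop_logmean = log(40000)` thousand and `pop_logsd =
0.8` (provincial populations a few million to ~120 million);
`area_logmean = log(160000)` km² and `area_logsd = 1.1` (6×10³ to 1.7×10⁶
km²); `rho = 0.14` staff per thousand residents, matching a national
workforce near 190,000; `gamma = 1` (proportional-to-population policy) and
`sigma_e = 0.3` (moderate allocation noise). Under these defaults the
generated population-weighted Gini lands near 0.15 and the area-weighted
Gini near 0.6 — the same regime as the published series — which is a
consequence of staffing that tracks population while ignoring area, not of
any fitting to the published numbers.

What the generator deliberately does **not** emulate: serial correlation of
allocation noise across years (published series are smooth; synthetic ones
fluctuate more year-to-year), any population–area correlation, category
size differences, and within-province heterogeneity. Tests passing on
synthetic panels therefore validate the *estimators* and their identities,
not any claim about real yearbook data.

## Verification strategy and problem sizes

The statistics are cross-checked against independent brute-force oracles:
the trapezoid Gini against the weighted pairwise mean-difference form
$G = \sum_{ij} w_i w_j |r_i - r_j| / (2 W^2 \bar r)$ on 500 random
instances with $n \le 8$ (agreement to $10^{-12}$), and the decomposed
Theil total against the direct entropy sum on the same battery. Degenerate
cases are pinned analytically: proportional allocation gives exactly zero
under both measures, and full concentration in one of $n$ equally weighted
units gives $G = (n-1)/n$. The noise-sensitivity check runs 50 replicates
of a 31-province, single-year panel at $\sigma_e \in \{0.1, 0.5, 1.0\}$ and
requires the mean Gini and Theil to rise strictly across the grid; these
sizes keep the whole battery to a few seconds while leaving Monte-Carlo
error far below the effect size.

## Limitations

- Provinces are the atomic unit: within-province disparities are invisible,
  and the within-region Theil component conflates them with between-province
  differences inside a region.
- The HRDI is a level index with no notion of staff quality or skill mix.
- No uncertainty quantification is attached to any index; the panel is
  treated as a census, not a sample.
- Chain growth requires consecutive years and refuses gaps rather than
  interpolating.
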