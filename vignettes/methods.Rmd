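---
title: "Methods: chance-constrained stochastic DEA for pollution-day attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chance-constrained stochastic DEA for pollution-day attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`hazedea` studies how meteorological conditions and human activities relate
to the number of PM2.5 pollution days in a panel of cities. The unit of
analysis is the city-year. Daily inputs are reduced to annual day counts of
five threshold events ("disaster points") plus the pollution-day count, and
combined with nine annual socioeconomic indicators into a stochastic DEA
block where every cell is a (mean, standard deviation) pair.

### Threshold definitions

All thresholds are literal and configurable:

* wind speed **strictly below** 1.5 m/s (the boundary excluded);
* "no precipitation" means a measured daily total of exactly 0 mm by
  default. Whether trace amounts should count as dry is genuinely ambiguous
  in this setting, so the wet threshold is an explicit argument
  (`wet_threshold = 0.1` gives the "no effective precipitation" reading);
* temperature change **strictly positive**, pressure change **strictly
  negative**, both as today-minus-yesterday differences. The first observed
  day of a year has no predecessor and contributes nothing, and years are
  never chained across their boundary, so a January 1st never differences
  against December 31st of the previous year;
* relative humidity in the **closed** band [60, 90] % on dry days;
* a pollution day has 24-h mean PM2.5 **strictly above** 75 µg/m³. A 24-h
  PM2.5 mean above 75 µg/m³ already places the PM2.5 sub-index beyond the
  "good" band, so the concentration rule is the default; when a reported
  AQI category column is available, `require_aqi = TRUE` additionally
  demands "lightly polluted or worse", which only bites when other
  pollutants drive the reported category.

Missing days are skipped, never imputed; `n_observed_days` records actual
coverage and a warning fires below 90 % calendar coverage. One pre-aggregated
series per city is assumed — combining multiple stations into a city series
is upstream of this package.

## The stochastic frontier model

For city *o* at risk level $\alpha$, with input means $\bar x_{ij}$, output
means $\bar y_{rj}$ and standard deviations $\sigma^I_{ij}, \sigma^O_{rj}$:

$$\max_{\lambda \ge 0,\ \sum_j \lambda_j = 1} \theta$$

subject to, for every input $i$ and output $r$,

$$\sum_j \lambda_j \bar x_{ij} - \Phi^{-1}(\alpha)
 \sqrt{\textstyle\sum_{j \ne o} \lambda_j^2 (\sigma^I_{ij})^2
       + (\lambda_o - 1)^2 (\sigma^I_{io})^2} \le \bar x_{io},$$

$$\sum_j \lambda_j \bar y_{rj} + \Phi^{-1}(\alpha)
 \sqrt{\textstyle\sum_{j \ne o} \lambda_j^2 (\sigma^O_{rj})^2
       + (\lambda_o - \theta)^2 (\sigma^O_{ro})^2} \ge \theta\, \bar y_{ro}.$$

The stochastic efficiency is $1/\theta$. The variance terms sum squared
per-DMU contributions — a cross-DMU independence assumption that is part of
the model definition and is implemented exactly as written, with no
covariance terms. The model is output-oriented under variable returns to
scale (the convexity constraint $\sum\lambda = 1$); no input-oriented or
constant-returns variant is provided.

Three structural facts drive both the solver and the tests:

1. $(\lambda = e_o,\ \theta = 1)$ is feasible for every $\alpha$, so
   $\theta^* \ge 1$ and efficiency lies in $(0, 1]$.
2. $\Phi^{-1}(0.5) = 0$, or an all-zero SD panel, removes every buffer: the
   model *is* the deterministic output-oriented BCC linear program.
3. The feasible sets are nested as $\Phi^{-1}(\alpha)$ grows, so
   $\theta^*(\alpha)$ is non-decreasing: efficiency never rises with risk.

## Where the cell standard deviations come from

The model needs an SD for every cell, yet each year is evaluated separately
and the data sources are annual. This gap admits no single obviously-right
answer, so three strategies are implemented and selected by configuration:

* **`monthly`** (default): disaster counters are tallied per month within
  the year; the annual mean is $12\times$ the monthly mean (equivalently the
  annual total) and the annual SD is $\sqrt{12}\times$ the monthly SD,
  treating months as independent. Yearbook indicators have no sub-annual
  signal, so their SD defaults to a coefficient of variation of 5 % of the
  mean (`activity_cv`), a conventional reporting-uncertainty scale.
* **`across-years`**: each cell summarized over a multi-year window —
  statistically cleanest, but it blurs the per-year evaluation design.
* **`zero-sd`**: deterministic DEA, useful as a reference and for testing.

Variables enter untransformed. Radial DEA is invariant to per-column
rescaling and the solver normalizes internally, but units are recorded in
the panel metadata and never silently changed.

## Solving the program

* **LP reduction.** Whenever $\Phi^{-1}(\alpha) = 0$ or all SDs vanish, the
  program is the BCC LP, solved with `boot::simplex` over variables
  $(\theta, \lambda)$. Degenerate DEA polytopes occasionally break the
  tableau pivoting; the solver retries with a deterministic, escalating
  right-hand-side perturbation ($10^{-8}$ upward) and always recomputes
  $\theta$ exactly from the returned $\lambda$, so a perturbed retry cannot
  inflate the reported value.
* **Exact $\theta$ given $\lambda$.** With $\lambda$ fixed, each output
  constraint defines the largest feasible $\theta$ through a quadratic
  equation (squaring the buffer); the right root with the correct branch
  gives $\theta^*(\lambda)$ in closed form. This is used to polish every
  candidate and to warm-start.
* **Nonlinear case.** An augmented-Lagrangian loop over `optim(method =
  "L-BFGS-B")` with analytic gradients handles the chance constraints, with
  a $10^{-18}$ smoothing term inside the square roots (the gradient is
  bounded; the final certificate uses the exact, unsmoothed constraints).
  Every candidate is then projected back to the simplex, its small
  coordinates cleared of numerical dust, re-checked against the **exact**
  constraints at a $10^{-9}$ relative tolerance, and its $\theta$ recomputed
  in closed form. Only certified-feasible candidates can be returned;
  $\lambda = e_o$ with $\theta = \theta^*(e_o)$ is always among them, so the
  solver cannot fail.
* **Global vs local.** For $\alpha < 0.5$ the feasible region is convex and
  a local solve from the always-feasible $e_o$ (plus the BCC vertex as a
  second start) is globally valid; an installed conic solver would add
  nothing but a dependency. For $\alpha > 0.5$ the program is nonconvex:
  the solver multistarts from $e_o$, the BCC solution, any warm starts, and
  `n_random_starts` random simplex points (default 6, drawn from a seed
  derived deterministically from the call), reporting the best certified
  candidate as `multistart-best`. Six random starts were chosen as the
  point where additional starts stopped changing results on randomly
  generated panels once warm starts are in play; the count is a solver
  option, not a model constant.
* **Monotone sweeps by construction.** `efficiency_profile()` solves the
  grid in ascending $\alpha$ and feeds each solution to the next level as a
  warm start. Because a feasible point stays feasible when $\alpha$ grows
  and its exact $\theta^*(\lambda)$ cannot decrease, the reported profile is
  non-decreasing in $\theta$ regardless of how well the local solver does —
  the mechanism behind "efficiency falls as risk rises" is preserved
  numerically, not just on average.
* **Tie-breaking.** Among candidates within $10^{-9}$ of the best $\theta$,
  the smallest $\|\lambda\|_2$ wins, for reproducibility.
* **Tolerances.** Constraint certification $10^{-7}$ (relative to the
  evaluated city's own levels — constraints are checked in the solver's
  column-normalized scale, which is the only scale on which a single
  tolerance is meaningful across variables whose raw magnitudes span five
  orders), $\sum\lambda = 1$ to $10^{-8}$, efficiency comparisons $10^{-6}$,
  $\theta$ capped in $[10^{-6}, 10^{6}]$, and "efficiency equals 1" read at
  $10^{-4}$ (scores are conventionally reported to four decimals).

An independent brute-force oracle (`ccdea_grid_oracle`) enumerates the
$\lambda$-simplex at step 0.01 and maximizes $\theta$ per grid point by
bisection; the test suite holds the solver to it on small instances.

## Attribution by deletion

A variable (or group) is influential for a city at a risk level if removing
its column and re-solving changes the stochastic efficiency by more than
`change_tol = 1e-4`. Deletion is constraint removal, so the feasible set can
only grow and efficiency can only stay or fall; each deleted solve is
warm-started from the baseline solution, which makes the recorded drop
non-negative by construction rather than by hope. Scans iterate the six
fixed groups (MF{WS, NPD, PTC, NPC, RH}, ID{GOVIE}, SP{UR, PD, BCA},
T{CCO, NPTVO}, EU{EC, TCC}, EP{GCRBA}) or all fourteen singles; deleting the
output is disallowed. Regional summaries aggregate flags over the built-in
Southern/Central/Northern (5+3+5) and coastal/inland (3+10) partitions of
the 13 Jiangsu cities, both overridable.

The procedure is deliberately flag-based — "changed" or "not" — with no
marginal-effect magnitudes and no causal reading; `delta` is reported so a
user can apply a stricter cut.

## Grey relational screening

The screening step uses Deng's formulation: after normalization, pointwise
coefficients $\xi(k) = (\Delta_{\min} + \rho\,\Delta_{\max}) /
(\Delta(k) + \rho\,\Delta_{\max})$ with $\Delta(k)$ the absolute difference
between the normalized series, $\rho = 0.5$ by default, and the grade is
their mean. The method is named but not specified in detail in this
literature, so the formulation is explicit and switchable: initial-value
normalization (default), mean-value, or raw. Grades can be computed across
cities within a year or across years within a city — both axes are
meaningful and the table function simply follows how the panel is filtered.

## The synthetic study

The generators define the conditions under which the method is exercised:

* daily weather: AR(1) temperature (mean 15 °C, persistence 0.8, innovation
  SD 2 °C) and pressure (1015 hPa, 0.7, 3 hPa), Weibull(2, 3 m/s) wind,
  Bernoulli(0.45)-gamma(0.7, scale 8 mm) precipitation, humidity normal
  around 85 % (wet days) / 65 % (dry days) with SD 10, clamped to [0, 100].
  These place the five counters in the 60–240 day range a humid subtropical
  station plausibly shows — documentation values, not claims about any real
  place;
* PM2.5: the exceedance probability is logistic in the number of active
  disaster conditions (`plogis(qlogis(base_rate) + Σ coupling·indicator)`),
  planting the premise that pollution days concentrate on disaster days;
  concentrations are drawn above/below the 75 µg/m³ threshold accordingly;
* activity tables: lognormal-scale base levels per city with smooth yearly
  growth, so multi-year windows have usable dispersion;
* DEA instances: either fully random (mean scales log-uniform across
  columns, per-cell coefficients of variation in [0.02, 0.15]) or *planted*:
  one discriminating input with a strictly concave frontier in the
  (input, output) plane and all other inputs constant across cities.
  Constant columns bind identically under $\sum\lambda = 1$ and carry no
  frontier information, which makes the planted instance analytically
  checkable: the planted city is efficient only through the planted
  variable, so that deletion must flag it and no other deletion may move
  anyone.

Every generator is a pure function of its seed; sub-series use a documented
splitting rule (`(seed · 48271 + k) mod (2³¹−1)`), so each component is
independently reproducible and generation never disturbs the caller's RNG.

What the generators deliberately do **not** emulate: spatial correlation
between cities, seasonality and serial correlation of pollution episodes
beyond day-level coupling, trace-precipitation reporting conventions,
multi-station aggregation, or measurement error in yearbook indicators
beyond the CV assumption. Passing tests therefore demonstrate the
correctness and internal consistency of the method under controlled
conditions — not that any specific real-world dataset would yield the same
factor rankings.

## Problem sizes

The test suite profiles 50 random panels at the study scale (13 DMUs × 14
inputs across the nine-level risk grid), checks the solver against the grid
oracle on 20 instances with up to 3 DMUs, and runs 50 planted-influencer
scans of 6 DMUs × 4 inputs at two risk levels; the analysis drivers run one
simulated 13-city year end to end with both scan modes at
$\alpha \in \{0.8, 0.9, 0.95\}$. These sizes keep a complete run in the
minutes range on a single core while exercising every code path at the
study's own dimensionality.

## Known limitations

* The $\alpha > 0.5$ program is nonconvex; `multistart-best` is a certified
  feasible value and an upper bound is not computed. Warm-started sweeps
  make the reported profiles monotone, but an individual solve can in
  principle undershoot the global optimum.
* The monthly SD strategy treats months as independent and exchangeable;
  strong seasonality inflates those SDs.
* The grid oracle is exponential in the number of DMUs and refuses more
  than four.
* Flag-based attribution inherits the model's tolerance conventions: a
  factor whose removal moves efficiency by less than `change_tol` is
  invisible, whatever its real-world relevance.
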