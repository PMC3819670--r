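---
title: "Cluster LQAS design: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster LQAS design: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clqas)
```

## The classification problem

LQAS is a classification design, not an estimation design. An area is
sampled and labelled *acceptable* or *low quality*; no prevalence
estimate is reported. Four parameters, fixed by the programme before any
data are seen, define the problem:

* `p_u` — the defect prevalence at or above which an area must be
  flagged (upper threshold);
* `alpha_max` — the tolerated probability of *failing* to flag an area
  whose true prevalence is `p_u`;
* `p_l` — the prevalence at or below which an area must be left alone
  (lower threshold);
* `beta_max` — the tolerated probability of flagging an area whose true
  prevalence is `p_l`.

Between the thresholds lies the grey area: classification probabilities
there are deliberately unconstrained, and near the middle of the grey
area they approach a coin flip. Choosing thresholds far enough apart to
be operationally meaningful is the programme's responsibility; the
package only enforces `p_l < p_u`.

A simple random sample of size `n` with decision rule `d` ("flag when
`d` or more defects are seen") satisfies the constraints when

$$P(X < d \mid n, p_u) \le \alpha_{\max}, \qquad
  P(X \ge d \mid n, p_l) \le \beta_{\max},$$

with `X` binomial. `binomial_lqas_design()` scans `n = 1, 2, ...` and
returns the first `n` admitting any valid `d`; this `n_min` (20 for the
worked data-quality example with `p_l = 0.05`, `p_u = 0.25`, both risks
capped at 0.10) is also the natural upper end of the cluster-count range
for the clustered design, since at `m = n_min` clusters one unit per
cluster is a simple random sample of the required size.

## The clustered model

When `m` clusters of `k` units are sampled instead, outcomes within a
cluster are correlated. The package models the per-cluster defect count
as beta-binomial: cluster `i` draws a latent prevalence
$\pi_i \sim \mathrm{Beta}(a, b)$ and then a count
$X_i \mid \pi_i \sim \mathrm{Binomial}(k, \pi_i)$, with shapes

$$a = p\,\frac{1-\rho}{\rho}, \qquad b = (1-p)\,\frac{1-\rho}{\rho}.$$

This is the unique beta parameterization with mean `p` and pairwise
within-cluster correlation exactly `rho` (`rho = 1 / (a + b + 1)`), so the
single-cluster count variance is `k p (1-p) (1 + (k-1) rho)` — the
familiar design-effect inflation, which the test suite asserts in closed
form. Two conventions follow:

* `rho = 0` is handled as the exact binomial, and `p` of 0 or 1 as exact
  point masses, rather than as limits of the shape formulas (which would
  divide by zero);
* `rho` is restricted to `[0, 1)`: the model covers overdispersion only,
  which is the regime cluster sampling produces.

Clusters are independent and identically distributed, so the pooled
count is the `m`-fold convolution of the single-cluster pmf.
`cluster_total_pmf()` computes it by direct convolution in probability
space; supports here are at most a few hundred points, where direct
convolution is accurate to about 1e-14 and avoids the small negative
masses FFT-based convolution can produce. The single-cluster pmf itself
is evaluated in log space (`lchoose` + `lbeta`), stable far beyond
`k = 500`. A support cap (default `m * k <= 10,000`) guards against
accidentally enormous convolutions and is configurable.

## Design search

`classification_risks()` evaluates a candidate system `{m, k, d}`
exactly: `alpha = P(total <= d - 1 | p_u, rho)` and
`beta = P(total >= d | p_l, rho)`. Risks are compared against their
bounds *unrounded*; the three-decimal figures in printed tables are
presentation only.

`clqas_min_k()` fixes `m` and scans `k = 1, 2, ...` until some `d`
satisfies both constraints, so the returned `k` carries a minimality
certificate by construction — every smaller `k` was checked and failed
for every `d`. The scan is capped (default `k_max = 500`), and
infeasibility is always reported *relative to the cap*: the beta-binomial
total does not converge to a constraint-satisfying distribution as
`k` grows when `m` is too small, but the search never claims absolute
infeasibility.

A heuristic for "too small" exists: as `k` → ∞ the standardized pooled
count behaves like a binomial on the `m` cluster prevalences, and at
least `rho * n_min` clusters are needed. `feasibility_min_clusters()`
returns `ceiling(rho * n_min)` — with a 1e-9 downward guard, because
products such as `0.1 * 20` exceed their exact value in binary floating
point and would otherwise round a feasible cluster count away. The bound
is advisory; feasibility is always decided by the direct search.

**Decision-rule tie-break.** The admissible decision rules at the
minimal `k` form a contiguous range, because alpha is nondecreasing and
beta nonincreasing in `d`. When the range contains more than one value,
the package reports the `d` minimizing `max(alpha, beta)`, breaking
exact ties toward the smaller `d`. The minimax rule is the natural
symmetric choice — neither risk is privileged once both bounds hold —
and it balances the two risks at the cells where the range is wide
(e.g. at `m = 8`, an admissible smaller `d` leaves beta a hair under its
bound while minimax splits the slack). `d_rule = "smallest"` switches to
the smallest admissible `d`, which always minimizes the alpha risk.

`design_table()` assembles one row per `(rho, m)` over a grid, with
costs appended per scenario; `oc_curve()` returns the full operating
characteristic `P(flag | p)`, a nondecreasing bridge from `beta` at
`p_l` to `1 - alpha` at `p_u`.

## Costs

The cost model is the linear two-part tariff
`C_total = C_m * m + C_k * m * k`: reaching a cluster has a fixed cost
(travel, supervision) and each sampled unit a marginal one. Currency is
unitless. `cheapest_design()` returns *all* cost-minimizing feasible
rows rather than breaking ties arbitrarily — ties are real (two designs
tie at 3000 in the worked example) and the choice between them involves
considerations outside the cost model, such as preferring more clusters
when the ICC is uncertain. No travel-distance or time modelling is
attempted.

## Simulation engine

`simulate_counts()` draws from exactly the model the design assumes:
latent beta prevalences per cluster, conditional binomial counts,
independent clusters. The engine therefore emulates equal-sized,
independently sampled clusters with a correctly specified beta mixing
distribution — and nothing else. Real surveys add features the generator
deliberately omits: unequal cluster sizes, sampling without replacement
from a finite cluster frame, spatial correlation between clusters, and
non-beta prevalence distributions. Passing simulation tests show the
engine matches the package's own exact distribution (and that the design
machinery is internally consistent); they do not certify performance on
data violating those assumptions.

Sensitivity to the one assumption the designer controls — the ICC — is
the purpose of `simulation_summary()`: it simulates a fixed design under
a grid of *true* ICCs and reports empirical risks. Underestimating the
ICC inflates both risks beyond their bounds; overestimating it wastes
sample but keeps the guarantees. Designs with more clusters degrade more
gracefully.

Reproducibility: every public simulation entry point requires a seed,
and a whole `simulation_summary()` call runs on a single seeded RNG
stream (conditions drawn sequentially), so identical arguments and seed
reproduce the output bit for bit. Per-replicate substreams were
considered and rejected: the vectorized single-stream draw is simpler,
equally reproducible, and fast enough that parallelism is unnecessary at
the default 10,000 replicates (a full two-condition study runs in well
under a second).

## The ANOVA ICC estimator

After a survey, the ICC for the *next* design round can be estimated
from the collected binary outcomes. `anova_icc()` implements the
classical balanced one-way ANOVA moment estimator

$$\hat\rho = \frac{MSB - MSW}{MSB + (k-1)\,MSW},$$

which for binary outcomes is a function of the per-cluster counts alone
(`sum(y^2) = sum(y)` for 0/1 data). Three conventions matter:

* **Inestimability** is defined as a zero denominator, which happens
  exactly when all `m * k` outcomes are identical — no events in any
  cluster, or events everywhere. Both degeneracies are excluded, not
  just the no-events case; at a 5% prevalence with 36 units the
  no-events case dominates (roughly a quarter of replicates).
* The estimate is **not truncated** to `[0, 1]`: the raw estimator is
  negatively biased near `rho = 0` and individual estimates are often
  negative; truncation would hide exactly the bias a designer needs to
  see. Summaries report moments over estimable replicates only, while
  misclassification risks use *all* replicates.
* With few clusters (`m = 4`) the estimator is markedly biased downward
  relative to the true ICC even conditional on estimability — a
  conditional expectation the test suite verifies by exhaustive
  enumeration over all count configurations, which is feasible because
  the binary mean squares depend only on the `(k+1)^m` count tuples.
  Practitioners should treat ICC estimates from small-`m`
  implementations with caution: plugging them into the next design
  round risks underestimating the ICC, the harmful direction.

## Problem sizes and tolerances in the test suite

The tests run the full design grid (six ICC values, `m = 2..20`,
`k` searched to 500) exactly, since the whole table takes a few seconds.
Distributional identities (normalization, variance inflation, symmetry,
the binomial limit) are asserted at 1e-8 to 1e-12 on grids up to
`k = 500`; the log-space pmf loses a few digits by `k = 500`, so the
symmetry check relaxes to 1e-9 there. Convolutions are checked against
brute-force enumeration for `m <= 3`, `k <= 4`. Monte Carlo checks use
5,000–10,000 replicates and a 3.5-standard-error acceptance band
(two-sided miss probability about 5e-4 per comparison), with fixed seeds
chosen once.

## Known limitations

* Clusters are assumed equal-sized and drawn from an effectively
  infinite cluster population. With few clusters in the frame, the
  beta-binomial risks are conservative (true risks are smaller), so the
  designs remain valid but may oversample.
* No finite-population or hypergeometric correction within clusters.
* The risk guarantees are conditional on the assumed ICC; the package
  quantifies the cost of misspecification but cannot remove it.
* Areas whose true prevalence falls in the grey area are classified
  essentially at random; this is a property of the LQAS framing itself,
  not of the clustered extension.
* No Bayesian prior over prevalences is supported; incorporating prior
  knowledge of the prevalence distribution is a different design
  framework.
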