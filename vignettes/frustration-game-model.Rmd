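---
title: "A spatial game model of depression from payoff frustration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial game model of depression from payoff frustration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frustgame)
```

## The model

`frustgame` simulates depression onset driven by unfavourable social
comparison of economic payoffs. The population is an $n \times n$ square
lattice with toroidal boundary conditions (periodic in both directions,
chosen to remove edge effects), each cell one individual, connected to the
eight surrounding cells — the Moore neighbourhood of unit radius.

Each individual has played the investing-in-education game once, "against
the field": the individual's strategy is whether to acquire a formal
education (E) or not (NE); the field — the labour market — answers with
success (S) or nonsuccess (NS). The four outcomes pay $t$ for (NE, S), $r$
for (E, S), $p$ for (NE, NS) and $s$ for (E, NS), with the
prisoner's-dilemma ordering $t > r > p > s$ and $r > (t+s)/2$. Two earning
kinds A and B (proportions $c$ and $1-c$) split the success payoffs:
$t_A > t_B$, $r_A > r_B$; unsuccessful payoffs do not depend on kind. There
is no strategic choice in the simulation: strategies and outcomes are
assigned exogenously at configured population fractions, and the game is not
iterated.

Writing $q_i$ for the personal payoff and $\bar q_i$ for the arithmetic mean
of the eight neighbours' payoffs (the cell's own payoff excluded), the
one-shot transition rule is

$$\text{depressed}_i \iff \bar q_i - q_i > \begin{cases}\sigma & \text{men}\\
\tau & \text{women,}\end{cases}$$

evaluated simultaneously for all cells on the initially all-healthy lattice.
There is no recovery, no contagion and no time loop; the model is a static
threshold response to relative deprivation, with gender-specific
sensitivity.

### Parameters

| symbol | meaning | default | notes |
|---|---|---|---|
| $t_A, t_B, r_A, r_B, p, s$ | game payoffs (dimensionless) | 15, 10, 9, 6, 1, −1 | reference UK 2014-16 set |
| $c$ | kind-A fraction | 0.60 | applies to the whole population |
| $n$ | lattice side | 100 | $n^2 = 10{,}000$ individuals; $n \ge 3$ required |
| male fraction | gender mix | 0.493 | must be strictly inside $(0,1)$ |
| $\rho_{NE}$ | nonstudent fraction | 0.188 | students $\rho_E = 1-\rho_{NE}$ |
| $\rho_{NE,S}$ | successful nonstudents | 0.05 | absolute population share |
| $\rho_{E,S}$ | successful students | 0.75 | absolute population share |
| $\sigma, \tau$ | frustration thresholds | calibrated | payoff units; sign unconstrained |
| $x_o, \epsilon$ | calibration target and band | 0.20, 0.01 | prevalence fractions |
| $\Delta$ | adaptation step | 0.05 | payoff units |
| ratio band | female/male prevalence | $[1.5, 3.0]$ | epidemiological constraint |
| $\eta$ | ensemble replicates | 100 | |

The success shares $\rho_{NE,S}$ and $\rho_{E,S}$ are read as *absolute*
population fractions, so the six payoff-category probabilities are
$\pi(t_A) = \rho_{NE,S}\,c$, $\pi(t_B) = \rho_{NE,S}(1-c)$,
$\pi(r_A) = \rho_{E,S}\,c$, $\pi(r_B) = \rho_{E,S}(1-c)$,
$\pi(p) = \rho_{NE}-\rho_{NE,S}$, $\pi(s) = \rho_E-\rho_{E,S}$. A
consequence is that a sweep of $\rho_{E,S}$ is only feasible up to
$1-\rho_{NE}$; sweep functions flag points beyond that bound as infeasible
rather than silently dropping or rescaling them.

## The population generator

`assign_population()` is the package's synthetic-data generator and defines
the study conditions. Design choices:

* **Exact category counts.** All attribute counts come from
  largest-remainder apportionment (`allocate_counts()`, ties to the earlier
  category), and labels are placed by random shuffles of exact-count pools.
  A configured 10% is realised as exactly 10% in every draw, which removes a
  nuisance variance component from replicate ensembles and matches the idea
  of distributing official statistics over a population.
* **Independence structure.** Gender is shuffled independently of
  everything else, so gender carries no information about payoff (the test
  suite checks this with a pooled chi-square over realisations). The kind-A
  fraction $c$ is applied exactly *within* each payoff-relevant category —
  the six payoff categories get exact counts, and the unsuccessful
  categories are split $c : 1-c$ exactly as well — so kind is uninformative
  about education and outcome. The RNG consumption order (gender shuffle,
  then the joint strategy/kind shuffle) is fixed and documented, making
  every realisation bit-reproducible from its seed.
* **Coordinates** are 0-based `(row, col)` with row-major linear indexing;
  the torus wraps by modular arithmetic. `torus_neighbors()` returns the
  neighbour index as an `n² × 8` matrix aligned with the population's row
  order, built once and reused across replicates.

What the generator deliberately does *not* emulate: spatial correlation
(attributes are exchangeable across cells — there is no residential
clustering by income or education), household or network structure beyond
the fixed lattice, individual covariates other than gender/kind, and any
temporal dynamics. Tests that pass on this generator therefore validate the
model's internal logic and its statistics, not the realism of any particular
social geography.

## The exact oracle

`exact_prevalence()` provides an independent analytic route to the same
prevalence. Under an i.i.d. approximation (own payoff $\sim$ categorical
$\pi$; the eight neighbour payoffs $\sim$ Multinomial$(8, \pi)$,
independent), the depression probability at threshold $\theta$ is

$$P(\theta) = \sum_{q} \pi(q) \sum_{k \,\in\, C(8,6)}
\binom{8}{k_1 \cdots k_6} \prod_v \pi(v)^{k_v}\;
\mathbf{1}\!\left[\tfrac{1}{8}\textstyle\sum_v k_v v - q > \theta\right],$$

enumerated exactly over all $\binom{13}{5} = 1287$ compositions. Men use
$\sigma$, women $\tau$; the overall value is the gender-weighted mean. The
lattice simulator differs from this in one respect only: exact-count
assignment induces tiny negative correlations between cells, a discrepancy
of order $1/n^2$ (measured at a few parts in $10^4$ for $n \in \{30, 100\}$
by the test suite, well inside three Monte-Carlo standard errors of an
$\eta = 100$ ensemble). The oracle is implemented with vectorised
log-gamma arithmetic and is cross-checked in the tests against a separate
`stats::dmultinom` enumeration, so the two routes stay independent.

## Calibration: design choices

The calibration loop adjusts $(\sigma, \tau)$ on a fixed $\Delta$-grid until
the simulated prevalence matches $x_o$ within $\epsilon$ *and* the
female/male prevalence ratio falls in the configured band.

* **Corrective direction.** The update is negative feedback: prevalence
  above the band ⇒ both thresholds *increase* (a higher threshold strictly
  shrinks the depressed set, since the rule compares $\bar q_i - q_i$
  against it); prevalence below ⇒ both decrease. Any other sign convention
  moves the prevalence away from the target and cannot terminate; the
  package treats the corrective direction as the defining property of the
  algorithm. Monotonicity of the depressed set in each threshold (nested
  sets on a fixed realisation) is what guarantees the loop crosses the
  target band, and is itself a tested invariant.
* **Ratio branch, symmetric completion.** When prevalence is on target but
  the ratio is below `ratio_low`, $\tau$ alone decreases by $\Delta$ —
  depressing more women raises the ratio. The mirrored case (ratio above
  `ratio_high`, or undefined because no man is depressed) raises $\tau$.
  Starting from a symmetric $\sigma(0) = \tau(0)$ only the low-ratio branch
  is normally exercised; the high/undefined branch is a minimal symmetric
  completion, and its use is visible in the trace (`action` column,
  `ratio_extension_used` in `glance()`).
* **One calibration population.** By default a single population is drawn
  at the start and reused for every iteration, making $x(j)$ a
  deterministic, monotone step function of the thresholds — the loop then
  terminates cleanly at the first acceptable grid point. A
  `resample = TRUE` mode redraws the population each iteration for
  sensitivity analysis; with the default $\epsilon = 1\%$ band and
  $n = 100$ (per-replicate noise $\approx 0.2$ percentage points) it
  converges all the same.
* **Grid bookkeeping.** Thresholds are stored as integer step counts and
  materialised as `sigma0 + k * delta`, so reported values sit on the
  $\Delta$-grid without floating-point drift.
* **Ties and degenerate cases.** The transition inequality is strict; a
  payoff gap exactly equal to the threshold stays healthy (an
  equality-inclusive variant is intentionally not exposed — at the default
  payoffs the gap lattice is multiples of $1/8$ and the distinction only
  matters on grid coincidences). The ratio is `Inf` when only women are
  depressed and `NA` when nobody is; both are treated as "above the band"
  in the ratio branch. `max_iterations` (default 1000) guards against a
  $\Delta$ too coarse for $\epsilon$: the result is then flagged
  unconverged and carries the full trace instead of a fabricated answer.

### Behaviour on the reference configuration

With the default composition the payoff landscape is strongly unequal: about
20% of individuals hold $p = 1$ or $s = -1$ while the neighbourhood mean sits
near 6.6, so at thresholds of order one the model already classifies over
30% of the population as depressed (this is directly computable:
`exact_prevalence(fs$pop, fs$game, thresholds(1, 1))`). Reaching a 20%
target therefore drives the calibration *up*, to $\sigma^* \approx 4.7$–$4.9$
and $\tau^* \approx 1.6$–$1.9$ depending on the calibration population, where
the depressed set consists of the unsuccessful strata modulated by their
neighbourhoods. The ratio criterion stops at its first satisfied grid point,
which lands the ensemble female/male ratio just above the lower band edge
(≈1.55–1.65). The acceptance script recomputes exactly these quantities at
run time; nothing in the package hard-codes them.

At those calibrated thresholds the sweeps show: prevalence decreasing in
$\rho_{NE,S}$ (success replacing failure among nonstudents), a rise-and-fall
in $\rho_{E,S}$ with an interior worst point (maximum inequality at
intermediate student success; at the calibrated thresholds the peak sits
near $\rho_{E,S} \approx 0.4$), and — because the thresholds are large —
prevalence mildly *decreasing* in $\rho_{NE}$: adding nonstudents lowers the
neighbourhood mean, which pulls the typical payoff gap below a high $\sigma$
faster than it adds low-payoff individuals. At small thresholds the same
sweep increases instead; the sign of this trend is threshold-dependent, not
a universal property of the model.

## Problem sizes

The test suite exercises lattices of side 3–100. Full-scale checks (the
calibration, the $\eta = 100$ ensemble and the trend sweeps) run on
$n = 100$ with 20–30 replicates per sweep point; distributional and
property-style tests use $n = 20$–50 with fixed seeds, sizes at which every
statistical tolerance is derived from measured Monte-Carlo error rather
than tuned. The 3-D factorial sweep defaults to a 2.5-point grid with
$\eta = 100$ and is the only operation that takes more than seconds at full
scale; its tests run on a deliberately coarse grid.

## Known limitations

* The transition is one-shot: no disease course, remission, treatment or
  social contagion of mood.
* Thresholds are population constants; there is no individual heterogeneity
  in frustration tolerance beyond gender.
* The absolute-fraction reading of the success shares restricts feasible
  sweep ranges (flagged, not rescaled); an alternative within-stratum
  reading would change the payoff-category arithmetic throughout.
* The female/male ratio criterion accepts at the *first* grid point inside
  the band, so the calibrated ratio tends to hug the band edge nearest the
  symmetric start; it is a constraint, not a fitted quantity.
* The exact oracle assumes i.i.d. assignment and is biased by $O(1/n^2)$
  relative to the exact-count simulator; at $n < 10$ this bias can exceed
  Monte-Carlo error.
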