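---
title: "Modelling stem-cell competition under chronic low-dose-rate radiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stem-cell competition under chronic low-dose-rate radiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcompete)
```

## The model

A stem-cell pool of fixed size $N$ holds two cell types: intact and damaged.
Chronic irradiation converts intact cells to damaged cells irreversibly
("transitions"); the dose-rate parameter $\lambda$ is the expected number of
successful track hits per cell per cell-cycle length, folding the physical
hit rate and the per-hit damage probability $H$ (which absorbs repair) into
one number. Turnover follows a Moran process: each elementary step one cell
divides, chosen uniformly, and one cell is eliminated, chosen with
probability proportional to its *cost*. Cost is inverse fitness - a cell
that is expensive to keep is the one competition removes - and it is
*frequency-dependent*, set by a $2\times2$ interaction cost matrix with
entries $c_{I\leftarrow I}, c_{I\leftarrow D}, c_{D\leftarrow I},
c_{D\leftarrow D}$ (`cost_matrix()`).

With $k$ damaged cells present, the expected costs of an intact and a
damaged cell are the partner-frequency averages

$$F_k = \frac{c_{I\leftarrow I}(N-k-1) + c_{I\leftarrow D}\,k}{N-1},
\qquad
G_k = \frac{c_{D\leftarrow I}(N-k) + c_{D\leftarrow D}(k-1)}{N-1},$$

and the damaged-cell count moves up or down by one per elementary step with

$$P_{k,k+1} = \frac{k}{N}\,\frac{(N-k)F_k}{(N-k)F_k + kG_k},
\qquad
P_{k,k-1} = \frac{N-k}{N}\,\frac{kG_k}{(N-k)F_k + kG_k}.$$

Only cost *ratios* enter, so scaling all four entries by a common factor
leaves the law unchanged (a tested invariant), and matrices are classified
by which type is cheaper against each partner type (`regime()`): intact or
damaged dominance, positive frequency dependence (own-type interactions
cheaper; a coordination game) or negative frequency dependence (cross-type
interactions cheaper; includes hawk-dove).

$N$ elementary steps constitute one cell cycle, the model's time unit. The
headline observable is $T_{abs}$: the mean number of cell cycles until
damaged cells occupy the entire pool, the unique absorbing state once
$\lambda > 0$. Large $T_{abs}$ means competition retards damage
accumulation; in the neutral case (all costs equal) $T_{abs}$ is the
baseline against which suppression or promotion is judged.

## Radiation scheme

The model statements to reconcile are that $\lambda$ is (i) the expected
number of transitions per elementary step when nearly all cells are intact,
and (ii) the expected number of hits per cell per cell cycle. Both hold
under Poisson thinning: each intact cell independently converts with
probability $1 - e^{-\lambda/N}$ per elementary step. Expected transitions
per step approach $\lambda$ as $k \to 0$, per-cell hits per cycle equal
$\lambda$, and the scheme is valid for any $\lambda \ge 0$, with no
$\lambda \le 1$ restriction that a single-hit Bernoulli step would need.
Within an elementary step radiation acts first and division/elimination
second, and costs are evaluated on the post-radiation composition -
the sequential reading of the process description.

## Analytic machinery

With radiation off, a single damaged cell fixes with the classic
birth-death probability

$$\pi_1 = \Bigl(1 + \sum_{j=1}^{N-1}\prod_{k=1}^{j} G_k/F_k\Bigr)^{-1},$$

and at very low dose rates absorption is dominated by waiting for the first
hit whose lineage fixes, giving $T_{abs} \approx 1/(N\lambda\pi_1)$
(`approx_absorption_time()`). Three numerical choices matter:

* **Log space.** The partial products overflow double precision well below
  $N = 10^4$ in dominant regimes, so `fixation_probability()` accumulates
  $\log(G_k/F_k)$ and aggregates by log-sum-exp. The neutral identity
  $N\pi_1 = 1$ then holds to $10^{-12}$ even at $N = 10^5$.
* **Independent cross-check.** `fixation_probability_bruteforce()` solves
  the first-step hitting-probability system directly. The tridiagonal
  Thomas solve runs in extended precision with iterative refinement because
  strongly selected matrices make the system ill-conditioned in double
  precision (observed forward errors up to $10^{-7}$); with the refined
  solve the two routes agree to better than $10^{-10}$ across random
  matrices up to $N = 50$.
* **Exact oracle.** `exact_expected_absorption_time()` builds the composite
  one-step matrix (binomial radiation jump, then the Moran step) on
  $k = 0..N$ and solves $(I - Q)\,t = \mathbf{1}$; it is the ground truth
  the stochastic engine is validated against for $N \le 100$.

The approximation ignores the time fixation itself takes, so it can
undershoot badly outside its regime: for negative-frequency-dependent
matrices an interior coexistence attractor makes conditional absorption
slow, and at $\lambda = 0.01$, $N = 36$ the exact value exceeds the
approximation by two orders of magnitude. The dose-rate sweep therefore
always tabulates the simulation/approximation ratio so the user can see
where the closed form is trustworthy.

## Pool-size shape analysis

Because $T_{abs} \approx f(N)/\lambda$ with $f(N) = 1/(N\pi_1)$, the
pool-size dependence is dose-rate free. $f$ is normalized so the neutral
case is identically 1. `classify_shape()` inspects the sign pattern of
successive differences of $\log f$ over a pool-size grid: all negligible
(`constant`), one-signed (`monotone_*`), a decrease run followed by an
increase run (`convex_down`), anything else `other` - mixed patterns are
reported loudly rather than forced into a category. Working on the log
scale is what makes $N = 10^5$ reachable; sign patterns are invariant under
the monotone transform, and the $10^{-9}$ tolerance on log differences is a
first-order $10^{-9}$ relative tolerance on $f$, small enough that the
neutral case classifies as constant rather than noise-monotone.

The default grid `default_n_grid()` runs from $N = 2$ to $10^5$ with
log-ish spacing, dense at small $N$ where the convex-down dip lives. The
two boundary indicators are implemented as their operational definitions
rather than closed forms: `small_n_decrease()` tests $f(3) < f(2)$ and
`large_n_increase()` tests $f(10^5) > f(5\cdot10^4)$, both with strict
inequalities (ties fall outside the boundary; the raw $f$ values are
exposed for anyone wanting a different convention).

## The lattice variant

`simulate_lattice_absorption_times()` puts the pool on an $L \times L$
torus, one cell per site, with 8-site Moore neighborhoods. A site's cost is
its cost-matrix average over the 8 neighbors; elimination picks a site with
probability $\Phi_i/\sum_j \Phi_j$; the vacancy is filled by a uniform draw
from the nine candidates consisting of the removed cell itself and its 8
neighbors. Including the removed cell is the only reading under which a
clone of the removed cell can reoccupy its own space, as the replacement
rule requires; it also makes uniform grids exact fixed points of the
competition step. Radiation is the well-mixed scheme with $N = L^2$.
$L = 3$ is permitted but flagged: under periodic wrap every site then
neighbors every other, so the model degenerates toward well-mixed.
Comparisons with the well-mixed model are restricted to perfect-square pool
sizes; the runner refuses to approximate a non-square $N$.

Because spatial fixation probabilities have no tractable closed form,
`estimate_fixation_probability_lattice()` estimates $\pi_1$ by replicate
simulation from a single damaged cell placed uniformly at random -
translation invariance of the torus makes the placement irrelevant, and
randomizing it documents that fact in the tests.

The engine maintains per-site costs incrementally (a flip touches only the
site and its 8 neighbors, each recomputed exactly from its neighbor count,
so no floating-point drift accumulates); a full-grid recompute path exists
in R (`site_costs()`) and equality of the two is a test.

## Random numbers, skip-ahead, and reproducibility

The compiled engines draw from a private `mt19937_64` per replicate, seeded
by a splitmix64 hash of (seed, replicate index): sweeps are reproducible,
replicate-order independent, and platform-stable (no `std::*_distribution`,
whose mapping from bits to variates is implementation-defined; binomial and
categorical draws are inverse-CDF). The single-step R functions
(`radiation_substep()`, `moran_substep()`, `lattice_substep()`) use R's
global RNG and exist for inspection and testing; the engines are validated
against the exact chain, not against them.

While the pool is all-intact, division/elimination cannot change anything
and the only possible event is a radiation hit, so the engines sample the
geometric waiting time to the first hit-carrying step directly and then the
hit count from a $\ge 1$-conditioned binomial (exact inverse-CDF). This is
law-identical to stepping through the idle period and is what makes
low-dose-rate runs ($\lambda = 10^{-4}$, thousands of replicates) take
seconds instead of hours. Replicates that exceed `max_cycles` (default
$10^7$ elementary steps) are returned as censored records, counted and
excluded from means, never silently dropped - damaged-disadvantaged
regimes at tiny $\lambda$ can be astronomically slow, and a censored row is
more honest than a hang.

## Problem sizes and what the tests show

The test suite validates the simulation engines against the exact chain at
$N \in \{2, 5, 10\}$, $\lambda \in \{0.01, 0.1\}$ with 2000 replicates
(3-standard-error agreement), checks the approximation ratio at
$\lambda = 10^{-4}$, and exercises the lattice claims at $L = 4..10$ with
150-200 replicates: neutral fixation at $1/L^2$, the monotone lattice trend
for the positive-frequency-dependent matrix
$(1, 1.75, 1.25, 0.5)$ over $N \in \{16, 36, 64, 100\}$, and faster lattice
occupation for the negative-frequency-dependent matrix
$(1, 0.25, 0.5, 0.75)$ at $N = 36$. For the trend comparison the analytic
well-mixed curve is classified on a denser grid spanning the same
$[16, 100]$ range: its minimum lies near $N \approx 24$, so the curve is
convex down on the range even though a four-point subsample straddles the
dip. These sizes are an order of magnitude below tissue-scale stem-cell
counts but large enough that every qualitative regime distinction the model
makes is exercised.

All inputs here are model parameters - there is no synthetic-data layer to
mistake for biology. What the simulations emulate is the model itself:
irreversible single-hit damage, constant cost matrices, a fixed pool with
no external influx, and (on the lattice) a homogeneous torus. Real stem-cell
niches have influx, repair, dose-rate-dependent interaction phenotypes, and
irregular geometry; agreement of the engines with the model's own exact
chain says nothing about those. The package's claims are about the model,
and the dosimetry helpers (`occupational_lambda()`) exist only to place a
physically meaningful $\lambda$ - about 0.08 hits per cell per 24-h cycle
for a worker at the 20 mGy/year occupational limit - on the model's axis.

## Known limitations

Two cell types only; no repair or back-conversion; cost matrices constant
in dose rate (plausible extensions would make the damaged-cell entries
functions of $\lambda$); periodic square lattices with Moore neighborhoods
only; the exact oracle is dense and stops at $N = 100$; conditional
fixation-time corrections to the low-dose-rate approximation are not
implemented - the exact chain or the simulator covers the regimes where
they would matter.
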