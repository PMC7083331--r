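---
title: "Multi-state Markov kinetics of the epithelial-to-mesenchymal transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state Markov kinetics of the epithelial-to-mesenchymal transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtkinetics)
```

## The model

The epithelial-to-mesenchymal transition (EMT) is observed experimentally
as three macroscopic phenotypes — epithelial (E), partial EMT (P) and
mesenchymal (M) — but population time courses of the three macrostate
fractions decay too slowly to be explained by a three-state Markov chain:
the dwell times are visibly non-exponential. `emtkinetics` models EMT as an
absorbing continuous-time Markov chain over *hidden microstates*. Each
macrostate contains one or more microstates; a cell traverses them
irreversibly (or, optionally, with a backward rate) until it reaches the
absorbing mesenchymal state. Non-exponential macrostate dwell times then
arise naturally as phase-type (Erlang / hypoexponential) distributions.

Transition rates follow an Arrhenius energy-barrier law. With the energy
measured in units of $k_BT$, a step with barrier $\delta E$ proceeds at
$k = k_0 e^{-\delta E}$, where $k_0$ (1/day) sets the time scale. The total
barrier $\Delta E$ from E to M is fixed, and a topology distributes it
over steps:

* **chain** — $N_{int}$ intermediates in series; the barrier splits evenly,
  $k = k_0 e^{-\Delta E/(N_{int}+1)}$, and the arrival time into M is
  Erlang$(N_{int}+1, k)$ with mean first arrival time (MFAT)
  $(N_{int}+1)/k$;
* **parallel** — $N_{pth}$ disjoint paths of near-equal length; path $i$
  with $N_i$ intermediates gets $k_i = k_0 e^{-\Delta E/(N_i+1)}$ and the
  root exits at $k_A = \sum_i k_i$;
* **layered** — the cell must cross $N_{ly}$ layers; all steps share
  $k = k_0 e^{-\Delta E/(N_{ly}+1)}$ and the root exit aggregates over the
  $N_{L1}$ first-layer states, MFAT $= (N_{ly} + 1/N_{L1})/k$;
* **stabilized** — one chain intermediate has an $m$-fold larger exit
  barrier (a deeper well). Either the total barrier is held constant
  (regular steps $k_1 = k_0 e^{-\Delta E/(N_{int}+m)}$, stabilized exit
  $k_2 = k_0 e^{-m\Delta E/(N_{int}+m)}$) or the regular steps keep the
  even split and the total grows
  ($k_1 = k_0 e^{-\Delta E/(N_{int}+1)}$,
  $k_2 = k_0 e^{-m\Delta E/(N_{int}+1)}$).

The central structural prediction is a trade-off: subdividing a fixed
barrier into more steps raises each step's rate exponentially but adds
steps linearly, so the MFAT
$(N_{int}+1)\,e^{\Delta E/(N_{int}+1)}/k_0$ is minimized near
$N_{int}+1 = \Delta E$ and the minimum is interior whenever
$\Delta E \gtrsim 2$. Parallel paths help at low barriers and hurt at high
ones; layers do the opposite; the two MFAT-versus-$\Delta E$ curves cross
exactly once for comparable topologies. A stabilized intermediate traps
cells for a mean dwelling time of exactly $1/k_2$ and can only delay
completion.

## Parameters, units and defaults

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `delta_E` | total barrier E to M | $k_BT$ | — |
| `k0` | attempt rate | 1/day | 1 |
| `k_fit`, `N_fit` | calibration: fitted step rate and chain length | 1/day, count | 3.4261, 9 |
| `N_int`, `N_pth`, `N_ly` | intermediates, paths, layers | counts | — |
| `S`, `m` | stabilized index, barrier ratio | count, ratio $\ge 1$ | — |

Time is measured in days throughout, because the calibration anchoring the
rate scale (`k_fit` = 3.4261/day through nine intermediates, from fitting
TGF-$\beta$-induced EMT of MCF10A cells at daily sampling) is on the day
scale. `calibrate_k0()` inverts
$k_{fit} = k_0 e^{-\Delta E/(N_{fit}+1)}$, so that whatever barrier is
assumed, the calibrated chain reproduces the fitted kinetics exactly.

In the parallel case the package divides each path's barrier over its own
$N_i + 1$ steps ($k_i = k_0 e^{-\Delta E/(N_i+1)}$). This per-path even
split is an assumption: nothing in the barrier picture fixes how unequal
path lengths share $\Delta E$, and the chosen reading is the one under
which every root-to-absorbing path crosses the same total barrier.

Intermediates are split over branches as evenly as possible. Path sizes
are reported ascending and layer remainders go to the earliest layers
(`N_L1 = ceiling(N_int/N_ly)`); the order is observationally irrelevant —
every downstream quantity depends only on the multiset of sizes — and is
fixed purely so outputs are deterministic.

## Two conventions worth knowing about

**Parallel MFAT.** The package computes the parallel mean as
$(1 + \sum_i N_i)/k_A$, from first-step analysis: the root waits
$1/k_A$, enters path $i$ with probability $k_i/k_A$, and then needs
$N_i$ stages of mean $1/k_i$, so the path terms collapse to
$\sum_i N_i / k_A$. A superficially different published closed form,
$(\sum_i k_i + N\,k_A)/k_A^2$, agrees with this expression only when $N$
denotes the *total* intermediate count; read per-path it disagrees with
simulation already for two one-state paths at $k=1$ (1.0 versus the
correct 1.5 days). The implementation follows the derivation, which the
Gillespie ensemble confirms, and the quadrature cross-check in
`fat_summary()` guards the identity at run time.

**Arrival at the stabilized state.** The occupancy of the state just
before the stabilized one is an Erlang$(S, k_1)$ term, which makes the
mean arrival time into the stabilized state $S/k_1$. A published variant
states $(S+1)/k_1$, consistent with a convention that counts the exit
from E as a step. `mfat_to_stabilized()` returns $S/k_1$ by default —
the value the stochastic simulator reproduces — and exposes the offset
variant via `convention = "offset"` rather than silently choosing.

## Numerical choices

* **Erlang terms** are evaluated as Poisson point masses
  (`dpois`/`ppois`), i.e. in log space: occupancies remain finite and
  conservative for $kt$ far beyond the overflow point of the naive
  $(kt)^{n-1}/(n-1)!$ form.
* **Hypoexponential occupancies** (parallel, layered) have textbook
  closed forms that subtract truncated exponential sums; for large
  $|k_i - k_A|\,t$ those alternate catastrophically. The package instead
  expands the defining convolution into a positive-term series summed in
  log space (`logsumexp`), accurate to full precision for either sign of
  $k_i - k_A$; the $k_i = k_A$ limit is the chain and is delegated to it.
* **Stabilized-chain occupancies** use regularized incomplete-gamma
  identities: the arrival CDF into any post-stabilized state is
  $H_n(t) = P(\mathrm{Erlang}(n,k_1) + \mathrm{Exp}(k_2) \le t)
  = \mathrm{pgamma}(k_1 t, n) - (k_1/(k_1-k_2))^n e^{-k_2 t}\,
  \mathrm{pgamma}((k_1-k_2)t, n)$, with the second term assembled in log
  space because the ratio power overflows as $k_2 \to k_1$. Below a
  relative rate difference of $10^{-9}$ the uniform-chain limit is
  returned (the removable $m = 1$ singularity).
* **Reversible chains** are solved by a uniformized matrix exponential
  ($P = I + A/\lambda$, Poisson-weighted powers, truncation tail below
  $10^{-12}$, sequential propagation over sorted time points). This was
  chosen over eigendecomposition because the generators of interest are
  frequently *defective* — a repeated rate gives repeated eigenvalues
  with deficient eigenvectors, which makes an eigen-solver singular while
  uniformization is unaffected.
* **Quadrature.** Every `fat_summary()` carries a composite-Simpson
  normalization and mean computed on a uniform grid over
  $[0, \max(50\,\mathrm{MFAT}, 10)]$ days (4097 points), which holds all
  but $\sim 10^{-9}$ of the density mass; the closed-form means agree
  with these quadratures to better than $10^{-6}$ relative in the tests.
* **Three-state confluent limit.** When $|k_1 - k_2|/k_1 < 10^{-9}$ the
  printed two-exponential form is replaced by its limit
  $p_P = k_1 t\,e^{-k_1 t}$.
* **Gillespie tie-break.** Event selection uses a strict-left /
  inclusive-right cumulative-propensity rule
  ($\sum_{i<r} a_i < u\,a_0 \le \sum_{i\le r} a_i$); the tie is measure
  zero. Per-cell RNG substreams are seeded as `seed + cell index`, so
  enlarging an ensemble never reshuffles earlier cells, and the horizon
  defaults to $50\times$ the analytic MFAT so censoring is negligible
  (censored cells are excluded from arrival statistics and counted).

## Fitting hidden microstate counts

`fit_irreversible()` reproduces the grid-search procedure for population
time courses: for every combination of $N_E$ epithelial and $N_P$
partial-EMT microstates (defaults $N_E \in 1..10$, $N_P \in 0..10$;
$N_P = 0$ is the two-state model), the common step rate $k$ is fitted by
bounded scalar minimization (log-parameterized, bounds $[10^{-3},
10^{3}]$/day, tolerance $10^{-10}$) of the root-mean-squared error pooled
with equal weight over the three macrostate curves and all time points, on
the percent scale. Pooling and weighting are a choice — the procedure's
description leaves them open — and equal weights keep reported RMSEs on
the familiar percentage-point scale. Grid ties break toward smaller
$N_E + N_P$, then smaller $N_E$ (parsimony). Boundary solutions are
flagged, not hidden. `fit_reversible()` adds a backward rate and fits both
rates per grid cell by L-BFGS-B from three starts; its default forward
bound is $10^2$/day because the uniformization cost grows with
rate $\times$ horizon and day-scale data never identifies faster rates
(the bound is an argument, not a constraint of the method).

## What the synthetic generator does and does not emulate

`generate_timecourse()` stands in for the induction experiment the model
is calibrated against: cells initially 100% epithelial, driven
irreversibly to M, observed as macrostate percentages at days 0–8 with
multinomial sampling at $10^4$ cells per time point, truth
$(N_E, N_P, k) = (5, 5, 3.4261/\mathrm{day})$. Multinomial (not
independent binomial) sampling keeps rows summing to exactly 100. The
sampling days and cell counts of the original experiment are not public;
these defaults are stated assumptions, recorded in the generated file's
metadata header, and everything is configurable.

The generator reproduces the *statistical* structure the fitting assumes
— exchangeable cells, synchronous induction, exact macrostate
classification, time-stamped cross-sections. Real data add marker
misclassification near gate boundaries, asynchronous induction, growth
and death, and batch effects. Passing recovery tests on synthetic data
therefore shows the procedure is correct and well-conditioned at realistic
noise levels, not that a particular biological dataset has exactly five
and five microstates.

## Problem sizes used in the validation suite

The test suite validates each closed form against direct integration of
its generator (deSolve, 100+ randomized instances at $N_{int} \le 8$),
and against Gillespie ensembles of $10^4$ cells for the chain
($N_{int}=9$, $k=3.4261$), parallel $(4,5)$ at $\Delta E = 6$, layered
$3\times3$ at $\Delta E = 5$, and stabilized $(S=6, m=6)$ at
$\Delta E = 10$ scenarios, using simultaneous Bonferroni multinomial
bounds at family level 0.01 and three-standard-error checks on means.
The parameter-recovery study uses 20 multinomial replicates at $10^4$
cells. These sizes give comfortable statistical power for the asserted
tolerances while keeping the full suite around two minutes.

## Known limitations

* Topologies are restricted to chain / parallel / layered (plus one
  stabilized chain state); arbitrary DAGs and mixed
  parallel-of-layered designs are out of scope, as are continuum
  (infinite-state) limits.
* Layered solutions are layer-aggregated; per-state layered detail is
  available only through the simulator.
* The minimum-over-branches MFAT decreases with $N_{int}$ only up to the
  granularity of the integer branch split: uneven path sizes produce
  sub-percent upticks at a few $N_{int}$ (e.g. 13 and 17 at
  $\Delta E = 6$) on an otherwise decreasing curve.
* Reversible chains keep M absorbing (no backward flow out of M); the
  reversibility applies to the transient microstates only.
* Model selection is by raw RMSE, as in the original procedure; no
  information criterion penalizes the microstate counts beyond the
  parsimony tie-break.

## A worked example

```{r example}
# calibrated chain: barrier 10 kBT through 9 intermediates
k0 <- calibrate_k0(10)
ra <- step_rates(energy_config(10, k0), topology_spec("chain", N_int = 9))
fat_mfat_chain(ra$step_rates[1], 9)$mfat   # mean first arrival, days

# where is the optimal chain length for this barrier?
mfat_surface(10, 0:30)$argmin

# recover hidden microstate counts from a synthetic experiment
tc <- generate_timecourse(generator_spec(seed = 1))
fit_irreversible(tc)
```
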