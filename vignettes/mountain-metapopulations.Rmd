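---
title: "Metapopulations of virtual species on warming mountain landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metapopulations of virtual species on warming mountain landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spomscape` simulates the fate of virtual mountain species under climate
warming with a deliberately minimalist model: the only environmental covariate
is elevation, so that whatever differences emerge between landscapes can be
attributed to their geomorphology (area distribution across elevations,
habitat connectivity and fragmentation) rather than to ecological detail.
This vignette explains the model, the calibration that makes species
comparable, the warming experiment, and the numerical and design choices made
where more than one option was defensible.

## The occupancy model

The landscape is a grid of $N$ cells with elevations $z_i$. A species is a
triple $(z_{\mathrm{opt}}, \sigma, D)$ with Gaussian elevational fitness

$$f_i = f_{\max}\, e^{-(z_i - z_{\mathrm{opt}})^2 / (2\sigma^2)},$$

where $z_{\mathrm{opt}}$ is the elevation of maximal fitness (m), $\sigma$ the
niche width (m) and $D$ the dispersal distance (cell units; the grid spacing
is the distance unit). Occupancy $p_i(t) \in \{0, 1\}$ evolves as a
synchronous Markov chain. Over a step $\Delta t$, an occupied cell goes
extinct with probability $1 - e^{-E_i \Delta t}$, where $E_i = e / f_i$, and
an empty cell is colonized with probability $1 - e^{-C_i(t) \Delta t}$, with

$$C_i(t) = c \sum_{j \ne i} p_j(t)\, f_j\, \frac{e^{-d_{ij}/D}}{2\pi D^2}.$$

Distances are Euclidean between cell centers (minimal-image on periodic
landscapes); connectivity does not depend on the suitability of the path.
All transition probabilities of a step are evaluated from the state at time
$t$, then every cell performs one independent Bernoulli draw — a cell is
either a colonization candidate or an extinction candidate, never both. The
empty landscape is absorbing, and immigration from outside the grid is
disabled throughout.

The extinction and colonization constants default to $e = 0.02$ and
$c = 15\,\mathrm{yr^{-1}}$. Only their ratio matters for which species
persist (the persistence criterion below depends on $e/c$), while their
magnitude sets the pace of turnover relative to $\Delta t$.

## Comparable viability: the equal-fitness-mass calibration

The mean-field landscape matrix $\mathbf M$ has entries $m_{ij} = f_i f_j$
($i \ne j$, zero diagonal). Its leading eigenvalue $\lambda_M$ is the
metapopulation capacity: the species persists iff $\lambda_M > e/c$. On a
geomorphologically unbiased reference landscape — an infinite 1D constant
slope with the species centered on it — the Perron–Frobenius row-sum bound on
$\lambda_M$ is attained at the optimal-elevation row and converges, as the
domain grows, to the Gaussian integral

$$\sum_j f(z_{\mathrm{opt}}) f(z_j)\,\Delta x \;\to\; f_{\max}^2\, \sigma
\sqrt{2\pi}.$$

Holding this bound at $\sqrt{2\pi}$ for every niche width therefore requires

$$f_{\max} = 1/\sqrt{\sigma}.$$

This is the equal-viability constraint applied by `fmax_for_sigma()` and, by
default, by `species_params()` and `sample_species_pool()`: wide niches come
with low fitness everywhere, narrow niches with high fitness near the
optimum, and all species start from the same reference viability. Note two
subtleties, both documented in the code:

* the *bound* is what is equalized, not $\lambda_M$ itself; the actual
  leading eigenvalue on the discretized slope tracks $\sum_i f_i^2$ and
  retains a residual width dependence. `metapop_capacity()` (rank-one power
  iteration, never materializing $\mathbf M$) and `perron_bound()` are both
  exported so the distinction can be inspected.
* `metapop_capacity()` power-iterates $\mathbf M + \max(f^2)\,\mathbf I$:
  $\mathbf M$ can have a negative eigenvalue of the same magnitude as the
  leading one (exactly so for two cells), which stalls unshifted power
  iteration. The shift makes the leading eigenvalue strictly dominant.

The calibration uses the mean-field matrix, with no dispersal kernel, exactly
as the persistence criterion is formulated. A kernel-weighted capacity
(`metapop_capacity_kernel()`) is provided as a diagnostic of dispersal
limitation but plays no role in the calibration.

## Climate warming as an upward niche shift

A warming of $\Delta T$ degrees over $\Delta t_c$ years, combined with an
atmospheric lapse rate $\gamma_w$ (degrees lost per meter climbed), displaces
isotherms upward at $\Delta T / (\gamma_w \Delta t_c)$ meters per year. The
defaults — $\Delta T = 4\,^\circ$C over 100 yr (a worst-case scenario) and
$\gamma_w = 1/150\,^\circ$C/m — give 6 m/yr. `warming_schedule()` derives the
rate; during a warming run the optimum moves up by `shift_rate * dt` after
every step and the fitness field is recomputed. Species do not adapt:
ecological timescales are assumed much shorter than evolutionary ones, and
warming is spatially uniform.

## The five-step fate experiment

For each species, `run_fate_experiment()` runs an ensemble of replicates
(default 100) through five phases:

1. **Regional filter.** From full occupancy, run to quasi-stationarity under
   constant climate. The species is *regional* if at least half the
   replicates (configurable) are non-extinct; extinct replicates are
   re-seeded with equilibrium configurations drawn from the survivors, so the
   warming phase starts from a complete ensemble.
2. **Warming.** Each replicate runs for the warming duration with the
   optimum drifting upward.
3. **Extinction debt.** Climate is frozen at the post-warming optimum and
   surviving replicates run on; deaths in this phase are the debt being paid.
4.–5. **Suitability rerun.** If any replicate died during warming, step 1 is
   repeated at the post-warming optimum, deciding whether the new conditions
   would have been suitable at all.

Per-replicate outcomes (extinct during warming and suited/unsuited,
extinction debt, survivor with increased/decreased occupancy) are reduced to
a species fate by majority, with ties broken worst-first
(`extinct_unsuited` > `extinct_suited` > `extinction_debt` >
`survivor_decrease` > `survivor_increase`). Survivor increase vs decrease
compares the ensemble median occupancy at the end of step 3 against the
step-1 median; any nonzero change counts (an optional tolerance argument adds
a dead zone, default 0, since no numeric threshold is inherent to the
definition). `occupancy_relative_trajectory()` reduces the replicate
trajectories to the median percentage of the initial median occupancy, the
quantity used to describe range contraction during and after warming.

Choices worth flagging:

* "Stationarity" is implemented as fixed horizons with early exit on
  extinction: 500 yr for the equilibrations (steps 1 and 4–5) and 500 yr for
  the debt phase. Debt payoff can take centuries, which motivates horizons
  this long; both are configurable.
* The warming duration is exactly 100 yr; with the default $\Delta t = 1$ yr
  the optimum moves exactly 6 m per step.
* Seeding is keyed on (base seed, species id, replicate, phase), so sweeps
  are reproducible, independent of pool ordering, and the replacement rule in
  step 1 draws from the replicate's own seed stream.

## Landscapes

Three geometric landscapes isolate specific geomorphic features, all with a
0–3000 m relief and absorbing boundaries:

* **pyramid** — area decreases monotonically with elevation (shrinking
  cross-section perimeter);
* **roof** — uniform hypsographic curve (elevation depends only on one grid
  axis), isolating connectivity effects from area effects;
* **cone-in-a-square** — hump-shaped hypsographic curve: the cone's base
  radius is the circumscribed radius (it reaches the grid corners), so area
  per elevation band vanishes at the base (only the four corner sectors),
  peaks where the cross-section circle is inscribed in the square (about
  $0.29\,z_{\max}$), and decreases toward the apex. This mimics the
  mid-elevation area maximum of real mountain ranges. (An inscribed cone with
  flat corners — available via the `radius` argument — instead concentrates
  area in the lowest band and loses the hump.)

**Optimal Channel Networks** provide statistically realistic topographies:
starting from a random loop-free drainage forest on a periodic lattice
(`init_drainage()`), single-cell drainage-direction proposals are accepted
greedily (or by simulated annealing with geometric cooling) when they do not
create loops and do not increase the total energy dissipation
$E = \sum_i A_i^\gamma$, with drainage areas maintained incrementally along
the affected flow paths. Elevations follow from the slope–area relation
(local slope $\propto A^{\gamma - 1}$, $\gamma = 0.5$ by default; link
lengths 1 or $\sqrt 2$), accumulated upstream from outlet level zero and then
rescaled to the target relief. The proportionality constant of the slope is
immaterial because of the rescaling. The default budget of $50 n^2$ greedy
proposals is enough for a 64×64 lattice to develop the hump-shaped
hypsographic curve; individual realizations are stochastic, so only
statistical properties (energy decrease, mass conservation, upstream
elevation growth, hypsographic shape) are meaningful, not specific maps.

Real digital elevation models load through `load_dem()` (ESRI ASCII grids,
single-band TIFF), are affinely rescaled to 0–3000 m so relief matches the
synthetic landscapes, and can carry a reporting mask (polygon or 0/1 raster):
occupancy is then reported inside the mask while the dynamics run on the full
buffered square, avoiding border artifacts. No-data cells inside the
simulation square are rejected rather than imputed, and no hydrological
conditioning (pit filling, flow routing) is attempted on real data.

## Numerical choices

* **Kernel truncation.** The dispersal kernel is truncated at `cutoff * D`
  (default 10 dispersal lengths), discarding relative contributions below
  $e^{-10}$.
* **Convolution.** Colonization rates are computed either by direct
  summation over occupied sources or by FFT convolution on a padded grid
  (wrap-around-safe for absorbing boundaries, torus-exact minimal-image for
  periodic ones); the two agree to near machine precision and an
  operation-count heuristic picks the cheaper one each step.
* **Vanishing fitness.** Cells with $f_i < 10^{-12}$ are treated as
  instantly extinct ($P_E = 1$) instead of evaluating $e/f_i$; this matters
  only when a niche has shifted essentially off the landscape.
* **Time step.** $\Delta t = 1$ yr for experiments (one 6 m shift per step);
  halving it changes long-run occupancies by well under 1% at the default
  rates. Oracle-style comparisons use $\Delta t = 0.1$.
* **Hypsographic bins.** Equal-width bins over the observed range,
  right-open with the last bin closed. On grids whose ring elevations fall
  exactly on bin edges, floating-point ties decide the bin; even grid sizes
  avoid such collisions.

## What the synthetic generators do and do not emulate

The geometric landscapes and OCNs reproduce the *area–elevation structure*
and (for OCNs) the aggregated, fragmented habitat of fluvially carved
topographies. They do not reproduce steep glacial slopes, aspect effects,
microclimate, land use, or any covariate other than elevation; fitness is a
single scalar field per cell by design (`run_occupancy()` accepts arbitrary
fitness matrices, so externally built suitability layers can be injected
without touching the machinery). Tests passing on these landscapes therefore
demonstrate the model's internal consistency and its response to controlled
geomorphology — not predictive skill on any real species.

## Problem sizes used by the test suite and acceptance script

Full-study settings (100×100 and larger grids, 4000-species pools, 100
replicates) are supported but deliberately scaled down in the shipped checks:
a 50×50 cone, a 150-species uniform random pool (large enough that regional
species occur on both sides of the hypsographic peak), 20 replicates, and
500-yr horizons; the null-warming control uses 24 species and 10 replicates;
OCN checks use a 64×64 lattice. These sizes keep the whole suite within
minutes while leaving every qualitative contrast (fate partition, nesting of
survivor sets, direction of the range-shift effect) intact.

## Known limitations

* Persistence on desk-scale grids is sensitive to the elevation gradient per
  cell: rescaling a 3000 m relief onto few cells makes niche bands thin and
  fragmented, and fewer species are viable than on fine grids with the same
  relief. Comparisons should therefore hold the grid size fixed.
* The equal-viability constraint equalizes the row-sum bound, not the
  capacity itself (see above).
* No demographic structure within cells, no multi-species interactions, no
  rescue effect on extinction rates, and no Gillespie-style continuous-time
  variant: the model is a synchronous chain, and results should be read at
  the $\Delta t$ resolution.
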