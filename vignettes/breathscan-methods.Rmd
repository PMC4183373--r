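---
title: "breathscan: model, numerics and analysis conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breathscan: model, numerics and analysis conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathscan)
```

# Overview

`breathscan` simulates the thermal "breathing" of double-stranded DNA — the
transient local opening of base pairs — together with a protein-like
particle that slides along the molecule and binds preferentially to open,
soft regions. Because promoter elements and transcription start sites (TSS)
tend to sit in A-T-rich, mechanically soft sequence, the stationary
statistics of this coupled system single out TSS-like positions from
sequence alone. The package turns raw promoter sequence into a ranked table
of candidate binding macrostates, each characterized by its occupancy
probability, its free energy relative to the pool of nonspecific sliding
states, and its conformational entropy.

The pipeline has five stages, each exposed as ordinary R functions and
orchestrated end to end by `analyze_promoter()`:

1. **Sequence encoding** (`encode_chain()`): each base pair becomes one
   lattice site classified A-T or G-C; stiff G-C clamps are appended at both
   ends to emulate the continuation of the molecule and suppress end fraying.
2. **Langevin dynamics** (`run_ensemble()`): the chain openings and the
   particle coordinate evolve under damped, thermally driven dynamics.
3. **Dimensional reduction** (`fit_pca()`, `project_trajectory()`): opening
   trajectories are compressed onto a few collective coordinates.
4. **Conformational Markov network** (`discretize_projection()`,
   `build_network()`): frames are discretized into microstates; observed
   transitions link them into a weighted network.
5. **Free-energy landscape** (`find_basins()`, `build_dendrogram()`,
   `cluster_macrostates()`, `promoter_report()`): the network is decomposed
   into basins of attraction, nonspecific basins are pooled, and kinetically
   connected basins are merged into macrostates that form the final report.

# The model

## Degrees of freedom and units

Site $n$ carries a single opening coordinate $y_n$ (Å), the transverse
stretch of the base pair relative to its closed equilibrium. The particle
carries a continuous position $x$ in units of the lattice spacing (base
pairs). Energies are in eV, masses in amu, distances in Å; the derived time
unit is $\mathrm{\mathring{A}}\sqrt{\mathrm{amu/eV}} \approx 10$ fs.
Boltzmann's constant is $k_B = 8.617\times10^{-5}$ eV/K, so the default bath
at $T = 290$ K has $k_B T \approx 0.025$ eV.

## On-site potential

Each site feels a Morse potential plus a Gaussian barrier,

$$V(y_n) = D_n\left(e^{-a_n y_n} - 1\right)^2 +
  G\,e^{-(y_n - y_0)^2 / (2 w^2)},$$

with depth $D_n$ and inverse width $a_n$ depending only on whether the pair
is A-T or G-C. The Morse term binds the pair and saturates at $D_n$ for
large opening; the barrier (height `G_bar` at position `b_pos`, width `b_w`)
models the solvent-stabilization of partly open states and makes opening an
activated, bubble-forming event rather than a smooth drift.

## Stacking

Adjacent sites couple through an anharmonic stacking term,

$$W(y_n, y_{n-1}) = \frac{k}{2}\,
  \bigl(1 + \rho\, e^{-\alpha (y_n + y_{n-1})}\bigr)\,(y_n - y_{n-1})^2 .$$

When both pairs are closed the effective elastic constant is $k(1+\rho)$;
once either pair opens it drops toward $k$. This entropic softening is what
lets openings organize into bubbles of cooperative, multi-site extent
instead of isolated single-site spikes.

## Particle coupling

The particle interacts with every site through a well whose depth grows
with the local opening and saturates:

$$V_p(x, \{y\}) = -A_p \sum_n \tanh\!\left(\frac{\max(y_n, 0)}{y_s}\right)
  e^{-(x - n)^2 / (2\sigma_p^2)} .$$

A closed chain exerts no force, so the particle diffuses freely along
closed DNA (nonspecific sliding). Wherever a bubble opens, a well of depth
up to $A_p$ per site appears; the particle can fall in, and — because the
force is reciprocal — its presence in turn stabilizes the bubble. This
two-way feedback is the detection mechanism: soft, A-T-rich stretches
nucleate bubbles more often, capture the particle for longer, and
accumulate occupancy. The Gaussian footprint $\sigma_p$ sets the protein
contact size; wells are evaluated within $\pm 6\sigma_p$ of the particle
(beyond that the weight is below $1.6\times10^{-8}$) and the particle
coordinate wraps periodically only for bookkeeping — wells are never
duplicated across the boundary.

## Default parameters

All defaults live in `model_params()` and print with units:

```{r}
model_params()
```

Rationale, briefly:

- `D_AT` = 0.05 eV and `D_GC` = 0.075 eV with `a_AT` = 4.2, `a_GC` = 6.9
  Å$^{-1}$ place the A-T pair dissociation scale at twice $k_BT$ and make
  G-C pairs both deeper and stiffer, so A-T tracts dominate breathing at
  290 K.
- `G_bar` = 0.03 eV, `b_pos` = 2 Å, `b_w` = 0.5 Å put an activation barrier
  of order $k_BT$ on the opening pathway, giving rare, long-lived bubbles
  rather than continuous flickering.
- `k_stack` = 0.025 eV/Å², `rho` = 2, `alpha` = 0.35 Å$^{-1}$ produce
  bubbles of roughly ten sites with openings that saturate at a few Å —
  the physical regime the model is intended to represent.
- `mass` = 300 amu is a nucleotide-scale inertial mass; with `gamma` = 0.05
  (inverse time units) the chain dynamics is moderately damped.
- `mass_p` = 1 amu gives the free particle a sliding diffusivity
  $D = k_BT/(m_p\gamma) = 0.5$ bp² per time unit, so a run of $10^5$ time
  units lets it explore several hundred base pairs — scanning must be
  faster than bubble turnover for site search to work at simulation scale.
- `A_p` = 0.03 eV and `sigma_p` = 5 bp are the coupling calibration
  described next.

## Calibrating the particle coupling

The coupling amplitude `A_p` controls the balance between sliding and
trapping, and the useful window is narrow. For a saturated bubble of width
$W$ the well depth is roughly $A_p \min(W, \sqrt{2\pi}\sigma_p)$, but the
*net* free energy of a bound state is much smaller because holding a
bubble open costs on-site and stacking energy; realistic specific-site
occupancies correspond to net binding of only a few $k_BT$.

We calibrated on synthetic 300-bp promoters (background A-T fraction 0.4)
carrying one 30-bp A-T-rich window, asking where the particle's visit
histogram peaks across independent master seeds:

- at $A_p \le 0.02$ eV the histogram is nearly flat — binding is too weak
  to beat free sliding, and the mode falls anywhere on the sequence;
- at $A_p \ge 0.04$ eV the particle falls irreversibly into the first
  short A-T cluster it meets and never equilibrates between competing
  sites within accessible run lengths;
- at $A_p = 0.03$ eV the mode lands in the planted soft window for most
  seeds, with residual failures caused by kinetic trapping at incidental
  background A-T runs.

The footprint discriminates between those competitors and a genuine soft
region: a bubble narrower than the footprint yields depth $\propto$ its
own width, while a wide soft window supports bubbles that fill the whole
footprint. Widening `sigma_p` from 3 to 5 bp (a protein contact of
~10-20 bp) roughly doubles the depth advantage of 30-bp soft windows over
the ≤6-bp background runs and made window recovery consistent.

Because individual trapping events remain sticky on desk-scale runs, the
recommended protocol averages many short realizations (each with an
independent random initial particle position) rather than one long run:
incidental traps differ from realization to realization while the soft
window is found repeatedly, so the pooled histogram concentrates there.
Both defaults were frozen after this calibration and are not adjusted per
analysis.

# Numerical integration

## Scheme

`langevin_run()` integrates the underdamped Langevin equation with a
splitting scheme: one classical fourth-order Runge-Kutta step of the
conservative dynamics, followed by an exact Ornstein-Uhlenbeck update of
every velocity,

$$v \leftarrow c_1 v + \sqrt{\tfrac{k_BT}{m}(1 - c_1^2)}\,\xi,
  \qquad c_1 = e^{-\gamma\, \Delta t},$$

with independent standard normals $\xi$ and per-mass constants for chain
sites and particle. Two properties follow by construction and are enforced
by tests:

- with the thermostat off ($\gamma = 0$, $T = 0$) the scheme is exactly
  classical RK4, so deterministic trajectories converge at fourth order;
- the velocity update alone samples the Maxwell distribution exactly for
  any $\Delta t$.

At the default $\Delta t = 0.5$ (≈ 5 fs) the fastest mode (a closed G-C
pair) is resolved by roughly 40 steps per period. Empirically the energy
drift of the conservative limit contracts by a factor of ~30 per halving of
$\Delta t$ — faster than the $2^4$ of the global error — because for
oscillatory dynamics the RK4 energy error is dissipative and scales as
$\mathcal{O}(\Delta t^5)$ per period; the tests assert the fourth-order
floor. An explicit Euler-Maruyama integrator (`method = "euler"`) is kept
as a slow cross-check oracle.

## Equilibrium checks and the reflecting wall

The Morse plateau is only $2\,k_BT$ above the minimum at 290 K, so a single
unconstrained pair escapes to $y \to \infty$ at finite rate and its
Boltzmann marginal is not normalizable. For single-pair equilibrium
validation a reflecting wall at $|y| = y_{\mathrm{wall}}$ (option `y_wall`)
truncates the domain; the empirical opening distribution then matches the
numerically integrated $e^{-V/k_BT}$ on the truncated domain to
Kolmogorov-Smirnov distance below 0.01. In multi-site chains the stacking
coupling and clamps regularize the problem and no wall is used.

## Seeding

`run_realization()` derives one sub-seed per realization from the master
seed with a Lehmer-style map, runs a short preheating stage to decorrelate
from the closed-chain initial condition, and draws the initial particle
position uniformly along the chain. Every run is wrapped in
`withr::with_seed()`, so the entire pipeline is reproducible from
`sim_config()$seed` alone.

# Analysis conventions

## PCA

The covariance is pooled over all frames of all realizations, over
non-clamp sites only. Eigenvector signs are fixed (largest-magnitude entry
positive) so downstream binning is deterministic. The particle coordinate
is never mixed into the covariance; it rides along as an extra reaction
coordinate.

For whole genes, `analyze_gene_chain_only()` runs the bare chain (coupling
forced off) and reports where leading eigenvectors localize via the
participation ratio $PR = 1/\sum_n v_n^4$ and per-region squared-amplitude
shares: the leading component captures molecule-wide collective breathing,
while localized components concentrate in soft promoter regions. This is
the justification for running the expensive coupled analysis on promoter
windows rather than whole genes.

## Microstates and network

Each sampled frame becomes a key `"s|b1,...,bk"`: the particle's nearest
site `s` (periodic wrap, 1-based) plus equal-width bin indices of the first
`n_pc` principal scores. Bin edges are pooled over all realizations; the
maximum falls in the top bin and out-of-range values clip into the end
bins. Transitions are counted between consecutive frames *within* a
realization only (no seams across runs); node weight is the visit fraction,
edge probabilities are normalized per source node.

## Basins, dendrogram, macrostates

Basins of attraction are found by deterministic steepest ascent: each node
follows its heaviest strictly-heavier neighbor (ties broken by
lexicographically smallest key) until reaching a local maximum, which
defines the basin's attractor. A seeded stochastic variant
(`method = "stochastic"`) is available as a cross-check. Basin free
energies are $F_b = -\ln(P_b / P_{\max})$ in $k_BT$.

Basins below the occupancy threshold `ns_threshold` are pooled into the
nonspecific state with total weight $P_{NS}$; reported free-energy
differences are $\Delta F = \ln(P / P_{NS})$.

Two analysis settings interact strongly with this construction and were
calibrated once on synthetic promoters, then frozen. First the network lag:
the sampling stride must keep consecutive frames spatially adjacent
(free-sliding displacement per frame well below the particle footprint),
otherwise frames "teleport" between distant traps and create spurious
direct links; with the default diffusivity, `sample_stride = 10`
($\sigma \approx 2$ bp per frame) satisfies this while `sample_stride =
50` does not. Second the nonspecific threshold: every binding basin is an
extended *capture* basin (the trap plus its sliding apron), so adjacent
basins always share direct links and merge at zero effective barrier —
macrostate boundaries can only appear where entire basins drop below
`ns_threshold`. The threshold therefore controls the nonspecific "moat"
between binding regions. Scanning it shows a stability plateau
(`ns_threshold` 0.02-0.03 for the protocols used here) where the heaviest
macrostate's entropy collapses from ~3 to ~1, its reported position
becomes threshold-independent, and $P_{NS}$ settles at a
majority-sliding background; analyses in the tests and README use 0.02.
Below the plateau the sliding apron keeps the landscape fully connected
and macrostates agglomerate distant traps.

The disconnectivity dendrogram is built by an ascending sweep over
inter-basin link barriers with union-find merging. Macrostates are cut from
it: two branches merge into one macrostate when the barrier between them,
measured from the deeper branch minimum, is below `barrier_cut` (default
$1\,k_BT$ — structure finer than thermal noise is not meaningful).
Each macrostate reports its total occupancy $P_\alpha$, its Shannon entropy
over member-basin weights, and the chain position of its deepest basin's
attractor, translated into promoter coordinates (negative upstream of the
coding-start anchor, no zero).

# Problem sizes and limitations

The package is routinely exercised at desk scale: chains of 300-500 bp,
ensembles of 2-5 realizations of $10^5$ time units, which complete in
minutes on one core. Biological-scale inference (multi-kilobase promoters,
$5\times10^6$ time-unit ensembles, replicate landscapes) uses the same code
paths but cluster-scale compute; nothing in the implementation assumes the
small sizes.

Known limitations:

- The model is mesoscopic: one coordinate per base pair, no helicity,
  sequence enters only through the A-T/G-C dichotomy. Positions are
  resolved to a few base pairs at best.
- Stationary occupancies require the particle to equilibrate between
  competing soft regions; at strong coupling or short runs the landscape
  reflects kinetic trapping. Compare several master seeds before trusting
  a ranking.
- At desk-scale run lengths the dominant noise source is not particle
  trapping (escape times from incidental traps are ~10^3 time units,
  far below a realization) but long-lived bubbles at background A-T
  clusters, whose lifetimes are comparable to a whole realization. Their
  occupancy contributions therefore fluctuate at the realization level,
  and fine-grained statistics such as the per-base-pair histogram argmax
  can sit within ~1-2 sigma of a competing site; adding realizations
  redraws rather than converges such ties. Region-level masses (e.g. the
  total visit share of a 30-bp window) are far more stable and are the
  recommended decision statistic at desk scale; production-scale
  ensembles (~5x10^6 time units) average over bubble lifetimes.
- The equal-width binning of principal scores is simple and deterministic
  but not adaptive; very anharmonic landscapes may need more bins
  (`n_bins`) or components (`n_pc`).
- Chain-only PCA never produces a chain-spanning ("delocalized") first
  component. Opening variance is dominated by nonlinear bubble events
  whose spatial correlation length is the bubble width (~10 bp, set by
  the short-ranged stacking), so the pooled covariance is
  block-localized and every leading eigenvector is supported on one soft
  cluster (participation ratio ~5-10 regardless of sequence composition,
  decreasing with more sampling). The localization *contrast* between
  soft and stiff regions — the property `analyze_gene_chain_only()`
  reports — is robust; a molecule-wide collective breathing mode is not
  part of this Hamiltonian's equilibrium fluctuations.
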