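---
title: "Kinetic transition networks for antenna energy transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic transition networks for antenna energy transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonet)
```

## The model

`excitonet` analyses excitation energy transfer (EET) as a continuous-time
Markov chain over exciton states. The central object, `kinetic_network`,
stores the full master-equation generator: off-diagonal entry `(i, j)` is
the rate `k(i -> j)` in ps^-1 from row-state to column-state (this
orientation is fixed and validated everywhere, since the opposite
convention is equally common), and the diagonal is minus the row sum.
Time is picoseconds throughout, matching the natural EET timescales
(sub-ps intra-domain hops to multi-hundred-ps peripheral excursions).
Reaction-centre charge-transfer states are absorbing: charge separation is
taken to be effectively instantaneous, so a trap state has zero outgoing
rate by contract.

States carry metadata — subunit, monomer, domain, optional site energy,
trap flag — because every analysis stage aggregates over it: initial
conditions are "an excitation in CP43", dwell profiles are per subunit and
monomer, knockouts delete subunit instances. Energies are expressed in
units of kT; the default `kT = 1` therefore corresponds to whatever
temperature the rates were computed at (about 207 cm^-1 at 298 K), and
changing `kT` rescales Boltzmann weighting consistently. State indices in
the R API are 1-based, the native R convention; files identify states by
label, never by index, so no off-by-one ambiguity can cross the I/O
boundary.

### Equilibrium and validation

The equilibrium distribution is defined on the trap-free transient
subnetwork (the absorbing chain itself has no non-trivial stationary state)
as the null vector of the transposed generator, computed by replacing one
balance equation with the normalisation constraint — a dense solve that is
exact to machine precision at these sizes (tens to low hundreds of
states). It requires the transient subnetwork to be strongly connected;
a disconnected network is an error that reports the components rather than
silently returning one of many stationary states.

`validate_network()` is purely diagnostic: generator row sums, negative
rates, weak connectivity, trap reachability, and the detailed-balance
residual `max |pi_i k(i->j) - pi_j k(j->i)| / max(flux)`. The residual is
advisory rather than fatal because rate matrices averaged over
inhomogeneous realisations violate detailed balance mildly; the
free-energy translation (below) handles that case explicitly.

## First-passage-time machinery

For a target set (both RC charge-transfer states, typically),
`make_absorbing()` restricts the generator to the transient states. The
FPT density from an initial distribution `p0` is

    f(t) = p0' exp(T t) r,   r = flux into targets,

assembled spectrally as `f(t) = sum_k c_k exp(lambda_k t)` with
`c_k = (p0' V)_k (V^-1 r)_k` from the eigendecomposition `T = V L V^-1`.
Moments follow without any grid: the n-th raw moment is
`n! sum_k c_k / (-lambda_k)^(n+1)`.

Numerical choices:

- **Defective generators.** Irreversible chains with equal rates (the
  `chain3` fixture: two eigenvalues at -1) have no eigenbasis. We estimate
  the conditioning of the eigenvector matrix (`1 / (||V|| ||V^-1||)` in the
  infinity norm) and below `1e-12` fall back to a dense
  scaling-and-squaring matrix exponential for the density and to repeated
  linear solves for moments. The fallback is exact for the density at grid
  points, just slower.
- **Complex eigenpairs.** Conjugate pairs (possible when detailed balance
  is broken) combine analytically to a real density; a residual imaginary
  part above `1e-8` of the density scale is raised as an error, never
  silently dropped.
- **Unreachable targets.** If part of the state space cannot reach the
  targets, the naive solve is singular. The solver restricts itself to the
  states that can reach the targets (backward reachability) and assigns
  absorption probability zero elsewhere, so "MFPT = Inf with absorption
  probability 0" is an explicit, well-defined outcome rather than an
  overflow.
- **Competing traps.** When other absorbing states exist (a quencher
  sink), the reported MFPT is conditional on absorption in the targets and
  the absorption probability is reported alongside — this matches the
  convention of normalising the FPT distribution to unit integrated
  probability.
- **Two independent algorithms.** `mfpt(method = "linear_solve")` solves
  `(-T) m = 1` (the absorbing-Markov-chain route) with an LU
  factorisation; `method = "spectral"` uses the eigenpairs. They share no
  code path and are asserted to agree to 1e-8 relative in the tests, which
  guards both implementations at once.
- **Time grid.** Log-spaced, default `1e-2` to `1e4` ps with 400 points —
  wide enough to cover sub-ps direct core-to-RC transfer and the slowest
  peripheral detours of the synthetic networks.
- **Initial conditions.** "Excitation in subunit X" defaults to Boltzmann
  weights over X's transient states at the configured kT (uniform and
  point-mass alternatives are available). The choice matters little on a
  flat landscape but is always explicit in the API, since the convention
  used for intra-subunit relaxation is a genuine modelling degree of
  freedom.

## Kinetic Monte Carlo

The kMC engine is rejection-free (Gillespie/BKL): exponential waiting time
with the state's total escape rate, successor proportional to outgoing
rates. The inner loop is C++ (Rcpp). Each trajectory owns an `mt19937_64`
stream seeded by a splitmix64 hash of `(master seed, trajectory index)`,
and uniforms/exponentials are produced by inverse transform rather than
`std::` distributions — so a trajectory is reproducible independently of
execution order and platform, and a single trajectory re-simulated with
`simulate_trajectory(seed, traj_index)` is bit-identical to the same
trajectory inside a batch. No tau-leaping or rare-event acceleration is
used: the networks are small and have no rare events, so exact stepping at
10^5 trajectories costs only seconds.

Censoring: trajectories exceeding `max_time` (default 10^6 ps, i.e.
effectively never on these networks) are flagged and excluded from FPT
statistics but counted. Dwell times are accumulated per
subunit-instance (or per state on request) inside the C++ loop, so the
dwell of every complete waiting interval is assigned exactly once; the
per-trajectory dwell row sums to the trajectory's FPT by construction,
which is the conservation property the dwell-profile tests assert to
1e-9 relative.

## Dwell-time profiles

`dwell_profile()` implements the trajectory-ensemble average of integrated
residence time per subunit over a closed FPT window
`[t_lo, t_hi]` (boundary ties included — the window convention must be
fixed somewhere, and closed bounds make the "window covering everything"
limit exact). Multiple visits to a subunit accumulate within a trajectory
before averaging. The preset windows (13.5-23.5, 50-90, 155-255 ps) are
the canonical short/medium/long trajectory classes for core-antenna
excitations; a 50-95 ps variant of the middle window is also provided
because both forms are quoted in the literature for the same analysis, and
we expose rather than resolve the discrepancy. Profiles report the two
monomers separately.

## Perturbation experiments

- **Knockouts** are hard deletions: all states of the named subunit
  instances are removed, rows and columns dropped, and surviving rates are
  bitwise-untouched (no renormalisation). This is the "delete the
  corresponding sites" convention; soft decoupling would answer a
  different question.
- **Quenchers** are phenomenological: one absorbing sink per monomer
  represented in the host set, fed at `k_capture` from each host state.
  There is no canonical `k_capture` — the mechanistic literature spans
  wide ranges — so it is a required argument and embedded in every output.
  Which chlorophylls within a subunit couple to the quencher is likewise
  exposed as an explicit host-state input rather than guessed.
- **Committors** (`first_hit_probability`) solve the boundary-value
  problem on the transient generator (1 on A, 0 on B and on any competing
  trap). The committor is harmonic with respect to the jump chain and is
  verified as such (fixed-point residual < 1e-10), and against kMC hit
  fractions. `quench_map()` assembles the placement-by-initial-subunit
  table of P(quencher before either RC); when two placements' host
  chlorophylls share a fast-equilibrating domain, their columns coincide —
  the generator can construct such shared-domain pairs on demand to test
  exactly this equivalence.

## Free-energy landscape and disconnectivity graphs

Although EET rates are not barrier-determined, the network can be
visualised exactly as a free-energy landscape. State free energies
reproduce the equilibrium occupations, `F_i = -kT log(pi_i)` (minimum
shifted to zero); transition-state free energies reproduce the rates,
`F_ts(i, j) = F_i + kT log(nu / k(i->j))`. Under detailed balance the two
directions agree identically; for averaged matrices the stored value is
their mean, with the maximum disagreement reported as
`asymmetry_residual` and an optional strict mode that fails above a
threshold. The prefactor `nu` (default 1 ps^-1) shifts all transition
states uniformly and cancels exactly in the round trip
`k = nu exp(-(F_ts - F_i)/kT)`, which the tests require to be the identity
to 1e-12 relative — the "faithfully reproduces the rates and equilibrium"
contract that makes the picture quantitative rather than decorative.

The disconnectivity tree sweeps a threshold upward over a level grid
(default 60 levels spanning `[min F_state, max F_ts]`) and merges
components by union-find over edges with `F_ts <=` threshold; a transition
state falling exactly on a level merges at that level. Merge heights are
therefore minimax path barriers quantised to the grid, and the resulting
merge structure is ultrametric (asserted on random leaf triples). Leaves
can be annotated with single-state MFPTs to the RCs (one linear solve for
all leaves). Trees export to Newick via `ape` and to the two-file
minima/transition-state convention of standard disconnectivity plotting
tools.

## The synthetic generator: what it does and does not emulate

`psii_network()` generates the study conditions for every test in this
package, since the microscopic rate matrix of a real supercomplex is the
product of an elaborate upstream pipeline (structure-based couplings,
modified Redfield / generalized Förster rates, disorder averaging) that is
out of scope here. The generator emulates the end product's statistical
structure:

- **Topology**: two mirror monomers, each with RC, CP43, CP47, CP26,
  CP29, CP24 and the S-/M-LHCII trimers; adjacency per the supercomplex
  contact map (CP43-RC, CP43-CP26, CP43-S-C, CP26-S-A, the S and M trimer
  rings, S-B-M-A, M-C-CP29, CP24-CP29, CP29-CP47, CP47-RC) plus the two
  inter-monomer contacts (CP47-CP47', S-C-CP29').
- **Flat landscape**: subunit base energies uniform over
  `landscape_span = 1` kT, small intra-subunit spread, then Gaussian
  static disorder (`energy_disorder_sigma = 0.3` kT) applied after
  mirroring monomer 1 into monomer 2. The disorder default is a
  placeholder of realistic order for chlorophyll-protein inhomogeneous
  broadening relative to kT; the true widths are protein-specific.
- **Timescale separation**: rates follow a barrier model
  `k(i->j) = nu exp(-(B_ij - E_i)/kT)` with a symmetric random barrier
  `B_ij >= max(E_i, E_j)`, giving detailed balance exactly by
  construction. The prefactor is `intra_rate = 10` ps^-1 within a domain
  (~100 fs local equilibration) and `inter_rate = 0.2` ps^-1 between
  domains (~5 ps hops), an order-of-magnitude-realistic fast/slow split.
  Barrier excesses are drawn once per mirror-equivalence class of pairs,
  so at zero disorder the dimer symmetry is exact, not approximate.
- **Traps**: one absorbing charge-transfer state per RC, fed only from
  that RC's lowest exciton state at `trap_rate = 2` ps^-1.

With the defaults (3 states per subunit: 72 transient + 2 trap states) the
generated networks reproduce the qualitative signatures the analysis is
designed around: FPT distributions spanning over two orders of magnitude,
core-antenna MFPTs shorter than peripheral ones, short-FPT dwell confined
to the starting monomer, and knockouts of core-adjacent minor antennae
shortening the transfer.

What passing tests on these networks **does not** show: quantitative
agreement with any real supercomplex (the generator makes no attempt to
fit measured rate constants or reproduce published MFPT values — analysing
a deposited rate matrix is a matter of `read_network()` on its files);
non-Markovian or coherent transfer effects; exciton-exciton annihilation;
and any structural realism below the subunit contact map.

## Problem sizes and reproducibility

The test suite and the acceptance script run the analytic/stochastic
cross-checks at 10^5 kMC trajectories on the default 74-state network
(KS distance ~0.002, well inside the asserted 0.01), committor checks at
10^5 trajectories, and occupancy recovery at 150-200 trajectories of
1500 ps on a trapless 50-state variant — sizes chosen so the whole suite
completes in well under a minute on one CPU while leaving the Monte Carlo
errors far below the asserted tolerances. Every stochastic entry point
takes an explicit integer seed, and the per-trajectory stream design makes
results independent of execution order.

## Known limitations

- Dense linear algebra throughout: appropriate to hundreds of states, not
  to the 10^5-state networks of molecular energy landscapes (for which
  graph-transformation methods exist).
- The free-energy translation requires two-way edges among transient
  states; genuinely irreversible transitions (other than into traps) have
  no finite transition-state free energy.
- The committor solver assumes the absorbing sets are honest absorbing
  states of the chain; time-dependent (switching) quenchers are out of
  scope.
- `run_command()`/the CLI wrapper cover the standard pipelines; anything
  bespoke is expected to go through the R API.
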