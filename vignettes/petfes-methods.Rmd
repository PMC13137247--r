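---
title: "Coarse-grained free-energy methods for PET conformational polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained free-energy methods for PET conformational polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petfes)
```

## The scientific problem

Polyethylene terephthalate (PET) is degraded enzymatically only where its
chains are conformationally accessible. Amorphous PET is a mixture of
*gauche* (g) and *trans* (t) conformers of the ethylene-glycol (EG) torsion
Psi (the OC--CO dihedral), with an experimental g:t ratio of 91:9 at 30 C;
crystalline PET is fully trans, packs tightly, and is almost inert to
PET-hydrolysing enzymes. Two thermodynamic consequences follow: a
crystalline substrate pays a free-energy penalty to populate catalytically
competent enzyme--substrate geometries, and detaching a chain from a
crystalline surface costs substantially more work than detaching it from an
amorphous one.

`petfes` implements, at desk scale, the machinery needed to study this
picture quantitatively: a coarse-grained (CG) torsional model of a PET
tetramer whose g/t equilibrium is steered by distance restraints,
well-tempered metadynamics (wt-MTD) and Hamiltonian replica-exchange
(solute-tempering) engines written from scratch, reweighted free-energy
surface (FES) analysis with block errors and bound/unbound state
integration, and the closed-form bookkeeping that converts simulation
outputs to standard-state and per-monomer quantities. Atomistic systems,
explicit water and the enzyme itself are out of scope; the analysis layer
nevertheless reads trajectories carrying the atomistic CV names
(`d0`, `h0`, `h1`, `s0`, `chi2`, `d_COM`) so the same machinery applies to
deposited atomistic data.

## The coarse-grained tetramer

The chain has three beads per repeat unit plus one terminal bead
(13 beads, 12 bonds for the tetramer). Bond lengths and angles are rigid;
the only degrees of freedom are one Psi torsion per repeat unit, placed on
bonds {3, 6, 7, 10} so the set is symmetric under chain reversal. All other
dihedrals are frozen trans. Two bond angles are used: 114 degrees along the
backbone and 90 degrees at the glycol beads flanking each Psi bond, so that
a gauche torsion kinks the chain decisively.

The terminal beads mark the terminal carbonyl carbons; their distance is
the collective variable d1. The bond length is calibrated so the fully
extended chain spans `n_units * all_trans_repeat_length` = 4.10 nm.
This taut length is deliberately just above the 4.0 nm crystalline-state
restraint. The choice matters: with a generous margin (for instance a span
of 4.36 nm) a single gauche kink can be re-absorbed by small trans-basin
adjustments of the other torsions -- a crankshaft-like compensation that
keeps d1 above 4.0 nm at almost no energetic cost, leaving 10--15% spurious
gauche under the crystalline restraint. With the taut-span geometry the
4.0 nm lower wall (k = 1500 kJ mol^-1 nm^-2, the published force constant)
pulls the chain tight and the trans fraction exceeds 99.9%, the mechanism
the corresponding atomistic restraint exploits. Enumerating all 3^4
discrete torsion states confirms the geometric exclusion: every state
containing at least one gauche torsion has d1 < 3.5 nm.

```{r geometry}
g <- chain_geometry()
g
e <- petfes:::enumerate_d1(g)
tapply(e$d1, e$n_gauche, range)
```

The geometry constants (span 4.10 nm, angles 114/90 degrees) were fixed by
a design-time scan against the two target behaviours of the restrained
chain -- about 9:1 g:t under a 2.4 nm lower wall, essentially 100% trans
under a 4.0 nm wall -- and are not meant to be tuned per analysis.

## The torsion potential

Psi moves on a 360-degree-periodic four-term cosine series with minima at
180 degrees (trans) and +/-70 degrees (gauche, degeneracy 2), a tunable
gauche--trans gap `gt_gap`, and a tunable barrier (default 20 kJ/mol above
the trans minimum). Three cosine terms are not enough: with the three
minima pinned, the barrier of a three-term series is an algebraic function
of the gap (a gap of -4 kJ/mol forces a barrier under 0.3 kJ/mol). With
four terms and a fixed barrier position the coefficients satisfy four
linear conditions -- stationarity at 70 degrees and at the barrier top, the
gap, and the barrier height -- and are solved exactly; the barrier position
is chosen by scanning for the admissible shape (exactly three minima)
closest to 114 degrees. The barrier default of 20 kJ/mol keeps the basins
sharply separated so that the +/-120-degree classification boundary carries
negligible population; because the Monte Carlo proposals are uniform on the
circle, barrier height has no effect on mixing.

Gauche conformers are defined as -120 < Psi < 120 degrees (boundary
classified trans), which partitions the circle exactly.

## Calibration of the gauche--trans gap

For two states with gauche degeneracy 2, matching a target split
(p_g, p_t) gives the closed form `gt_gap = -kB T log(p_g / (2 p_t))`,
about -4.09 kJ/mol for 91:9 at 303.15 K. The sampled chain needs a deeper
gap (about -6.9 kJ/mol) because the gauche wells are narrower than the
trans well; the two-state formula ignores this entropic asymmetry.
`calibrate_gt_gap()` therefore bisects the gap against the seeded sampler
(the closed form is the initialization), or, since the unrestrained
torsions are independent, against the exact single-torsion Boltzmann
integral (`method = "quadrature"`, deterministic; used as the independent
oracle in the tests). Calibration uses 303.15 K, the temperature of the
experimental reference ratio; all other CG sampling runs at 300 K.

```{r calibration}
gap <- calibrate_gt_gap(c(0.91, 0.09), method = "quadrature")
as.numeric(gap)
```

## Monte Carlo sampling

`sample_chain()` performs Metropolis Monte Carlo in torsion space: one
sweep redraws each Psi once, uniformly on the circle, rotating the
downstream arm rigidly (a pivot move). The energy is the torsion series
(scaled by lambda in solute-tempering replicas) plus the unscaled d1 wall
and any metadynamics bias. Uniform proposals make the move set ergodic for
any finite barrier; an acceptance watchdog still aborts if the chain stops
moving. Every source of randomness flows from an explicit seed, and the
compiled sampler draws from R's RNG stream, so runs are exactly
reproducible.

## Well-tempered metadynamics

The bias is a sum of repulsive Gaussians deposited every `pace` sweeps
with the well-tempered damping rule
`w = w0 * exp(-V(s) / (kB (gamma - 1) T))`; defaults follow the published
settings (w0 = 0.5 kJ/mol, sigma = 0.05 nm, gamma = 15). Deposit heights
are computed from the exact kernel sum; for the per-step energy the
compiled samplers additionally cache the bias on a uniform grid
(2048 nodes) with linear interpolation, the standard engine optimization.
Kernels are never dropped or merged. Wall potentials remain part of the
unscaled Hamiltonian in every replica.

Free energies are recovered by final-bias (umbrella-like) reweighting:
frame i receives weight proportional to `exp(+V_final(s_i) / kB T)` with
the fully deposited bias evaluated at the frame's biased CVs. The variant
of metadynamics reweighting is a genuinely open choice; the final-bias
estimator was selected for its simplicity and because its residual error
is dominated by the early, far-from-stationary deposits, which are handled
by discarding a transient fraction of frames (default 20% in the
detachment workflow; the `frame_weights()` default is 0 so that the
estimator itself stays assumption-free). On the analytic double well the
reconstruction agrees with the potential to well under 1 kJ/mol RMSE over
the basins.

## Solute tempering (HREX)

The replica ladder is geometric, `lambda_i = lambda_min^((i-1)/(n-1))`;
`lambda_min = 0.426934` reproduces the published eight-replica ladder to
six decimals (the rounded 0.43 does not). In the CG model there is no
solvent, so the REST2 prescription of scaling charges, Lennard-Jones
epsilons and proper dihedrals reduces to scaling the torsion series (and,
for the toy system, its polynomial) linearly by lambda -- a documented
deviation from atomistic REST2, where solute--solvent cross terms scale as
sqrt(lambda). Walls and geometry are never scaled. Each replica carries
its own wt-MTD bias with Gaussian height `w0 / lambda`, so the flattened
minima of hot replicas fill at a matched rate.

Coordinate swaps between nearest-neighbour rungs are attempted at a fixed
sweep interval, alternating even/odd pairs (the pairing scheme is not
specified by the published setup; coordinate and lambda swaps are
statistically equivalent and coordinate swaps were chosen). The Metropolis
factor uses the full replica energies, including each replica's own bias
evaluated on both configurations. Analysis statistics come from the
unscaled lambda = 1 replica only; no multi-state (MBAR-style) reweighting
across the ladder is attempted. Exchange acceptance is logged but not
asserted against the published atomistic range (39--48%), which has no CG
equivalent.

## FES analysis, block errors and state integration

`make_fes()` converts weighted histograms to free energies,
`F = -kB T log(p)`, shifting the minimum over occupied bins to zero and
flagging empty bins as missing rather than zero. Binning defaults to 100
bins over the observed range and is declared in the pipeline
configuration, not hard-coded. Errors come from block analysis: the
trajectory is cut into contiguous equal blocks (default 5; remainder
frames join the last), each block yields a normalized probability profile,
and the standard error of the mean probability propagates to
`sigma_F = kB T * SE(p) / mean(p)`. On independent frames this matches a
bootstrap within its estimator noise; because weights are renormalized
within blocks, the errors are invariant to a constant shift of the bias.

Bound and unbound states are defined by a threshold on one CV (default
3 nm, frames at the threshold counting as bound), and
`state_delta_f()` integrates the Boltzmann-weighted populations:
`dF = -kB T log(P_bound / P_unbound)`, antisymmetric under swapping the
regions. `convergence_series()` recomputes dF on growing prefixes;
`delta_delta_f()` forms the aPET-vs-cPET style difference with errors in
quadrature, reported with the sign convention that a positive value means
the first system costs more to detach.

## Thermodynamic bookkeeping

All bookkeeping runs at 298.15 K by default (the published depletion
factor is insensitive to 298 vs 300 K at the quoted precision) with
`V_standard = 1.66054` nm^3 per molecule (1 mol/L):

* standard-state correction `-kB T log(V_box / V0)`: -17.2 kJ/mol for a
  12 nm cubic box;
* standard unbinding `-(dF_box + correction)`: 77.2 and 42.2 kJ/mol from
  box values of -60 and -25 kJ/mol, i.e. 19.3 and 10.6 kJ/mol per monomer
  of a tetramer;
* population depletion `exp(dF / kB T)`: a 25 kJ/mol penalty depletes
  the catalytically competent ensemble about 2.4e4-fold;
* fold-surface conversion `2 sigma_e A_chain N_A`: 25.5 kJ/mol per repeat
  unit from sigma_e = 0.106 J/m^2 and A_chain = 0.20 nm^2.

```{r thermo}
standard_state_correction(12^3)
standard_unbinding(c(-60, -25), 12^3)
population_depletion_factor(25)
fold_surface_cost()
```

## Synthetic data: what it does and does not emulate

The fixture generators produce data whose answers are known exactly:
two-state Boltzmann torsion labels with tunable gap, i.i.d. samples from
the quartic double well, and a two-basin d_COM mixture with prescribed
bound/unbound dF. Together with the CG chain they emulate the
*statistical* structure the analysis assumes -- Boltzmann-distributed
torsion populations, deposited bias histories, two-state CV distributions
-- but none of the physics the published atomistic systems contain: no
solvent, no enzyme, no interchain packing, no kinetics on a physical time
axis (the samplers have no time scale; deposit paces and exchange
intervals are in sweeps). Passing tests therefore certify the estimators
and engines, not the atomistic free-energy values, whose published numbers
enter only as inputs to the bookkeeping layer.

## Numerical choices and problem sizes

Units are kJ/mol, nm, degrees and Kelvin throughout, with
kB = 0.0083144621 kJ mol^-1 K^-1. Degenerate inputs fail loudly:
empty trajectories, empty partition regions, zero total weight,
non-finite CVs, ragged table rows (with line numbers) are all distinct
errors. Ties at the classification boundary go to trans; frames at the
partition threshold count as bound.

The validation suite sizes were chosen to keep every stochastic check
comfortably inside its tolerance on one CPU: 1e5-sweep chain runs for the
restrained-equilibrium checks, a 2e6-step double-well run for the wt-MTD
reconstruction (at 1e6 steps the RMSE fluctuates around the 1 kJ/mol
bound), 2e5-sample reweighting oracles, and 50-block/200-replicate
block-vs-bootstrap comparisons (per-bin ratios carry about 10% estimator
noise, so agreement is asserted on the aggregate level).

## Known limitations

* The CG chain has no excluded volume and no interchain interactions; d1
  is a plain Euclidean distance without periodic images.
* The trans-shoulder region (|Psi| between about 110 and 120 degrees) is
  gauche by the classification rule but conformationally trans-like; at
  the crystalline restraint it contributes the residual <0.1% gauche.
* Final-bias reweighting carries a transient-dependent systematic that the
  transient-discard parameter controls but does not eliminate.
* The detachment workflow reinterprets d1 as the unbinding coordinate of a
  single chain; it exercises the full bound/unbound machinery but is not a
  two-oligomer model.
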