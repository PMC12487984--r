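---
title: "Methods: bottom-up coarse-grained lipid force fields by variational force matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up coarse-grained lipid force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cglipid)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the method leaves them open. All quantities are in the package unit system:
Angstrom, femtosecond, amu, kcal/mol (`cg_units()`).

## The coarse-grained model and its mapping

Each lipid is represented by six beads: a headgroup bead (HG; phosphate plus
choline or serine), a middle bead (MG; glycerol plus esters) and two beads
per acyl tail (T1 = first half, T2 = second half), bonded as HG–MG, MG–T1,
T1–T2 for each tail — five bonds per lipid. A bead sits at the center of
mass of its atom group (`map_coordinates()`). Because the groups are
disjoint and the map is a mass-weighted mean, the consistent force mapping
is the plain *sum* of atomic forces per group (`map_forces()`): this is the
unique linear mapping for which the total force is conserved exactly, and
the package asserts that conservation to machine precision on every fixture
frame. A mass-fraction-weighted alternative exists in the literature for
overlapping groups; with disjoint groups it is not needed, and the sum was
chosen.

Two conventions are fixed package-wide because downstream indexing depends
on them: beads are ordered (lipid index, then scheme bead order), and atoms
of a group are unwrapped relative to the group's first atom by the
minimum-image convention before averaging, so lipids straddling the
periodic boundary map correctly.

## Variational force matching with a prior

The CG potential is fitted by minimizing the force-matching functional: the
mean over frames of `1/(3N) * sum_I |F_I(mapped) - F_I(model)|^2`, where
`F(model) = -grad U`. Fitting the *total* potential this way is poorly
conditioned — the model would have to learn the steep repulsive core and
bond restoring forces from data alone, and early training would visit
unphysical configurations. The package therefore trains on **delta forces**:
a physics-based prior is parametrized first, its forces are subtracted from
the mapped forces, and the trainable model only represents the residual.
The production force field is always prior + model (`total_force_field()`).

### The prior

*Bonds* are harmonic in the convention `V(r) = k (r - r0)^2 + V0` (the
spring constant absorbs the usual 1/2; `V0` is a base offset that never
affects forces). They are parametrized by Boltzmann inversion with a radial
Jacobian correction: the observed bond-length samples are reweighted by
`1/r^2` so that the inverted potential refers to `p(r)/r^2`, which is the
distribution a harmonic bond actually generates along the bond coordinate.
The harmonic parameters then follow by moment matching — `r0` is the
(weighted) mean and `k = kB*T / (2 sigma^2)` — which is exact for the
Gaussian implied by the harmonic form, bin-free, and unbiased, unlike a
histogram least-squares fit. The Jacobian correction is a package choice
(`jacobian = TRUE` in `fit_bond_prior()`), flagged configurable because
either convention appears in practice.

One caveat the closed-loop tests quantify: Boltzmann inversion acts on the
*marginal* bond-length distribution of the interacting system, not on an
isolated bond. For bonds whose length correlates with the nonbonded
environment — in practice the tail T1–T2 bond, broadened by tail–tail
cohesion — the inverted `k` is systematically softened by a few percent.
This is the same physics that makes the T1–T2 distribution non-Gaussian in
real lipids and motivates the B-spline bonded term below; the delta-force
model absorbs the residual either way.

*Repulsion* is `V(r) = 4 eps r^-6 + V0`, the repulsive half of a
Lennard-Jones-style potential. `fit_repulsive_prior()` least-squares fits
`4 eps r^-6` to the pair potential of mean force `-kB*T*log g(r)` over a fit
range covering only the rising wall — by default from the smallest observed
distance to where the shell-normalized histogram first reaches its plateau —
because the `r^-6` form is only meant to model the core, not the liquid
structure beyond it. `eps` is clipped at zero if a sparse pair turns the fit
attractive. Directly bonded (1–2) pairs are excluded from the repulsion;
1–3 pairs are kept, because the prior is deliberately minimal and the
trained model can reshape 1–3 correlations. Below a guard distance of
0.5 A the diverging `r^-7` force is capped (linear energy continuation) so
that a rare overlap during early training cannot produce astronomically
large delta forces. There is no electrostatic prior: the model family is
solvent-free and charge-free.

*B-spline bonded alternative.* `fit_spline_bond()` fits a cubic B-spline to
the Jacobian-corrected bond PMF on a histogram, for bond types whose
distribution is bimodal (two tail rotamer populations) and therefore
misrepresented by a harmonic. Empty interior bins are dropped from the fit
(the spline interpolates across them) with a warning; outside the knot
range the potential continues linearly with the boundary slope, a C1
extrapolation guard that keeps forces finite without inventing curvature.

## Trainable potentials

Both implementations satisfy one contract: a single scalar energy per
frame, forces equal to the exact negative coordinate gradient, translation
invariance, and invariance under permutation of identical-type beads (both
depend on coordinates only through minimum-image pair distances).

### Graph message-passing potential

The many-body model is a continuous-filter graph convolution network written
directly in R with hand-derived gradients. Per frame: each bead gets a type
embedding; edges are bead pairs within the cutoff; each of `n_layers`
interaction layers filters neighbor features through a learned function of
the edge distance (Gaussian radial basis expansion, two dense layers with
shifted-softplus activations, multiplied by a smooth cosine cutoff
envelope) and adds the aggregated message back residually; an MLP head
contracts node features to per-bead energies summed to `E`. The cosine
envelope makes `E` (and hence the forces a Langevin integrator consumes)
continuous as neighbors cross the cutoff.

Defaults (`graph_config()`): 4 interaction layers, embedding width 128,
18 radial bases, cutoff 12 A, head width 64 — all configurable; the tests
use smaller instances of the same architecture. Parameter initialization is
deterministic from a recorded seed, with the last head layer started near
zero so an untrained model perturbs the prior only weakly; seeds are
first-class because seed-to-seed variability is part of how such models are
assessed.

Three differentiation passes are implemented by hand and validated against
central finite differences in the test suite: the forward pass; reverse
mode for `dE/d(distance)` (exact forces); and a forward-over-reverse pass
for the parameter gradient of the force-matching loss, which requires
`d(forces)/d(parameters)` — the loss differentiates through the force
computation itself.

### Pairwise B-spline baseline

The classical tabulated-potential alternative: per unordered type pair, a
cubic B-spline on `[0, cutoff]` multiplied by the same cosine envelope, so
the potential and its first derivative vanish smoothly at the cutoff. The
energy is linear in the coefficients, which makes force matching a
well-conditioned linear problem and makes this model the natural
*closed-loop* recovery target (below). Its limitation is the point of the
graph model: it cannot represent many-body packing effects, which is
visible in the worked example as an underestimated tail order parameter at
matched pair structure.

## Training

`train_potential()` minimizes the empirical force-matching loss with Adam
on mini-batches of frames, an initial learning rate of 5e-3 halved on
validation plateaus, and early stopping; the best-validation parameters are
retained. The ensemble average in the functional is implemented as the
per-frame mean of `1/(3N) sum |.|^2`, averaged over frames — the per-frame
normalization keeps the loss comparable across system sizes. The validation
split is 10% of frames under a seeded shuffle; two runs with identical
seeds produce bitwise-identical loss histories (asserted in the tests).
Checkpoints serialize parameters as full-precision decimal strings so a
save/load round trip is bit-stable.

## Langevin simulator

`run_simulation()` integrates underdamped Langevin dynamics under NVT with
the BAOAB splitting, chosen for its accurate configurational sampling at
large time steps — relevant because smooth trained potentials are typically
run at 20 fs, while 1 fs is the conservative default. Defaults: 300 K,
damping 0.1 ps^-1. In the zero-temperature, zero-friction limit the step
reduces to velocity Verlet (the tests verify energy conservation there),
and the thermostat is validated against the analytic Boltzmann bond-length
distribution of a harmonic dimer (two-sided Kolmogorov–Smirnov at the 1%
level, n = 1e4) and the Einstein relation `D = kB*T/(m*gamma)` for free
particles. Initial velocities are Maxwell–Boltzmann at the set temperature
under the run seed. Center-of-mass motion is not removed by default
(Langevin noise is per-bead and the stationary distribution does not
require it); a flag exists. Coordinates are propagated unwrapped, so
trajectories feed the MSD analysis directly; interactions always use the
minimum image, so unwrapping is purely a bookkeeping convenience.

## Membrane observables

* **RDF**: 3-D shell-normalized pair histogram under minimum image,
  averaged over frames; exact bin-count agreement with an O(N^2) loop is
  asserted for small systems.
* **Z-density**: histogram of bead z-coordinates, recentered per frame on
  the bead midplane, normalized to unit integral over z. "Area-normalized"
  was read as unit integral; a per-xy-area convention would differ only by
  the constant box area and is noted as the alternative.
* **Thickness**: leaflets assigned by the sign of z relative to the
  per-frame headgroup midplane (the simplest rule consistent with planar
  bilayers; lipids crossing the midplane mid-frame are out of scope); the
  xy plane is gridded in 10 x 10 A cells; each cell's value is mean upper
  HG z minus mean lower HG z; unoccupied cells are flagged, never imputed;
  the scalar is the occupancy-weighted mean.
* **Order parameter**: `S = <(3 cos^2 theta - 1)/2>` of bond vectors
  against the box z-axis (the membrane normal for planar bilayers, fixed by
  design). `S` is 1 for bonds along the normal, -0.5 in-plane, 0 at the
  magic angle; these analytic limits are the package's acceptance anchors.
* **Lateral MSD and diffusion**: in-plane squared displacement averaged
  over all time origins and selected beads (conventionally the MG bead, one
  per lipid); `D` is a quarter of the slope, from a weighted linear fit
  over lags in `[10%, 50%]` of the maximum — a window that avoids both the
  ballistic start and the poorly averaged tail, the method being silent on
  the exact choice. Wrapped input is detected (inter-frame jumps beyond
  half a box edge) and refused rather than silently unwrapped.

## The synthetic-data generator

`generate_cg_dataset()` stands in for a mapped reference ensemble: it runs
the package's own Langevin integrator under a **toy force field with fully
known parameters** (`toy_lipid_ff()`), discards a burn-in, stores frames at
decorrelating intervals (at least 100 steps apart), and attaches to every
stored frame the toy forces re-evaluated at the stored coordinates — exact
by construction, so the mapping, prior-fitting and training stages are
tested against ground truth rather than against another simulation's noise.

The toy force field: harmonic bonds (k = 5 kcal/mol/A^2; r0 = 4.8, 4.4,
4.0 A for HG–MG, MG–T1, T1–T2) and pair terms
`(a r^-6 + b exp(-(r - rm)^2 / 2 w^2)) * envelope(r)` — a repulsive core
(`a` = 6000–12000 kcal/mol A^6, strongest for head-involving pairs) with a
Gaussian cohesion well (`b` = -1.5 kcal/mol at rm = 5 A, w = 1.5 A) among
tail beads and a weaker one (-0.6) for MG–T1. The cohesion values were
chosen once so that a solvent-free bilayer is metastable over
fixture-length runs at 300 K under both the fixture-generation damping
(10 ps^-1, a strong-coupling choice that decorrelates samples quickly) and
the production damping (0.1 ps^-1); the initial lattice splays the two
tails of each lipid 1.75 A sideways so the unexcluded 1–3 tail contact
starts outside the repulsive core and the template begins cohesive rather
than strained. All parameters are recorded with every fixture, and fixtures
are bit-reproducible from (spec, seed).

`expand_pseudo_atomistic()` inverts the mapping direction for testing:
every bead becomes `atoms_per_bead` atoms with random masses (drawn once
into the emitted mapping scheme) and random positions and forces
constructed so the mass-weighted position mean and the force sum equal the
bead values *exactly* — mapping the expansion back must reproduce the CG
frame to machine precision, which is the package's strongest mapping test.

What the fixtures do **not** emulate: real lipid chemistry or CHARMM-level
energetics, water-mediated interactions, undulation spectra of large
patches, lipid flip-flop, or mixed-composition membranes. Passing the
closed-loop tests therefore demonstrates that the pipeline's machinery is
correct and self-consistent, not that a model trained on these fixtures
transfers to real membranes.

## Problem sizes and the closed loop

The end-to-end check (`end_to_end_recovery()`) runs the full workflow —
generate, map-level priors, delta forces, train, simulate, analyze — on an
18-lipid bilayer with 120 stored frames, and asserts that training cuts the
validation force RMSE at least in half and that the learned-model
simulation reproduces the truth simulation's first tail–tail RDF peak
within one histogram bin (0.2 A). These sizes were chosen as the smallest
bilayer (2 k^2 lipids with k = 3) whose leaflets are unambiguous and whose
pair statistics make the RDF peak sharp; unit tests use 4–10-lipid gas
fixtures where geometry does not matter. The closed loop trains the spline
baseline: the toy truth is pairwise-representable, so the spline is the
model for which recovery is an exact target rather than an approximation,
and any failure isolates a pipeline defect rather than model capacity. The
graph potential's trainability (validation-loss reduction on fixture data)
and its exact loss gradient are asserted separately.

## Numerical choices, degenerate inputs, limitations

* Orthorhombic boxes only; the minimum image is exact there and the pair
  search is an all-pairs scan adequate for a few thousand beads.
* Zero-variance bond samples, empty fit ranges, empty selections, empty
  leaflets, zero-length bond vectors and wrapped MSD input all raise typed
  errors rather than producing numbers.
* The near-singularity guard, cutoff envelopes and C1 spline extrapolation
  exist so that every force the integrator ever sees is finite and
  continuous; blow-ups (non-finite coordinates or a displacement exceeding
  a box edge in one step) abort with the step number and the last saved
  frame.
* Boltzmann inversion of condensed-phase marginals carries the systematic
  environment bias discussed above; the delta-force construction makes the
  total force field exact at the matched configurations regardless.
* The CLI writes all outputs atomically (temporary file + rename) and logs
  a provenance header (package version, seed, config hash) for every
  subcommand.
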