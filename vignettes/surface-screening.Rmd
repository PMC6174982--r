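---
title: "Methods: surface patch screening of protein expressability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface patch screening of protein expressability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`posq` screens protein structures for two surface features associated with
poor secretion of recombinant targets: the size of the largest positive
electrostatic-potential surface patch (PosQ) and the maximal
nonpolar:polar solvent-accessible-surface ratio over 13 Å atom patches
(NPP). This vignette documents the models behind both scores, every
tunable parameter, the numerical choices, and what the synthetic-structure
validation does and does not establish.

# The electrostatic model

## Linearized Poisson–Boltzmann

The potential $\phi$ around the solute satisfies the linearized
Poisson–Boltzmann equation

$$\nabla\!\cdot\!\big(\varepsilon(\mathbf r)\,\nabla\phi\big)
  - \varepsilon_s\,\kappa^2(\mathbf r)\,\phi
  = -\rho_f(\mathbf r)/\varepsilon_0,$$

with a two-dielectric map ($\varepsilon_p$ inside the solute,
$\varepsilon_s$ in solvent) and Debye screening $\kappa$ active only where
mobile ions can reach. Linearization is appropriate here: at 0.15 M
(Debye length $1/\kappa \approx 7.9$ Å) the surface potentials that matter
for a 25 mV contour are at most a few $kT/e$, and linearity gives exact
superposition, which the test suite exploits as an oracle (a two-charge
solve must equal the sum of the single-charge solves). Nonlinear PB,
membrane slabs and pKa/site titration are out of scope.

## Discretization and solver

* Cubic grid, default spacing 0.8 Å, at least 10 Å solvent margin on every
  side; dimensions are odd so the structure centroid falls on a node.
  Structures screened here are single domains (< 250 residues), so a
  single-level solve without focusing suffices.
* Face-centred ("staggered") dielectric: each of the three face arrays is
  assigned $\varepsilon_p$ where the face midpoint lies inside any atom
  sphere inflated by the solvent probe (1.4 Å), else $\varepsilon_s$.
  Defaults $\varepsilon_p = 4$, $\varepsilon_s = 78.4$.
* Ion accessibility: $\kappa^2$ is zeroed inside atoms inflated by a
  2 Å Stern layer.
* Charges are spread onto the eight surrounding nodes with trilinear
  weights.
* Dirichlet boundary: the sum over charges of the ion-excluded
  Debye–Hückel sphere term
  $\phi_j(r) = \ell_B q_j e^{-\kappa (r - a_j)} / \big(\varepsilon_s (1 +
  \kappa a_j) r\big)$ with $a_j$ the atom radius plus Stern layer. The
  exclusion factor matters: a bare $e^{-\kappa r}/r$ boundary carries a
  spacing-independent bias of a few percent, which would mask grid
  convergence.
* Red–black successive over-relaxation (compiled kernel), relaxation
  factor $2/(1 + \pi/n_{max})$, deterministic sweep order, convergence
  when the largest per-sweep update falls below `tol` ($10^{-6}$ by
  default) relative to the field maximum. Non-convergence is an error, not
  a warning.
* Internal units are $kT/e$; outputs are mV via $kT/e = 25.693$ mV at
  298.15 K, so the 25 mV contour is 0.973 $kT/e$.

Solver validation uses the Born ion (`make_born_ion()`): one charged
sphere whose closed-form linearized-PB (Kirkwood) solution is compared
with solver output at sample points at least two grid spacings outside the
sphere, under grid refinement 1.2 → 0.8 → 0.6 Å. The fixture pairs with
`stern_layer = 0` so the analytic and discrete ion-exclusion boundaries
coincide.

## Charge and radius scheme

The screen fixes pH 7 but no force field, so parameterization is
deliberately minimal and auditable (`default_scheme()`):

* Bondi-style element radii: C 1.70, N 1.55, O 1.52, S 1.80 Å
  (overridable per element or per atom name).
* Formal charges at group tip atoms: Asp/Glu −1 split over the carboxylate
  oxygens, Lys +1 on NZ, Arg +1 split over NH1/NH2, His neutral at pH 7,
  N-terminus +1 on N, C-terminus −1 (split over OXT/O when OXT is
  present). No partial-charge force field: formal charges reproduce the
  positive/negative patch logic the scores depend on, and the scheme's net
  charge is checkable against a closed-form residue tally.
* Hydrogens are ignored (united-heavy-atom surfaces); crystallographic and
  homology models typically lack them anyway.
* Polarity: C and S nonpolar, N and O polar — the common SASA convention.

Because the original screen's charge set, radii, grid resolution and
boundary treatment are not published, exact numeric parity with its
reported PosQ values is not claimable; all claims here are property-based
(orderings, invariances, recovery of planted ground truth).

# Surfaces and patches

## Solvent-accessible surface

`compute_sasa()` implements Shrake–Rupley: a deterministic golden-spiral
template of 960 points per atom on the probe-expanded sphere
(radius + 1.4 Å), points inside any neighbouring expanded sphere removed.
Every surviving point carries an equal area weight, so per-atom SASA is
the exposed fraction times $4\pi(r+p)^2$ and the point cloud is an
area-weighted surface sample with per-point atom ownership — the
substrate for both patch measures. 960 points give isolated-atom areas
accurate to well under 1%; the count is configurable and all downstream
quantities are area-based, hence sampling-density invariant.

## Positive-potential patches and PosQ

Surface points are assigned potentials by trilinear interpolation;
points at or above the 25 mV contour (closed inequality) are clustered by
fixed-radius adjacency. The link radius defaults to twice the mean
inter-point spacing, estimated as $\sqrt{\overline{w}}$ from the mean
per-point area weight $\overline{w}$ — this decouples clustering from the
sphere-point count. Components come from igraph; the test suite checks
them against an independent breadth-first search on hundreds of random
clouds.

Patch *size* is the summed solvent-accessible area (Å²) of member points,
not a point count. PosQ is the largest patch area over a threshold
`threshold_A2`. The packaged default (400 Å²) is an explicit placeholder:
the original calibration against a cell-free E. coli solubility database
is unpublished and re-deriving it is out of scope. Every ranking the
package produces is threshold-invariant (the ratio is monotone in the
area), and `rank_report()` orders by increasing PosQ with ties broken by
NPP descending, then label.

## Nonpolar:polar patch ratio

For every atom with exposed area, the patch is all atoms whose centres lie
within 13 Å of the centre atom's centre (buried members contribute zero
area, so inclusion is harmless); the ratio is summed nonpolar over summed
polar exposed area, and the score is the maximum over centres. Patches
with zero polar area get a configurable cap (default $10^3$) so rankings
propagate caps, not infinities. Whether the 13 Å criterion should be
atom-centre or surface-point based is not settled; atom-centre distance is
used and isolated behind the patch-radius parameter.

# Sequence engineering

Construct design mirrors the operations used to rescue a poorly secreted
TIMP: `swap_domains()` exchanges N/C-terminal segments at per-parent
boundaries (e.g. position 127 of one parent, 121 of the other; the
boundary residue stays N-terminal), and `replace_region()` grafts a donor
region over an acceptor region — both 1-based and inclusive, matching the
K26–I41 ← E26–I47 notation, with per-residue provenance recorded. The
classic graft lengthens the acceptor by exactly 6 residues; that
arithmetic is a frozen test. Donor coordinates are taken literally from
stated positions, never recomputed from an alignment — when positions and
alignment disagree, stated positions win. Pure deletions require an
explicit `allow_empty_donor` flag so a mis-typed region cannot silently
delete sequence.

`global_align()` is Needleman–Wunsch with affine gaps (BLOSUM62, open 10,
extend 0.5 — a gap of length $L$ costs $10 + 0.5L$), via Biostrings.
Percent identity and similarity use the full alignment length including
gap columns as denominator (the EMBOSS convention); similarity counts
columns with a positive substitution score. The implementation is checked
against exhaustive enumeration of all alignments for short sequences.
`annotate_chemistry()` partitions the 20 residues into the four classes
used for alignment colour-coding: small/hydrophobic (AVFPMILWG), acidic
(DE), basic (RKH), hydroxyl/sulfhydryl/amine (STYCNQ).

# Synthetic structures and what they establish

Real validation targets (crystal structures, homology models) are
version-dependent external artifacts, so the test battery runs on
generated pseudo-structures with planted ground truth
(`make_charged_blob()`, `make_nonpolar_blob()`, `make_born_ion()`).

A blob is the `n` jittered face-centred-cubic lattice sites nearest the
origin (nearest-neighbour distance 3.0 Å, jitter 0.05 Å, so separations
stay above 2.8 Å), with real element radii. Close packing is a deliberate
choice over random sequential packing: at densities a random packing can
reach, probe-sized interior voids remain, and their cavity surfaces show
up as spurious disconnected "patches" that have nothing to do with the
planted signal; the lattice guarantees a single outer envelope. Planted
clusters are geodesic surface caps of known extent (error if a cap would
exceed a hemisphere), carrying ±1e per member atom or a nonpolar element
switch; ground truth records members, centre atom and the cap's
solvent-accessible area by direct point-ownership classification,
independent of the patch-clustering code. Generation is a pure function of
the spec: the same seed reproduces coordinates bit-for-bit, and the
caller's RNG state is untouched.

For patch-recovery studies the blobs carry a weak acidic background
(−0.1e on each non-cap surface atom, `background_charge`). With a fully
neutral background, the 25 mV contour crosses the surface inside a shallow
annulus where crevice-scale potential variation fragments the contour into
slivers — a real property of contouring a bumpy molecular surface, not a
clustering artifact. A weak opposing background makes the cap boundary
steep, so "one planted cap, one patch; two disjoint caps, two patches" is
a well-posed ground truth. This mimics real soluble proteins, whose
surfaces are charge-mixed rather than neutral-plus-one-basic-cluster.

What passing these tests shows: the solver, surface, contouring,
clustering and scoring machinery are each correct against independent
oracles and jointly recover planted signals in rank order. What they do
not show: that PosQ computed with this particular charge scheme and grid
reproduces any specific published value for a real protein, nor that the
secretion correlation holds beyond the structures it was derived from. The
external check for users with structure access — scoring the published
TIMP-family / PAI-1 / artemin structure set and comparing the qualitative
PosQ ordering — is deliberately not part of the automated suite, since it
requires downloaded PDB entries and rebuilt homology models whose versions
drift.

# Numerical and edge-case policy

* Zero charges give an exactly zero field (the solver's fixed point), and
  a structure with only non-positive charges has PosQ exactly 0 (discrete
  maximum principle with non-positive boundary values) — both are tested
  as identities, not tolerances.
* Degenerate inputs error early with typed messages: empty structures,
  unknown atoms (parameterization error listing offenders), regions out of
  range, thresholds ≤ 0 (config error), sample points outside the grid and
  structures too close to the boundary (geometry error), non-convergence
  (convergence error with the residual).
* B-factor annotation clamps scores to [−99.99, 999.99] to respect the
  fixed-width column.
* Determinism: the sphere-point template, lattice, solver sweep order and
  report sort (ties: NPP descending, then label) are all deterministic;
  reruns of a config byte-reproduce the TSV report on one machine.

## Problem sizes in the automated suite

The tests and the acceptance script use blobs of 60–250 atoms, grids of
0.6–1.2 Å spacing (up to ~61³ nodes), 960 surface points per atom, 200
random clouds of up to 500 points for the clustering oracle, and five
planted cap extents (4–10 Å) for recovery — sizes chosen so the whole
battery runs in minutes on one CPU while every mechanism is exercised at
realistic scale.

# Known limitations

* Formal tip-atom charges ignore charge anisotropy and His protonation
  microstates; pKa shifts are not modelled.
* The PosQ threshold default is uncalibrated (see above); absolute PosQ
  values are comparable only within a fixed configuration.
* Homology modelling is upstream of this package: scores are only as good
  as the input coordinates.
* PDB ATOM records cannot carry the generator's planted charges, so
  synthetic blobs written to disk and re-read are re-parameterized by the
  amino-acid scheme; synthetic studies should score the in-memory
  structures.
* The point-sampled surface makes patch areas accurate to the sampling
  scale (~0.1 Å² per point at defaults); single-point slivers at a contour
  are physically meaningful but sampling-sensitive.
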