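---
title: "Methods behind abctraj: descriptors, landscapes, membranes and allosteric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind abctraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abctraj)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices taken where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real trajectories.

## Conventions

Coordinates are in Ångström, residue numbering is 1-based, the membrane
normal is the z axis, and the bilayer centre sits near z = 0 (defined
operationally as the midpoint of the phosphate-marker z distribution,
`bilayer_center()`). Inter-atomic distances use the minimal-image
convention under orthorhombic boxes; group centres of mass are computed on
whole molecules, never on wrapped fragments. COMs are mass-weighted by
default with a flag to disable; the synthetic systems give all
pseudo-atoms a uniform 12 amu so that mass-weighted and geometric COMs
coincide and descriptor arithmetic can be checked by hand.

## ABC conformational descriptors

The descriptor set follows the structural parameters in common use for
type-IV ABC exporters:

* **IC angle** — angle at the COM of the whole extracellular region
  between vectors to the COMs of the intracellular halves of
  TMH{1,2,3,6,10,11} and TMH{4,5,7,8,9,12}. It measures the opening of
  the intracellular substrate-entry cavity.
* **EC angle and EC distance** — same construction on the extracellular
  side, with the vertex at the COM of both NBDs and halves
  TMH{1,2,9,10,11,12} vs TMH{3,4,5,6,7,8}.
* **NBD distance** — distance between the two NBD COMs.
* **NBD rocking-twist** — signed dihedral
  COM(lobe₁)–COM(NBD1)–COM(NBD2)–COM(lobe₂), right-handed about the
  NBD1→NBD2 axis, in (−180°, 180°]. Lobe membership is a scheme entry
  and defaults to the N-terminal half of each NBD; published lobe
  definitions vary, so the choice is configurable rather than baked in.
* **NBS Gly–Ser distances** — Cα–Cα distances between the Walker-A
  glycine of one NBD and the ABC-signature serine of the other, one pair
  per composite site.

Which residues constitute each group is *data*, not code: a YAML
"selection scheme" maps descriptor roles to residue ranges, is validated
against the topology, and derives the composite half-groups from
per-helix entries. Real systems differ in their per-helix residue ranges
(and reference structures each need their own scheme), which is why the
shipped schemes are editable templates generated alongside each synthetic
system. Whether intracellular/extracellular "regions" are backbone-only
or all-atom is likewise a scheme-level option; the default selection is
all atoms of the listed residues.

Helix tilt is the angle between a helix's principal axis (largest-variance
eigenvector of its Cα cloud, oriented IC→EC) and the bilayer normal,
folded into [0°, 90°]. Note one honest numerical property: for a discrete
α-helix with a non-integer number of turns the Cα principal axis deviates
from the geometric axis by a few tenths of a degree; the tests assert
exactness on straight rods and sub-degree accuracy on full helices.

RMSF aligns every frame once onto the trajectory-average structure
(single pass; iterating the average changes results by far less than
sampling noise at the ensemble sizes involved). Core PCA diagonalises the
Cartesian covariance of the ABC core (backbone atoms of TMH1–12 and both
NBDs) and reports per-domain contributions as squared loadings summed
over TMD1 (TMH1–6), TMD2 (TMH7–12), NBD1 and NBD2. Superposition onto the
core average is applied by default but can be disabled for pre-aligned
input — relevant because fitting on a selection that itself moves leaks a
few percent of a single-domain motion into the other domains.

## Free-energy landscapes

Given n samples of a descriptor pair, a full-covariance 2D Gaussian
mixture is fitted by EM for each component count K in 2..12 with at most
20 iterations per fit — the component range and iteration cap used in
GMM-based landscape practice for MD descriptor data. Initialisation is a
seeded k-means++ centre draw, so fits are bit-reproducible; samples are
put into a canonical order first, making the result invariant under
permutation of the input rows. K is selected by mean held-out
log-likelihood under 3-fold cross-validation (the iteration cap acts as
implicit regularisation; cross-validation guards against overfitting the
component count). Covariance eigenvalues are floored at 1e-6 to survive
degenerate clusters.

The landscape is F = −kT ln p evaluated at the centres of an 80×80 grid,
shifted so min F = 0, with cells below 1e-6 of the peak density masked.
kT = 1 by default (free energies in thermal units); multiply by 0.6163
for kcal/mol at 310 K. Core states are found by steepest-ascent
assignment on the density grid over 8-neighbourhoods with a lexicographic
(density, −index) tie-break — without the tie-break, a mixture mean that
falls exactly between grid cells splits one basin into several plateau
fragments. Basins whose peak density is below 5% of the global peak are
merged into the nearest stronger peak; the 5% threshold is this package's
choice where published core-state cutoffs are not stated, and it is a
documented parameter (`merge_frac`). This gradient-basin construction is
a deliberate simplification of inflection-point state-boundary criteria;
it reproduces populations and free-energy gaps of well-separated states
but will draw different boundaries for strongly overlapping ones.

Convergence profiling splits a descriptor series into equal blocks and
flags convergence when the last two block means differ by at most one
pooled block standard deviation — a coarse screen, intentionally
conservative about what it claims.

## Pore profiles

The pore radius at height z is the radius of the largest sphere centred
in that z-plane clearing all atoms: max over (x, y) of
min_i(|c − r_i| − vdW_i), atoms taken from a slab of half-width 7.5 Å.
Instead of a stochastic search, each slab runs a deterministic
multi-start compass pattern search (5 starts seeded from the previous
slab's centre, step halving from 2 Å to 1e-4 Å), trading search fidelity
in pathological geometries for exact reproducibility. The radius is
capped at 15 Å and flagged when the cap binds or the slab is empty.
Depth series at z ∈ {18, 5, −15, −22} Å are reported per window with a
bootstrap standard deviation over resampled snapshots. Van der Waals
radii come from the topology, falling back to a bundled element table.

## Membrane analyses

S_CD(k) is ⟨(3cos²θ − 1)/2⟩ over the C–H vectors of carbon k relative to
z; the sn1/sn2 tails are identified by atom-name suffix. 2D densities
histogram each species' head marker (phosphate bead for phospholipids,
hydroxyl bead for sterols) per leaflet, normalised per Å² per frame so
the grid integral equals the mean molecule count. Occupancy hotspots
score, per lipid molecule, the fraction of frames with any heavy atom
within 6 Å of the protein selection (the cutoff is a package default —
occupancy thresholds of 50% and 80% are standard, the contact cutoff
rarely printed), and report the protein residues touched. Thickness maps
difference the leaflet-mean marker surfaces per xy cell, interpolating
and flagging cells with an empty leaflet.

The deformation energy uses a simplified two-term continuum functional
over the half-thickness deviation u = (h − h₀)/2:

ΔG = ∫ [ (K_A/2)(2u/h₀)² + (K_C/2)(∇²u)² ] dA

with periodic central differences for the Laplacian. Defaults
K_A = 0.6 kcal mol⁻¹ Å⁻² and K_C = 12 kcal mol⁻¹ are typical bilayer
elastic constants and are package defaults, not fitted values. This
functional is positive for any non-flat field; negative "deformation free
energies" reported in comparative studies arise from subtracting a
non-zero reference, which is left to the caller and stated as such.

## Networks and allostery

Nodes follow the coarse model used for transporter networks: one node per
protein residue anchored on Cα; three nodes per phospholipid (head, two
tails); three per ATP-like ligand (purine, ribose, triphosphate); three
per LTX-like ligand (glutathione, tail, acid); one per sterol or ion.
DCCM entries are normalised displacement covariances of node anchors;
contact maps count frames with any heavy-atom pair within 4.5 Å and zero
out same-residue and sequence-neighbour pairs (the standard
notSameResidue/notNeighboringCAlpha/notNeighboringResidue exclusions).
Communities are Girvan–Newman edge-betweenness clusters (igraph backend)
on the graph with edges where the contact fraction reaches 0.75 and
weights −log|C_ij|, keeping the maximum-modularity cut.

Mutual information uses the Gaussian closed form
MI = −½ ln(1 − ρ²) with ρ the DCCM correlation — exact when fluctuations
are Gaussian, which the synthetic generator makes true by construction; a
plug-in histogram estimator on displacement magnitudes is available
behind a flag for non-Gaussian data. Communication efficiency between two
residue sets is the effective conductance of the resistor network with
edge conductances g_ij = MI_ij × contact_ij, source and sink sets
contracted to super-nodes, solved as a grounded Laplacian system; node
betweenness is each node's total throughflow under unit injected current,
with super-node flow split equally over set members. A disconnected
source–sink pair yields zero efficiency, flagged rather than silently
propagated. Efficiency so defined is monotone in every edge conductance
and reduces to Ohm-law identities on series/parallel graphs, which is
exactly what the test oracles (independent Kron star-mesh elimination)
verify. Where a published "communication efficiency" formula is not
printed, this resistor-network definition is the package's documented
stand-in.

## The synthetic generator: what it does and does not emulate

`make_transporter()` places 12 pseudo-TMHs (each an ideal α-helix pair:
1.5 Å rise, 100° twist, 2.3 Å radius, IC and EC segments translated so
every segment centroid is exact), two two-lobe NBD point clouds, anchor
residues, an L0-like linker and coupling-helix stubs, so that the IC/EC
angles, NBD distance and twist equal their targets to machine precision —
half-group COM targets are laid out analytically and per-helix offsets
are placed on zero-sum hexagons. `make_trajectory()` draws frames i.i.d.
from weighted states with isotropic Gaussian noise; designated atom-set
pairs share a latent Gaussian, giving their fluctuations a prescribed
Pearson correlation exactly in expectation. `make_membrane()` reaches a
target |S_CD| level p·0.5 by making a fraction p of C–H vectors
membrane-plane and the rest isotropic. Default study conditions used
throughout the tests: σ = 0.5 Å positional noise, 10,000-frame recovery
runs, n = 50,000 landscape samples, n = 20,000 MI samples, cholesterol-
containing compositions such as 2:1:1 over 400 lipids.

What passing these tests shows: the estimators are correct on data whose
generative process matches their assumptions (Gaussian fluctuations,
i.i.d. frames, ideal geometry). What they do not show: robustness to
autocorrelated MD sampling, anharmonic or multimodal fluctuations within
a state, wrapped periodic coordinates, protonation/chemistry effects, or
force-field realism — none of which the generator attempts to mimic,
deliberately: it tests estimators, not physics.

## Numerical choices and edge cases

* Kabsch superposition corrects the reflection branch (det = +1 enforced
  via the SVD sign fix); fewer than three fit atoms is an error.
* Dihedral sign: right-handed about the NBD1→NBD2 axis; collinear centre
  points raise a degenerate-dihedral error rather than returning 0.
* Zero-variance DCCM nodes get zeroed rows with unit diagonal, logged.
* Singular GMM covariances are floored, not fatal.
* The H-bond decision is ≤ on the heavy-donor–acceptor distance (3.5 Å)
  and ≥ on the D–H···A angle measured at the hydrogen (120°); the vertex
  convention is stated because printed cutoffs usually omit it.
* Non-bonded energies are plainly truncated at 10 Å (no switching):
  the analyses are comparative, matching common simulation cutoffs.
* Interaction-energy sampling density (e.g. how many evenly strided
  points per replica) is left to the caller via trajectory striding.
* Replica statistics: replicas are aggregated as independent samples —
  n, mean and sd over replica means, never over pooled frames.

## Test and acceptance problem sizes

The suite exercises: 100-frame oracle-equivalence sweeps at 1e-9;
exact noise-free generator recovery plus 2%-level recovery at σ = 0.5 Å
over 10,000 frames; two-Gaussian landscape recovery at n = 50,000 for
weight ratios 1:1, 7:3 and 9:1 (ΔF within 0.1 kT of −ln(w₁/w₂), fits over
K = 2..4 at this n; the full 2..12 selection path is exercised at smaller
n); MI at ρ ∈ {0, 0.5, 0.9} and n = 20,000; exhaustive 4-node plus 200
random 5/6-node resistor-network comparisons at 1e-9; analytic pore
channels at the four standard depths within 0.1 Å; S_CD limits exact and
the isotropic case at 5,000 samples; the 8×10 H-bond truth table; and 20
seeded planted-partition recoveries. `scripts/acceptance.R` recomputes
the same quantities end-to-end from fresh synthetic systems and writes
them to JSON.

## Known limitations

Landscapes are 2D only and carry no kinetic information; the pore search
assumes a z-aligned channel; the continuum membrane model omits
curvature–tilt coupling and boundary-value solutions; MI is closed-form
Gaussian unless the histogram estimator is requested; suboptimal-path
(WISP-style) and time-lagged (transfer-entropy) network variants are out
of scope. DCD/XTC binary trajectory input is not implemented — multi-model
PDB is the interchange format; for large production trajectories, convert
and stride upstream.
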