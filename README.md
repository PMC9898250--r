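# abctraj

Trajectory analysis for ATP-binding cassette (ABC) transporter simulation
ensembles, with a built-in synthetic-system generator so that every stage of
the pipeline can be validated against known ground truth.

ABC exporters such as MRP1/ABCC1 alternate between inward-facing (IF) and
outward-facing (OF) conformations driven by ATP binding at two composite
nucleotide-binding sites (NBSs). Simulation studies of these transporters
lean on a common analysis stack: low-dimensional conformational
descriptors, density-based free-energy landscapes over those descriptors,
pore-radius profiles, lipid-structure metrics, and correlation/information
networks that trace allosteric communication between the substrate-binding
pocket and the NBSs. `abctraj` implements that stack as a tested R package
for structural bioinformaticians and simulation scientists.

## What it computes

**Conformational descriptors.** The intracellular opening angle is the
angle at the extracellular region's centre of mass (COM) between vectors to
the COMs of the two intracellular TMH half-groups, TMH{1,2,3,6,10,11} and
TMH{4,5,7,8,9,12}; the extracellular angle uses the NBD-pair COM and the
extracellular halves TMH{1,2,9,10,11,12} vs TMH{3,4,5,6,7,8}; the NBD
geometry is summarised by the inter-NBD COM distance d(NBD) and the
rocking-twist, the signed dihedral
COM(lobe1)–COM(NBD1)–COM(NBD2)–COM(lobe2). Walker-A glycine / ABC-signature
serine Cα distances, helix tilts, RMSD/RMSF and ABC-core PCA complete the
set.

**Free-energy landscapes.** A 2D Gaussian mixture is fitted to descriptor
pairs by EM (components K = 2..12, at most 20 iterations, K chosen by
3-fold cross-validated held-out likelihood); the landscape is
F = −kT ln p on an 80×80 grid, and core states are gradient-ascent basins
of the density with weak peaks merged.

**Pore, membrane, networks, interactions.** Hole-style pore radii per
z-slab (largest sphere maximising min over atoms of |c−r| − vdW, by
deterministic multi-start pattern search) with bootstrap errors at fixed
depths z ∈ {18, 5, −15, −22} Å; lipid order parameters
S_CD = ⟨(3cos²θ − 1)/2⟩, leaflet-resolved 2D densities, 50%/80% occupancy
hotspots, thickness fields and a two-term continuum deformation energy;
DCCM, restricted contact maps, Girvan–Newman communities, Gaussian
mutual-information matrices, and allosteric communication efficiency as
the effective conductance of the MI×contact resistor network with
current-flow betweenness decomposed over protein, lipid and ligand nodes
(lipids contribute three nodes each, ATP-like and LTX-like ligands three,
sterols and ions one); hydrogen bonds at 3.5 Å / 120°, Coulomb
(k_e = 332.06 kcal mol⁻¹ Å e⁻²) and Lennard-Jones ligand–site potentials,
and π-stacking centroid distances.

**Synthetic systems.** `make_transporter()` builds a pseudo-transporter
whose descriptors equal prescribed targets exactly in the noise-free
limit; `make_trajectory()` draws frames from state mixtures with optional
correlated modes of known Pearson ρ; `make_membrane()` builds bilayers
with an analytic S_CD level; `make_ligand()` provides tagged ATP-like /
LTX-like / sterol-like pseudo-molecules.

## Worked example

Two conformational states — an IF-like build (IC 33°, d(NBD) 52 Å) and an
OF-like build (IC 12°, d(NBD) 31 Å) — sampled 60/40 with 1 Å positional
noise, then analysed blind:

```r
library(abctraj)

ifs <- make_transporter(transporter_spec(ic_angle = 33, ec_angle = 2,
                                         nbd_distance = 52, nbd_twist = 75))
ofs <- make_transporter(transporter_spec(ic_angle = 12, ec_angle = 14,
                                         nbd_distance = 31, nbd_twist = 45))
traj <- make_trajectory(states = list(ifs$coords, ofs$coords),
                        weights = c(0.6, 0.4), n_frames = 4000,
                        noise_sigma = 1.0, seed = 1)
ds <- descriptor_series(traj, ifs$topology, ifs$scheme, gs = FALSE)
head(ds[, c("frame", "ic_angle", "ec_angle", "nbd_distance", "nbd_twist")], 3)
#>   frame ic_angle ec_angle nbd_distance nbd_twist
#> 1     1    33.05     1.98        51.77     79.75
#> 2     2    32.90     2.09        51.54     81.07
#> 3     3    33.14     2.03        51.46     74.35

gmm <- fit_density(cbind(ds$nbd_distance, ds$nbd_twist),
                   k_min = 2, k_max = 4, seed = 1)
ls  <- find_core_states(free_energy_grid(gmm))
round(sort(ls$populations), 3)
#> [1] 0.389 0.611
```

The per-frame descriptors sit on the IF build targets (IC ≈ 33°,
d(NBD) ≈ 52 Å) whenever the mixture draws the IF state, and the landscape
over (d(NBD), twist) finds exactly two core states whose populations,
0.611/0.389, recover the 60/40 sampling weights within sampling error. The
free-energy gap between the two basin minima came out at 0.48 kT here;
it tracks −ln(w₁/w₂) = 0.41 kT with the residual reflecting the two
basins' different widths.

A command-line front end covers the same pipeline
(`generate`, `descriptors`, `landscape`, `pore`, `membrane`, `network`,
`allostery`, `hbonds`):

```sh
Rscript inst/cli/abctraj generate --out sys --seed 7 --ic 30 --nbd-dist 40 --n-frames 100
Rscript inst/cli/abctraj descriptors --traj sys.pdb --scheme sys_scheme.yaml --out desc.tsv
```

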