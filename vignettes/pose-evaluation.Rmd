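---
title: "Evaluating docking poses against crystallographic references"
author: "dockeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating docking poses against crystallographic references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockeval)
```

## The problem

Rigid-receptor docking engines rank candidate ligand placements (poses) by
a scoring function, and the community habit is to take the best-scored
pose as "the answer". Whether that habit is justified can be tested
whenever a crystallographic reference complex exists: re-dock the ligand
into its own receptor conformation (self-docking) or into a receptor
conformation crystallised with a different ligand (cross-docking), and
ask at which scoring position the first pose appears that actually
reproduces the crystallographic orientation. `dockeval` implements that
evaluation pipeline - not the docking itself - so that the statistics can
be computed reproducibly from any engine's output.

The evaluation chain is:

1. **Binding-site definition.** The binding site of a reference complex
   is the set of residues with any atom within 10 Å (default,
   `site_cutoff`) of any heavy atom of the crystallographic ligand. The
   shell is measured from ligand heavy atoms to *any* residue atom - the
   most inclusive reading of a distance shell, chosen so that marginal
   side chains are kept rather than silently dropped.
2. **Receptor superposition (cross-docking only).** Poses produced in a
   foreign receptor frame are carried into the reference frame by a
   least-squares rigid transform fitted on the binding-site Cα atoms
   (Kabsch algorithm, SVD with determinant correction so reflections are
   impossible). Residues are paired by identical chain/number/name; there
   is no alignment fallback because both structures are crystal forms of
   the same protein - anything unpaired is dropped with a logged warning,
   and fewer than 3 pairs is an error. Self-docking uses the identity
   transform, so both modes share one code path.
3. **Symmetry-corrected RMSD.** The deviation of a pose from the
   reference is the minimum over all automorphisms σ of the heavy-atom
   bond graph of `sqrt(mean(|pose[σ(i)] - ref[i]|²))`. Chemically
   equivalent atoms (ring flips, symmetric substituents) therefore never
   inflate the RMSD, while the ligand itself is *never* re-superposed:
   docking accuracy means placement in the receptor frame.
4. **Classification and best-solution statistics.** Poses are good
   (RMSD ≤ 2.0 Å), acceptable (2.0-3.0 Å) or bad (≥ 3.0 Å). For each
   ensemble of top-N poses (N = 10 by default) the *s2* criterion takes
   the smallest rank whose pose is good; *s3* also admits acceptable
   poses. If no pose complies the instance is a bad solution (BS).
   Recurrence tables report the percentage of instances whose best
   solution sits at each scoring position; cross-docking matrices report,
   per (ligand, receptor) cell, whether any replicate found a solution.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `site_cutoff` | 10 Å | residue shell defining the binding site |
| `tau_good`, `tau_bad` | 2.0, 3.0 Å | class thresholds |
| `good_inclusive` | `TRUE` | whether exactly 2.0 Å is good |
| `top_n` | 10 | scoring positions analysed per ensemble |
| `max_automorphisms` | 10000 | enumeration cap for symmetry matching |
| replicates | 3 | docking repetitions counted as separate instances |

Two conventions deserve a note. First, the source thresholds are quoted
both as "≤ 2.0" (class definition) and "< 2.0" (criterion definition);
the package resolves the conflict by using the inclusive class boundary
everywhere and exposing `good_inclusive = FALSE` for the alternative
reading - a measured RMSD landing exactly on the boundary is vanishingly
rare, but the convention is stated rather than left ambiguous. Second,
each replicate counts as one instance in recurrence tables; this is the
only aggregation that requires no extra rule, and the grouping columns of
`recurrence_table()` let a user pool differently.

Score ties are broken by input order (stable sort), and lower scores are
always better, matching the sign convention of the common docking
energies.

## Symmetry matching

`automorphisms()` enumerates the automorphism group of the element- and
bond-order-labelled heavy-atom graph (aromatic bonds are their own order,
distinct from single and double). The implementation refines vertex
colours (1-WL: element, then iteratively the multiset of neighbour
colour/bond-order pairs, until the partition is stable) and then
backtracks over colour-compatible assignments. The cap of 10,000
automorphisms exists because highly symmetric pathological graphs grow
factorially; exceeding it is an error, not a truncation, so a minimum is
never silently computed over a partial group. Hydrogens are excluded
throughout: their positions come from preparation tools, not from the
crystallographic experiment.

Bond orders come from the input file (SDF/MOL2); the package refuses to
perceive bonds from distances or to guess aromaticity. A Kekulé-encoded
aromatic ring therefore has a smaller automorphism group than the same
ring written with aromatic bond types - the price of never inventing
chemistry that is not in the file.

## The pocket module

Binding-site volume (BSV), volume depth (VD = sum of pocket-point depths,
where a point's depth is its distance to the probe surface) and averaged
VD are computed on a regular grid with the published defaults: 1 Å grid,
1 Å probe, single point flag 12, protein depth flag 18. The procedure is
morphological: protein points lie inside the van der Waals surface
(Bondi radii); positions where a probe sphere fits are flood-filled from
outside; their dilation by the probe radius is the probe-covered region;
empty, uncovered points are pocket points, split into 6-connected
components and filtered. The clearance field, distance transforms
(exact Euclidean, Felzenszwalb-Huttenlocher), flood fill and labelling
run in compiled code, so refining the grid to 0.25 Å stays interactive.

The original pocket software defines its two noise flags only
operationally; here **SPF** is interpreted as the minimum component size
in grid points and **PDF** as the maximum allowed point depth in grid
units. These are documented interpretations - the published per-complex
BSV/VD values are *not* a reproduction target of this package, and both
flags are plain configuration knobs.

Validation uses synthetic receptors with geometrically known cavities
(`generate_toy_receptor()`): carbon pseudo-atoms on a 1.5 Å lattice with
cavity walls lined by calibrated atom planes. The liner planes sit
`r_eff` outside the nominal face, where `r_eff` averages the van der
Waals radius and the minimum scallop height of the liner lattice, so the
union-of-spheres boundary straddles the nominal face with near-zero mean
error and the nominal carved volume is the analytic reference. Enclosed
cavities (closed box, sphere) are unreachable by any probe and test pure
volume recovery; the open channel is sealed with a 6 Å probe (a probe of
radius above ~2.3 Å cannot pass a 5 Å aperture once van der Waals radii
are accounted for). Convergence is tested on the enclosed sphere -
a smooth boundary whose discretisation error genuinely shrinks with the
grid - at 1.0, 0.5 and 0.25 Å; the depth cap is scaled with the grid so
it stays a fixed physical 18 Å. On very fine grids (beyond those tested)
a thin sheet between the scalloped van der Waals surface and the probe
envelope of the *outer* slab faces becomes resolvable; it forms its own
component, which is why the tests identify the cavity pocket by overlap
or largest VD rather than by count alone.

## Ligand descriptors

`molecular_weight()` sums standard average atomic masses (IUPAC 2021
abridged values) over all atoms; hydrogens must be explicit, because
implicit-hydrogen guessing silently hides valence errors. A bond is
counted rotatable when it is a non-ring single bond between two
non-terminal heavy atoms, neither end participates in a triple bond, and
it is not an amide C-N bond; the amide exclusion is a switch
(`exclude_amide`) because conventions differ between tools. This
definition reproduces the published counts for the ligand structures
shipped as fixtures (built from their systematic names); for compounds
whose published values disagree with the standard structure the package
reports its own computed value rather than hiding the discrepancy.

## The synthetic generator

`generate_ensemble()` emulates what a docking engine hands the pipeline:
a reference conformation perturbed to controlled true RMSDs (random rigid
rotation about the heavy-atom centroid plus translation, amplitude found
by bisection to within 0.01 Å, the achieved value recorded as ground
truth) and scored as `score_slope * true_rmsd + N(0, score_noise_sd)`.
With zero noise the score is a perfect oracle of pose quality; the noise
parameter moves the score-RMSD correlation continuously from 1 towards 0.
`generate_benchmark()` assembles the full study design - a panel of
complexes, each in triplicate, top 10 poses - together with a truth table
written independently of the pipeline under test, so recovery tests never
re-derive ground truth from the code they are checking. All generators
are pure functions of their specification including the seed (seeding via
`withr::with_seed`, leaving global RNG state untouched).

What the generator does *not* emulate: physically realistic energetics,
torsional flexibility (perturbations are rigid-body by design, keeping
the achieved RMSD controllable by one-dimensional bisection and the
molecular graph trivially intact), correlated score errors, or receptor
rearrangement. A passing recovery test therefore demonstrates that the
bookkeeping - classification, ranking, recurrence, matrices - is exact,
not that any docking engine is accurate.

Test problem sizes: the recovery suite runs 30 complexes × 3 replicates
(the study's own panel size) at zero and moderate score noise; the
symmetry oracle compares against brute-force enumeration on >100 random
molecules of up to 7 heavy atoms, where full enumeration over
element-preserving bijections is exhaustive; the grid convergence suite
spans 1.0-0.25 Å on cavities of ~125-150 ų.

## Numerical choices and degenerate inputs

* Kabsch superposition rejects collinear point sets (second singular
  value below 1e-8 of the largest): the rotation about the line is
  undetermined. Orthonormality and det = +1 are enforced to 1e-8.
* `perturb_pose()` on a single-atom molecule in rotation-only mode is an
  error (the target is unattainable), as is a target beyond the reach of
  the perturbation amplitude.
* Empty pose ensembles, empty pockets, empty result tables and empty
  binding sites are errors, never silently empty outputs.
* Distance-shell and classification boundaries use `<=` comparisons with
  no epsilon: inputs are physical coordinates, not accumulated sums.
* Grids larger than `max_grid_points` (default 2·10⁷) abort with a
  suggestion to coarsen the spacing rather than exhausting memory.

## Limitations

The pipeline evaluates poses; it neither runs docking engines nor
prepares structures (protonation, bond-order assignment, missing loops
are upstream concerns). Residue pairing requires identical residue
numbering between crystal forms, which holds for deposited structures of
the same protein but not across homologues. The pocket metrics are a
documented re-specification of a published grid method, not a bit-exact
replica. ECIDAL constraints are plain distance contacts; angular or
chemistry-aware interaction definitions are out of scope.
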