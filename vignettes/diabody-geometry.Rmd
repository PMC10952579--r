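---
title: "Geometric descriptors of diabody solution structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric descriptors of diabody solution structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgeom)
```

## The problem

Diabodies are engineered antibody fragments: two chains, each a V_H and V_L
domain joined by a short linker, dimerize into two inter-chain Fv binding
sites. Unlike a Fab, the two Fvs share only a small artificial V_H-V_H
interface, so the relative orientation of the two binding sites is a soft
degree of freedom — one that directly determines how the two bound antigens
are positioned relative to each other. Characterizing that orientation, and
how engineering choices (interface disulfide bonds, the residue at the
Kabat H83 position) rigidify or shift it, requires quantitative per-frame
descriptors that work identically on crystal structures and on molecular
dynamics ensembles.

`dbgeom` implements three inter-Fv descriptors, one intra-Fv packing
descriptor, and a CDR-loop ensemble toolchain, plus synthetic generators
with analytic ground truth that make every stage testable without any
deposited data.

## The descriptors

**Four-tryptophan dihedral.** Each variable domain carries a conserved
buried tryptophan (Kabat W36 in V_H, W35 in V_L). The signed IUPAC torsion
over the four anchor CA atoms, ordered so the central virtual bond spans the
V_H-V_H interface (`V_L^A - V_H^A - V_H^B - V_L^B` by default), is a single
angle summarizing the inter-Fv twist. The package does not assign Kabat
numbers: anchors are explicit `(chain, resno)` references in the config,
because numbering-scheme assignment is a separate problem and the systems of
interest have fixed sequences. The anchor ordering is configurable
(`dihedral_order`).

**Pseudo-dyad axis and diabody angle.** V_H and V_L within one Fv are
related by an approximate two-fold. Superposing the V_H CA atoms onto their
V_L equivalents (an explicit residue-equivalence table in the config — a
deterministic correspondence-based least-squares fit rather than a
sequence-independent aligner, since the compared systems share sequences)
yields a rotation whose unit eigenvector with eigenvalue 1 is the pseudo-dyad
axis. Rotations under 0.5 degrees have no meaningful axis and raise an
error. To avoid the sign ambiguity of an axis, each axis is oriented by a
C-to-N rule: its dot product with (N-terminal anchor CA minus C-terminal
anchor CA) of the configured chain is made positive; the heavy chain's
first/last selected residues are the default anchors because the two domains'
termini can disagree and the choice must be explicit. The *diabody angle* is
the angle between the two oriented site axes, symmetric in site order.

**Sphere projection.** A canonical reference frame is built from one Fv's
beta-sheet CA atoms: hinge-residue CA centroid at the origin, the oriented
pseudo-dyad axis along +z, and the V_H sheet centroid spun to azimuth
theta = 0. Each frame is superposed onto this reference via one site's sheet
CA; the other site's V_H and V_L centers of mass are then projected onto the
unit sphere and reported as (theta, phi). Both alignments are computed per
frame ("dual projection"), doubling the statistics. Two conventions are ours
and documented rather than inherited: (i) the azimuth gauge (theta = 0 at
the V_H sheet centroid) — absolute theta values are therefore comparable
only between runs sharing a reference; and (ii) the center of mass defaults
to unweighted CA atoms of the domain's residues, consistent with the
CA-based reference and robust to missing side chains (a mass-weighted
all-atom option exists).

**VH-VL packing (six measures).** The relative orientation of the two
cylindrical variable domains is summarized by a distance `dc`, a torsion
`tor`, and four bend angles `a1..a4`. The canonical vector construction is
fixed by this package: each domain's reference sheet CA set defines a long
axis L (first principal axis) and in-plane perpendicular P (second), both
sign-fixed toward the N-terminal sheet residue; per frame the reference
domain is superposed onto the model domain to transfer L and P, and the
measures are taken against the inter-centroid segment. Values are
deterministic and comparable across runs sharing a reference, but not
numerically identical to any external implementation of the same idea —
distribution *shifts* between systems, which are the scientifically
meaningful output, are preserved under any fixed convention.

## CDR-loop ensemble analysis

Backbone phi/psi torsions of configured loop ranges are extracted per frame
(IUPAC, terminal torsions lacking a flanking residue excluded identically in
every frame). The dissimilarity between two loop conformations is the
circular dihedral distance

    d(a, b) = 2 (1 - cos(a - b)),   D(A, B) = sum_r d(phi_r) + d(psi_r),

evaluated on the raw angle differences (the cosine makes wrapping
unnecessary); each term is bounded in [0, 4]. Frames are clustered by
agglomerative average linkage cut at a fixed height; cluster centers are
*medoids* (the member minimizing summed within-cluster distance, ties to the
lowest frame index) because means are ill-defined for circular data. The
implementation delegates to `hclust(method = "average")`/`cutree` and is
verified, in the test suite, against a brute-force agglomerative oracle that
recomputes all pairwise average linkages at every step.

Loop PCA uses (cos, sin) of every torsion as features — circular-safe — and
fits components on the *pooled* frames of all compared systems, so the
per-system landscapes share one basis and are directly comparable
(per-system fitting is a special case with one ensemble). Landscapes are
`-ln(p / p_max)` on a 2D histogram of components 1-2 (default 60 x 60 bins);
empty bins are missing values, not infinities. Smoothed distributions of the
scalar descriptors use Gaussian kernel density estimation with Silverman's
bandwidth — deterministic and standard, with an explicit bandwidth override —
rather than a parametric curve fit, whose functional form would otherwise be
an arbitrary choice.

## Synthetic systems and what passing tests show

No trajectories are deposited for the motivating systems, so validation is
by parameter recovery on fully specified constructs:

* `build_toy_fv()` builds a two-domain Fv analog from ideal-geometry
  backbones (standard bond lengths/angles, omega = 180), with V_L the exact
  image of V_H under a 180-degree rotation about the dyad axis. The C2 is
  exact by construction, so the measured pseudo-dyad axis equals the stored
  one to machine precision.
* `build_toy_diabody(dihedral, angle)` places a rigid copy as site B by an
  analytic two-step: tilting the copy's dyad axis by the requested angle
  fixes the diabody angle exactly (the residual spin is about the tilted
  axis itself and cannot change it), and the spin is the closed-form root of
  a linear-in-(cos, sin) equation that sets the four-anchor dihedral.
  Infeasible pairs — any nonzero dihedral with parallel or antiparallel
  axes — are rejected, not projected.
* `sample_trajectory()` draws per-frame (dihedral, angle) from von Mises
  mixtures (Best-Fisher sampler; R's seeded RNG stream) and re-poses site B
  per frame. The defaults (unimodal mean 120 deg, kappa 20 for the dihedral;
  110 deg, kappa 50 for the angle; bimodal checks use means 60/150 deg,
  kappa 50) emulate the unimodal-to-bimodal circular distributions such
  ensembles display in solution, with angles inside the 60-160 degree range
  reported for real diabodies. The angle mixture is folded into [0, 180]
  since the diabody angle is polar, not circular. The scaffold is rigid
  across frames by default, which is what makes the generator's predicted
  sphere projections exact ground truth; with torsion noise the scaffold is
  rebuilt per frame and placement re-solved, keeping dihedral/angle truth
  exact while the projection prediction is omitted.
* `sample_torsion_ensemble()` draws loop torsion vectors from wrapped-normal
  mixtures with recorded labels, the ground truth for clustering and PCA
  recovery.

Every generator returns a machine-readable truth record, and all recovery
tests consume only that record. What passing tests demonstrate: the
descriptor pipeline is exact on rigid geometry, invariant under global rigid
motion, and recovers known mixture structure. What they do not demonstrate:
behavior on real proteins with missing atoms, alternate conformations,
inexact symmetry, or sheet masks of unequal size between sites — the
structure readers handle these inputs, but accuracy claims there are limited
to the rigid-body mathematics.

## Numerical choices and edge cases

* Angles are degrees at every API boundary, radians internally; dihedrals in
  (-180, 180], polar angles in [0, 180], azimuths in [-180, 180) with
  theta = 0 reported at the poles.
* Superposition is Kabsch via SVD with the proper-rotation determinant
  correction; degenerate (collinear) point sets are errors.
* `rotation_axis` takes the real eigenvector with eigenvalue closest to 1
  and fixes the sign so the first non-vanishing component of (z, y, x) is
  positive; domain orientation (the C-to-N rule) is applied by callers.
* Altloc policy on PDB input: first listed altloc wins, occupancies ignored;
  HETATM excluded; insertion codes honored; no renumbering.
* Anchor residues that are not tryptophan warn rather than error (engineered
  variants substitute them); missing residues or atoms are errors.
* Linkage ties in clustering are broken by the smallest lexicographic pair
  index (in practice by `hclust`; the oracle equivalence tests use
  continuous random matrices where ties have measure zero).
* Frames that fail per-frame descriptor evaluation fail fast by default;
  `dual_projection(on_error = "skip")` logs and drops them.

## Problem sizes

The shipped analyses and tests use 12-residue pseudo-domains, ensembles of
300-1000 frames, clustering oracles up to n = 12 over 200 random matrices,
and torsion ensembles of 400 frames — sizes chosen so the full validation
runs in about two minutes while every claim above is exercised at its stated
tolerance.

## Known limitations

* Kabat/Chothia/IMGT numbering, sequence-based domain detection, and
  structure repair are out of scope; configs carry explicit residue
  references.
* Absolute sphere-projection azimuths depend on this package's reference
  gauge and are not comparable to coordinates reported against other
  references (polar angles phi are).
* The six-measure packing descriptor is not bit-compatible with external
  cylindrical-domain tools; compare distributions within one convention.
* mmCIF input is not implemented; PDB (single- and multi-model) and DCD
  trajectories are.
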