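---
title: "Methods: automated N-glycan curation in crystallographic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated N-glycan curation in crystallographic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models and rules
it implements, the parameters that matter, the design decisions that were
genuinely open, and what the synthetic test bed does and does not
demonstrate about real data.

## The curation problem

An N-glycan is a rooted tree of pyranose residues covalently bonded to the
ND2 atom of an asparagine inside the sequon Asn-X-Ser/Thr (X anything but
proline). In deposited crystal structures these trees are often incomplete,
geometrically wrong (boat or skew rings, inverted anomers), chemically
misnamed (the α-anomer code NDG where the root must be β-NAG), or
disconnected from the protein because the covalent LINK record is missing.
`recarb` treats curation as a pipeline over a structure model plus a
real-space density map: detect missing links, validate rings, crop what is
bad, rebuild and extend what the density supports, and keep whichever tree
— old, new, or a graft of both — validates best.

## Covalent-link generation

For each NAG or NDG whose C1 is not covalently linked, asparagines with ND2
within `search_radius` (6.0 Å) of C1 are candidates. If OD1 of a candidate
is nearer C1 than ND2, the side-chain amide is flipped before evaluation;
the flip is persisted only when a link is accepted, because the accepted
bond chemically requires the nitrogen at that position. Three filters
follow, in order: (i) the asparagine must head a modeled sequon; (ii) if
ND2–C1 exceeds `direct_bond_max` (4.0 Å) some other atom of the sugar must
lie within `secondary_atom_max` (3.5 Å) of ND2 — this rescues sugars whose
ring is rotated so that C1 faces away; (iii) if more than one asparagine
survives, no link is generated. On success the leaving atom (O1, or O1L in
NDG) is deleted and the declared link distance is the actual ND2–C1
distance. Candidates with a missing ND2 or OD1 atom are disqualified, and an
asparagine whose ND2 already carries a link is never a candidate, so a
single run cannot give one amide two bonds. Distances here are evaluated
without symmetry expansion: a genuine N-glycosidic bond is intramolecular.
An NDG that ends up Asn-linked is renamed to NAG — the root of an N-glycan
is the β-anomer by chemistry, so the α assignment is a naming error.

## Ring validation

Puckering is described by the Cremer–Pople parameters for six-membered
rings, computed in the canonical O5, C1, C2, C3, C4, C5 order: out-of-plane
displacements `z_j` are taken along the normal of the mean plane constructed
from the two Fourier sums about the geometric centre (so that `sum(z_j)` is
exactly zero), and

* `q2, phi2` come from the second Fourier component,
* `q3 = sqrt(1/6) * sum((-1)^j z_j)`,
* `Q = sqrt(q2^2 + q3^2)`, `theta = acos(q3/Q)`.

The mean-plane normal is oriented so that the ideal ⁴C₁ chair — O5 displaced
above the plane, alternating signs around the ring — scores θ = 0 exactly;
inverting all displacements gives the ¹C₄ chair at θ = 180°. Because the
six L-fucose atoms are traversed in the same canonical order, FUC/FUL in
their proper chair sit at the 180° pole. A planar ring (Q below 1e−8) has no
defined θ and is reported as degenerate rather than given an arbitrary
angle.

The three-tier status emulates the consumer side of a yes/check/no ring
validator: **yes** requires the pucker within 30° of the expected pole, a
geometric anomer at C1 matching the component code, and a complete ring;
**check** is granted when the only defect is a pucker in the soft band
30°–45° from the pole; anything else is **no**. The 30°/45° windows are this
package's convention, chosen so that ideal chairs and mildly distorted ones
validate while boats and skews (θ near 90°) never do; they are deliberately
not tied to any external program's internal boundaries, and the acceptance
tests avoid boundary values. The geometric anomer is the sign of the
determinant of (O5−C1, C2−C1, X−C1), where X is the exocyclic anomeric
substituent (the link partner of C1, or O1); the sign depends only on
configuration, the reference signs are fixed by the package's ideal
templates, and L-sugars flip them. When no substituent is resolvable the
anomer check is skipped rather than guessed.

## Density model and scores

Model maps are sums of per-atom Gaussians derived from four-term
Cromer–Mann X-ray form factors: each term contributes
`a_i (4π/(b_i+B))^{3/2} exp(−4π² r²/(b_i+B))`, with the constant term
treated as a narrow Gaussian broadened by B, occupancy weighting, and
accumulation on a periodic grid over the unit cell (triclinic cells
supported through the standard orthogonalisation convention). When a
resolution is supplied, the grid is band-limited by zeroing Fourier
coefficients beyond 1/d_min. Hydrogens are ignored throughout, and only the
highest-occupancy conformer of each atom is used.

Three per-residue scores drive acceptance:

* **RSCC** — the Pearson correlation of observed and calculated map values
  over grid points within `mask_radius` (2.0 Å) of any residue atom. It is
  invariant to affine rescaling of either map, so no map scaling step is
  needed.
* **EDIAm** — per-atom electron-density support aggregated with a power
  mean of exponent −2, which drags the residue score toward its worst
  atoms. The per-atom EDIA is an emulation documented in full here: the
  atom radius is computed on the fly as
  `r = sqrt(ln 20 · (B + 15 + 4 d_min²)) / 2π` (a single-Gaussian width
  combining the B factor, an intrinsic form-factor width of 15 Å², and
  resolution broadening; "ln 20" places the radius at the 5%-of-peak
  contour). Density values are read from the σ-normalized observed map and
  capped at ±1.2σ. A parabolic weight `1 − (d/r)²` integrates capped
  density over the core sphere with ownership weighting (a grid point
  belongs to the relatively nearest atom); a negative penumbra between r
  and 2r penalises positive density claimed by no atom, at half weight. The
  result is floored at zero.
* **Density ratio** — mean observed density at the residue's atom centres
  divided by the mean over all protein main-chain N, CA, C, O atoms.

All carbohydrate B factors are overridden to `b_override` (30.0 Å²) before
the model map for scoring is computed. This compensates for the lack of
B-factor refinement of newly built sugars: with a constant, relatively low
B, good scores are only attainable where the experimental map actually has
density at decent contour levels, and the scores become independent of
whatever B values the input model carried (a property the test suite
asserts exactly).

A newly built residue is kept when its ring status is yes, it does not
clash (< `sym_clash`, 2.1 Å) with symmetry images of pre-existing atoms,
and it passes the density rule: RSCC ≥ 0.70, or RSCC + EDIAm > 1.20, or —
only at resolution better than 3.0 Å — RSCC in [0.60, 0.70) with density
ratio ≥ 0.25. The borderline branch is disabled at low resolution because a
sugar-sized blob of smooth density is too easy to find there. Discarding a
residue discards its descendants. The symmetry check uses genuine symmetry
images only (non-identity operator or non-zero lattice translation): the
root C1 is covalently bonded to a pre-existing ND2 at ~1.4 Å inside the
asymmetric unit, so an identity-inclusive check would reject every root.

## Templates and tree building

Monosaccharide templates are generated in code from canonical chair
internal coordinates: ring bonds ~1.43 Å (hexagon radius 1.35 Å,
alternating ±0.23 Å displacements), substituents on ideal tetrahedral
axial/equatorial directions according to each sugar's configuration
(glucosamine, mannose, glucose, galactose-like fucose), N-acetyl groups on
C2 where the component demands them, and L-sugars built as mirror images,
which places FUC/FUL in ¹C₄ as required. Each template carries its leaving
atom; placement drops it, since the glycosidic bond replaces it.

A child residue is placed by positioning its C1 at ideal bond length and
angle from the parent attachment atom (O2/O3/O4/O6, or ND2 with anchor CG
for the root), then rigidly orienting the template by two glycosidic
torsions (φ about the new bond, ψ about the attachment bond). Six candidate
(φ, ψ) pairs per linkage position — drawn from published glycosidic torsion
preferences, with the first pair of each list the "ideal" used by the
fixture generator — are scored by the mean interpolated σ-level over the
placed atoms; a ±20° grid refines the best pair, and a deterministic local
rigid-body refinement (greedy coordinate ascent: rotations about C1, which
preserve the bond, plus translations capped at 0.35 Å of C1 displacement)
polishes the pose against the map. The rigid step is what makes placement
robust to ordinary coordinate error in the parent anchor atoms; without it
a slightly wrong anchor frame propagates into a misoriented ring that the
torsion grid cannot fix.

Local acceptance requires the mean **and the median** atom σ-level to reach
`local_threshold` (0.6σ) and no hard clash (< 2.1 Å) with any existing atom
except the bonded attachment atom itself. The median criterion demands that
at least half the atoms are individually supported, which rejects poses
whose "support" is entirely the density skirt of a neighbouring residue;
the mean alone is fooled by one atom sitting on a tall neighbouring peak.
The threshold is deliberately permissive — the pipeline's RSCC/EDIAm
filters are the real gate.

Tree growth is a breadth-first walk over the open productions of the
selected grammar: core productions before branches, position 4 before 3
before 6, fucoses last, one child per parent position, every possibility
attempted exactly once. There is no randomness anywhere in the builder, so
identical inputs give identical trees.

The five tree grammars are shipped as a JSON production table
(`inst/extdata/tree_types.json`): all share the eukaryotic five-residue
core; high-mannose adds α1-2/3/6 mannose extensions and core fucoses,
the hybrid and complex types add β1-2/4/6 GlcNAc antennae and a bisecting
GlcNAc, with mammal versus plant distinguished by α1-6 versus α1-3 core
fucosylation. The table follows the published tree types of the Coot
carbohydrate module restricted to this package's monosaccharide vocabulary
(no galactose, xylose or sialic acids). Tree-type selection is global per
model: the default is high-mannose with fucoses enabled, overridden by the
type whose productions cover the most existing beyond-core residues; ties
break high-mannose first, then mammal before plant — a stated convention,
since no external rule defines the tie order.

## Pipeline orchestration

The stage order is: link detection → NDG renaming → tree extraction →
tree-type selection → cropping (status check/no, nonstandard components,
and all their descendants; a tree whose root falls is queued for whole-tree
addition) → temporary deletion of blockers (detached sugar chains within
2.5 Å of a site of interest, unlinked single sugars of the six allowed
types NAG/NDG/MAN/BMA/FUC/FUL, and **all** waters) → extension of existing
trees → whole-tree addition at remaining sequon sites (skipping asparagines
carrying a chitobiose, to avoid building a second tree on one amide) →
scoring and filtering of new residues → per-site comparison of old and new
trees → grafting → restoration → renumbering.

The old-versus-new comparison counts (yes, check, total) per tree; more
"yes" wins, then more "check", then more residues, and a full tie keeps the
new tree. When the new tree wins at a rebuilt site, old branches that were
deleted only because an upstream residue was cropped (their own status was
yes) are graft candidates: the branch root's C1 must lie within 2.5 Å of
the rebuilt parent's attachment oxygen — slots are matched by the path of
linkage positions from the root, and the bonded C1–oxygen pair is exempt
from the clash test — and the restored branch must not approach any newly
built residue closer than 2.0 Å. Restoration of parked molecules uses a
symmetry-aware 2.5 Å clash rule against new residues, per molecule for
waters and single sugars, all-or-nothing for detached chains. New residues
whose identifiers collide with restored ones are renumbered to the lowest
free number ≥ 401 in their chain; on flat-B models the carbohydrate B
factors are finally set to the flat value.

Conservation holds by construction and is asserted in the tests: every
input residue ends up exactly one of kept, permanently deleted (reported),
or restored; and a second pipeline run on an all-"yes" output builds and
deletes nothing.

## The synthetic test bed

`make_glycosite()` builds a short idealized peptide (fixed extended-strand
φ/ψ, ideal bond geometry) containing an Asn-Ala-Thr sequon, grows an ideal
glycan tree with the same templates and the ideal torsion of each linkage,
boxes everything in a P1 cell with 8 Å padding, synthesizes the "observed"
map from this ground truth at the requested resolution, σ-normalizes it,
adds white Gaussian noise (default 0.1σ) and renormalizes. The working
model is the truth minus cropped residues plus white coordinate jitter of
0.1 Å per coordinate by default — the typical positional error of a refined
structure near 2 Å resolution; a working model with zero coordinate error
would make rebuilding a deterministic replay of the generator, which shares
its templates with the builder. All randomness flows from the single seed,
and the same seed reproduces the fixture bit-identically.

What the fixtures do **not** emulate, and what passing tests therefore do
not show about real data: crystallographic noise is spatially correlated,
not white; real cells are densely packed, so σ-levels at atoms are a few σ
rather than the much higher contrast of a small fragment in a mostly empty
box; B factors vary and rise along the glycan; real sugars deviate from
ideal template geometry; and there is no bulk solvent, no reciprocal-space
refinement between stages, and no experimental phasing error. The recovery
experiments (rebuild of a cropped five-residue core at 2.0 Å/0.1σ, with
degradation at 3.5 Å/0.3σ) demonstrate the machinery end to end under
controlled conditions, not performance on deposited structures.

## Numerical choices and degenerate inputs

* Grid spacing defaults to 0.5 Å; fixture maps are roughly 70×60×90 points.
  Map interpolation is tri-linear and periodic.
* The atom-accumulation cutoff is where the widest Gaussian falls to 1e−4
  of its peak; atoms of unknown element get nitrogen-like factors with a
  warning.
* σ-normalization is over the full cell; a flat map cannot be normalized
  and errors out rather than dividing by ~0.
* An empty RSCC mask, an empty atom set in a symmetry query, or a missing
  protein main chain for the density ratio produce explicit undefined
  signals (NA / non-finite with a flag), never silent zeros.
* EDIAm returns 0 as soon as any atom's EDIA is ≤ 1e−6: with a power mean
  of exponent −2 an unsupported atom dominates, and the explicit floor
  avoids division blow-ups.
* Links that would close a cycle during tree extraction are dropped with a
  warning; the tree stays acyclic.
* Alternate locations: the highest-occupancy conformer wins, first in file
  order on ties. Insertion codes are preserved; residue identity is always
  the (chain, seq, ins) triple.
* Renumbering assigns the lowest unused number ≥ 401 per chain — the scheme
  is a convention; only the need for it is externally imposed.

## Known limitations

The builder has no real-space refinement of the protein: updating the
asparagine and its flanking residues after building reduces to persisting
the amide flip. Reciprocal-space refinement, R-factor accounting,
reflection-data I/O, electron scattering factors, O-glycosylation,
homology-driven site discovery and chitobiose remediation are out of scope.
The EDIA radius profile and the yes/check/no windows are documented
emulations, not clones of any external program's internals; scores agree
qualitatively, not digit-for-digit, with those tools.
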