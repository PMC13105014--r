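---
title: "Cross-beta fibril geometry: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-beta fibril geometry: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

## The geometry this package computes

Amyloid fibrils are helical stacks of peptide molecules. A deposition
describes one polymorph by a helical **twist** (degrees per repeat) and
**rise** (Angstrom per repeat), plus a symmetry class relating the two
cross-beta subunits (protofilaments) of the core: an exact two-fold
(**C2**), an approximate two-fold screw (**pseudo-2~1~**, twist near
±180°), or no symmetry at all (**C1**, conformationally inequivalent
subunits). In projection images the same fibril shows a periodic width
modulation whose period, the **cross-over distance** *d*, is the axial
distance over which the cross-section rotates by 180°:

$$ d = \frac{\text{rise} \times 180^\circ}{|\tilde\theta|}, $$

where $\tilde\theta$ is the *net* rotation of the cross-section per
repeat. For a pseudo-2~1~ screw the deposited twist contains a 180°
screw component that does not rotate the apparent cross-section, so
`fold_twist()` first reduces the twist modulo 180° into (−90°, 90°]:
−181.75° folds to −1.75°, and with a 2.34 Å rise gives *d* = 24.07 nm.
An exactly ±180° screw folds to zero: the fibril is apparently
untwisted, and `crossover_distance()` returns `Inf` rather than raising
an error, because untwisted fibrils are an observable state, not a
degenerate input.

Two sign conventions deserve explicit statement:

* **Twist sign does not encode handedness.** Published tables list
  right-handed fibrils with both +181.18° and −0.79° twists. Handedness
  is stored as metadata and never inferred from the sign.
* **Near-180° screws have two equivalent representatives.** A rotation
  of −181.75° and one of +178.25° are the same rigid motion, and
  published tables mix the two styles. When `fit_helical_params()`
  recovers a pseudo-2~1~ screw from coordinates it reports the
  representative whose sign matches the folded net rotation (folded
  −1.75° → −181.75°; folded +1.18° → +181.18°). Comparisons across
  conventions should go through `fold_twist()`.

## The twist-strain model

A cross-beta structure spaces molecules by *b* = 0.48 nm along the
growth axis (the default carries the reported ±0.01 nm uncertainty as a
tunable parameter). A cross-over distance *d* therefore requires an
inter-molecular rotation $\rho = b\pi/d$ radians. If the conformationally
ordered segment of each molecule is extended with length *L* and
centered on the axis, rotation moves the segment *ends* apart, and the
intermolecular distance at the N- and C-terminal ends grows to

$$ s = \sqrt{b^2 + L^2 \sin^2(\rho/2)}. $$

`end_spacing(7.3, 25)` gives 0.528 nm and `end_spacing(5.3, 25)` gives
0.506 nm — the model's two worked examples. Since backbone hydrogen
bonds tolerate only modest stretching, large *s* values disfavor the
combination of long ordered segments with rapid twist;
`max_ordered_length()` inverts the relation to give the longest segment
compatible with a tolerated end spacing. The package takes *L* as the
Cα-to-Cα distance between the first and last ordered residues. This is
an operational choice: the source data state segment lengths for
extended conformations without defining the measurement, and end-to-end
distance of the ordered span is the closest well-defined reading. For
strongly curved folds it underestimates the path length.

## Organizing atomic models

`read_fibril_model()` parses PDB and mmCIF files through bio3d,
retaining every model of a multi-model bundle (deposited fibril bundles
carry 10 independently refined structures, which this package uses to
attach mean ± circular-SD statistics to torsions and distances). Nothing
is assumed about the orientation of the deposited coordinates:
`infer_layers_and_subunits()` always fits the growth axis from the screw
transforms between equivalent chains, recovered by optimal rigid
superposition followed by rotation-axis extraction. Chains group into
subunits when they superpose within 1.0 Å *and* the rotation relating
them is below 90°; the companion subunit is always ~180° away, and the
inequivalent subunits of a C1 polymorph fail the RMSD test outright.
The C1 declaration threshold in `fit_helical_params()` is an
ordered-core RMSD of 1.5 Å after optimal superposition — configurable,
and chosen well above coordinate noise but below genuine conformational
differences. With chain copies carrying independent coordinate noise
$\sigma$, two copies superpose at about $\sigma\sqrt 6$, so the
grouping threshold should be raised accordingly for noisy inputs
(`same_rmsd` argument).

## Beta-strand assignment

The strand rule is hydrogen-bond based: a **beta-strand segment** is at
least three consecutive residues whose backbone amide *and* carbonyl
groups hydrogen-bond to neighboring chains, on axial sides that
alternate from residue to residue. "Side" is operationalized as the sign
of the axial component of the C=O vector — in a cross-beta sheet the
carbonyls point alternately up and down the fibril axis, which is the
geometric content of the alternation rule.

Deposited models carry no hydrogens and no published hydrogen-bond
criterion accompanies the rule, so the criterion is a package decision,
stated and configurable: the amide H is inferred at 1.01 Å from N,
antiparallel to the preceding carbonyl (the trans peptide plane), and a
bond requires N···O ≤ 3.5 Å with an N–H···O angle ≥ 120°. A
Kabsch–Sander energy criterion (cutoff −0.5 kcal/mol) is available as an
alternative (`mode = "dssp"`); on idealized sheets the two agree almost
everywhere. Segments for a bundle are the majority vote across bundle
models and across *interior* chains — boundary chains necessarily lack
half their hydrogen bonds and would veto every strand if counted.

## Contacts, axes, comparisons

Inter-subunit contacts are residue pairs whose minimum sidechain
heavy-atom distance is at most 5.0 Å (bundle mean of per-model minima),
classified hydrophobic when both sidechains are apolar
(A, V, L, I, M, F, W, P), salt bridge when acidic oxygens meet basic
nitrogens within 4.0 Å, polar otherwise. The K28–D23 salt bridge check
uses the Lys NZ to Asp OD minimum with the same 4.0 Å default; reported
dynamics-averaged distances near 3.3–3.5 Å sit comfortably inside it.
All cutoffs are arguments, recorded into pipeline reports.

The **major molecular axis** runs from the Cα of the first ordered
residue to the Cα of the last; its angle to the plane perpendicular to
the growth axis is the per-subunit tilt, and the angle between the two
subunits' axes (folded into [0°, 90°]) is the **herringbone angle** —
exactly twice the tilt when the subunits are exact two-fold images.

`superpose_rmsd()` deliberately separates the *fit* range from the
*score* range, because published comparisons align on one residue
window and report RMSD over another. Superposition is a proper-rotation
Kabsch fit; the test suite checks it against an independent closed-form
quaternion solution, and checks the dihedral code against an
independent four-point formulation, at 10⁻⁶ Å and 10⁻⁹ degrees
respectively. Torsion comparisons are circular throughout (a phi of
179° vs −179° differs by 2°), and differences are flagged when they
exceed the combined bundle SDs with a 0.01° numerical floor.

## What the synthetic generator emulates — and what it does not

`generate_fibril()` builds idealized in-register cross-beta stacks from
a planar Cα trace (the built-in template is a 40-residue U-shaped trace
with the turn at residues 23–29 and the two strands facing across
~9.6 Å; its coordinates are package fixtures, not measured values).
Layers are placed by exact screw operators; designed strand residues
receive axially alternating carbonyls, a pleated amide nitrogen, and
inter-layer N···O distances near 3.1 Å; turn residues keep in-plane
carbonyls and stay out of axial register. Sidechains are reduced to a
Cβ plus the charged tips of K28 and D23 placed at a designed
salt-bridge distance. All randomness (coordinate noise) flows from one
integer seed, outputs are byte-reproducible, and the generator restores
the caller's RNG state.

This idealization supports exact ground-truth tests: refitting recovers
twist and rise to 10⁻⁶, designed strands are recovered with precision
and recall 1 at zero noise, width-profile minima reproduce the analytic
cross-over within a few percent, and the measured end-of-segment
spacing in a generated two-layer stack reproduces the twist-strain
formula to better than 1%. It does *not* emulate realistic sidechain
packing, rotamers, solvation, bent or kinked protofilaments, or
cryo-EM image formation; passing tests demonstrate the correctness of
the geometry pipeline, not the realism of the template. One physical
feature carries over faithfully: at rapid twists the lateral
displacement between stacked copies grows linearly with radius, so
hydrogen bonds at the ends of a long flat template genuinely break —
the strain model's mechanism. Strand-recovery ground-truth tests
therefore use slow-twist specs, where the designed bonds are unstrained.

## Numerical choices

* Rotation-axis extraction switches from the antisymmetric-part formula
  to the +1 eigenvector of the rotation above 175°, where the former
  loses precision; both paths yield signed angles in (−180°, 180°].
* Width profiles bin atoms along the fitted axis (4 Å bins), smooth
  with a 9-bin running mean, and accept minima with prominence at least
  10% of the modulation range; untwisted profiles report "no minima"
  rather than fabricating a spacing. Reliable detection needs roughly
  three cross-overs of fibril length — the same requirement a
  microscopist faces — and the validation suite generates fibrils of
  that length (up to ~960 layers at *d* = 150 nm, Cα-only).
* Circular means use the resultant-vector direction; circular SDs use
  $\sqrt{-2\log \bar R}$. Undefined torsions (chain ends, missing
  atoms, collinear geometry) are `NA`, never 0, and are excluded from
  deviation calls.
* Beta-deviation windows (ϕ −130° ± 30°, ψ 130° ± 30°) are
  boundary-inclusive and use circular distance, so angles near ±180°
  are handled without artifacts.

## A worked characterization

```{r example}
## cross-over algebra from published helical parameters
tab <- crossover_report(ab40_polymorphs())
tab[, c("name", "twist_deg", "rise_A", "net_twist_deg", "crossover_round_nm")]

## a synthetic C2 fibril, characterized end to end
m <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3,
                                 tilt_deg = 3.5))
characterize_fibril(m, ordered_range = c(14, 36))
```

## Limitations

Deposited coordinate bundles are not shipped with the package; checks
against published per-deposition annotations (an RMSD of 3.18 Å between
two particular polymorphs, named contact sets, published strand tables)
run only when the user has populated a local accession cache, and the
offline validation rests on the synthetic ground truths above. The
strand rule and contact classes depend on stated, configurable cutoffs;
they reproduce idealized geometry exactly, but real deposited models
sit near criterion boundaries and can shift between neighboring
assignments with small cutoff changes. Handedness is never determined
by this package — that requires density maps, which are out of scope.
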