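---
title: "Blueprint arithmetic, idealized backbones and validation metrics for ovoid TIM barrels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blueprint arithmetic, idealized backbones and validation metrics for ovoid TIM barrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoidtim)
```

## The model

A TIM barrel is a (β/α)₈ fold: eight parallel β strands close into a
barrel surrounded by eight α helices. Two integers fix the barrel's
coarse geometry: the strand count *n* and the shear number *S*, the
total residue register offset accumulated when the hydrogen-bond ladder
is traversed once around the closed barrel. Each adjacent-strand
junction contributes an integer register shift; the shear is their
cyclic sum. The classical relation

\[ \tan\alpha = \frac{S\,a}{n\,b} \]

(*a* = rise per residue along the strand, *b* = perpendicular
interstrand spacing, α = strand tilt from the barrel axis) is exactly
the condition that a flat sheet of *n* tilted strand lines closes onto
itself with offset *S*, and it fixes the wall perimeter
\(P = n\,b/\cos\alpha\).

An *ovoid* barrel keeps n = 8, S = 8 but breaks circular symmetry by
where it spends its register shifts. The twofold blueprint used
throughout this package has, per 114-residue repeat, strands of length
5, 5, 7, 7 with shifts of +2 at the junctions following the third and
fourth strand; each repeat contributes a shift of 4, and residue *i*
pairs with residue *i* + 114 in the other repeat. Because the shifts are
concentrated rather than spread uniformly, the cross-section relaxes
from a circle to an ellipse: the two long strand pairs lie along the
flat (major) faces and the short pairs along the tight-curvature (minor)
faces, where sterically small residues pack best. `enumerate_layers()`
and `enumerate_cbeta_strips()` expose the two natural coordinate systems
of the core: layers collect core-facing positions at one axial height
(the unit mutated in hollow-variant ablations), strips follow one ladder
rung around the wall, advancing by the local register shift at each
junction.

## Parametric backbone construction

`generate_barrel()` builds the wall in unrolled-sheet coordinates
(arc position *u* along the wall, height *v*, normal offset *w*) and
wraps them onto an ellipse:

- Strand *i*, ladder coordinate *t* = local index + cumulative shift:
  \(u = (i-1)\,b\cos\alpha + t\,a\sin\alpha\),
  \(v = -(i-1)\,b\sin\alpha + t\,a\cos\alpha\). At any fixed height the
  strand lines are spaced \(P/n\) apart, so arc-length placement is
  uniform by construction.
- The ellipse's semi-axes are scaled so its perimeter equals the closure
  perimeter *P*; `barrel_params(semi_major_a, semi_minor_b)` therefore
  sets the *aspect ratio* only (the default 13:9 gives a generating
  eccentricity of 0.721). The tight-curvature vertices are centred
  between strand pairs 1/2 and 5/6.
- CA atoms pleat alternately in *w* by ±0.94 Å so consecutive CA–CA
  distances are 3.8 Å while the rise along the strand stays 3.3 Å.
  Amide N and carbonyl C are placed collinearly on the CA–CA segments
  (1.35 Å and 1.00 Å from CA); strand carbonyl oxygens are aimed at
  their ladder-partner amides — even ladder rungs donate towards the
  next strand, odd rungs towards the previous one, the pleated-sheet
  alternation — which makes the hydrogen-bond ladder detectable by a
  plain N···O distance criterion. Cβ atoms point radially inward at
  core-facing and outward at exterior-facing positions (the first
  residue of strand 1 is core-facing; facing propagates across junctions
  because rung partners share a ladder coordinate).

`generate_full_timb()` adds helices and loops. Helices are ideal
(2.3 Å radius, 1.5 Å rise, 100°/residue), placed outside the wall at
`helix_radial_offset` (default 6 Å) between their flanking strands and
running antiparallel to the preceding strand; all helix arc positions
are evaluated at a common reference height so their spacing stays
uniform. Loops are circular arcs between their anchors with exactly
equal chord steps of 3.8 Å, bulging outward/up for strand-to-helix turns
and outward/down for helix-to-strand loops. A deterministic
position-based relaxation then nudges loop CAs out of crowded regions
(clearance 4.3–4.7 Å to fixed atoms, an i,i+2 bend-opening constraint of
5.2 Å) while projecting consecutive distances back to 3.8 Å. For
rotationally repetitive blueprints, later repeats are propagated from
repeat 1 by the exact repeat rotation, so twofold self-RMSD is zero by
construction; the dangling C-terminal loop inherits the shape of its
repeat-partner loop and ends one virtual bond before residue 1 (the
circular closure of the symmetric design), so the terminal residue pair
is treated as bonded by the clash check. Any remaining backbone pair
closer than 2.5 Å (2.3 Å for donor–acceptor N/O pairs) raises an error.

These are geometric idealizations: bond geometry is approximate,
carbonyl azimuths on helices and loops are arbitrary (and re-aimed if
they collide), and no physical energy is evaluated.

## Structure analysis

`assign_strands()` detects β residues by a DSSP-style bridge criterion
on backbone N···O contacts (≤ 3.5 Å, sequence separation ≥ 5): a
residue pair is a bridge when both ladder hydrogen bonds of either
bridge pattern are present. On the idealized backbone only alternate
rungs carry both bonds, so single-residue gaps between bridge residues
are closed, frayed ends are recovered by a single-bond extension step,
and isolated runs shorter than 3 residues are discarded.

`measure_shear_from_structure()` traverses the ladder once around the
barrel. Because strand spans (5–7 residues) are shorter than the shear
(8), a single closed walk along one rung does not exist; instead each
junction's register offset is measured as the median difference of
residue numbers over that junction's bridge pairs, and the cyclic sum —
whose strand-boundary terms telescope away — gives the shear. The
absolute value is reported, making the result independent of traversal
direction.

The barrel axis is the sign-aligned mean of per-strand principal
directions (bridge-core residues only, so loop-extended ends do not tilt
it); strand CA positions projected onto the normal plane are fitted with
the numerically stable direct least-squares ellipse fit, giving
semi-axes, eccentricity, per-strand radii (median radial distance) and
face labels. Faces follow the curvature convention: *minor* faces are
the 90° arcs of tightest curvature, centred on the fitted major-axis
vertices (on an ellipse the radius of curvature at the major-axis vertex
is \(b^2/a\), the smallest anywhere), so short strands receive minor
labels and the length-7 pairs major labels.

`superpose()` implements the closed-form least-squares rigid
superposition (SVD with determinant correction);
`repeat_symmetry_rmsd()` applies it to the CA sets of the two repeat
halves. `small_residue_enrichment()` quantifies "small residues at the
minor face" with mean residue volumes as the size proxy and a seeded
label-permutation test (default 1000 permutations, one-sided towards
smaller-at-minor).

## ILV clusters

`pairwise_contacts()` restricts to Ile/Leu/Val side chains (an extended
mode adds Ala/Met/Phe). A residue pair is a contact when its side-chain
heavy atoms come within 4.5 Å or bury at least 10 Å² of pairwise
surface; buried area is the two-body solvent-accessible-surface
difference at 1.4 Å probe, computed with a deterministic golden-spiral
Shrake–Rupley surface (960 points/atom — deterministic, so no seed is
needed; the point grid is fixed in the laboratory frame, giving areas a
small orientation-dependent quadrature error of a few Å² on ~100 Å²
contacts). Contacts are counted per residue pair, not per atom pair.
`build_clusters()` takes connected components of the contact graph above
an area threshold and reports per-cluster and total contacts, buried
area and area per contact. Generated fixtures carry idealized
pseudo-atoms (CG/CD positions along the CA→CB direction) for ILV
residues so these statistics are computable without rotamer building;
absolute areas on such fixtures are idealizations, while counts,
identities and comparisons are meaningful.

## Two-state unfolding

`simulate_curve()` and `fit_two_state()` share the linear-extrapolation
model

\[ y(x) = \frac{(a_f + b_f x) + (a_u + b_u x)\,K(x)}{1 + K(x)},
   \qquad K(x) = e^{-(\Delta G - m x)/RT}, \]

with ΔG the folding free energy at zero denaturant (positive = stable),
*m* the denaturant dependence and \(C_m = \Delta G/m\) the midpoint. The
fit temperature defaults to 298.15 K (RT = 0.592 kcal/mol). Initial
values come from endpoint baseline regressions, the half-signal
concentration and the apparent transition width; optimisation uses
Levenberg–Marquardt nonlinear least squares, and \(C_m\) is reported
with a delta-method standard error. Parameters are invariant to affine
rescaling of the signal; a fitted midpoint outside the sampled range is
flagged with a warning. `thermal_melt_summary()` reports the fractional
signal change of a melt, reversibility against a post-cooling reading,
and an apparent midpoint only when a logistic fit converges inside the
scanned range with adequate amplitude — a flat trace is reported as "no
complete transition".

## Iterative enrichment design

`classify_positions()` is the automatic surrogate for manual position
triage: relative side-chain solvent accessibility (side-chain SASA in
the full structure, normalised by the same atoms' SASA in the residue's
own isolated context, so truncated pseudo side chains are treated
consistently) maps positions below 0.25 to *hydrophobic*, above 0.55 to
*solvent_exposed*, and between to *boundary*; core-facing strand
positions are always hydrophobic and exterior-facing strand positions at
most boundary. A user table overrides everything.

`run_trajectories()` runs independent seeded Monte-Carlo sequence
optimisations on the fixed backbone: uniform single-position proposals
from per-position alphabets, Metropolis acceptance at temperature 1.0
(energy units), 100 steps per designable position by default, distinct
sub-seeds per trajectory. At equilibrium the final sequences sample the
Boltzmann distribution of the supplied energy, which is what the
two-position exhaustive-enumeration test checks.
`profile_and_restrict()` computes per-position frequencies and keeps the
residues observed at frequency ≥ `min_frequency` (default 0: observed at
least once), always intersecting with the current alphabet so alphabets
never grow. `iterate_enrichment()` alternates the two, designing
hydrophobic + boundary positions first with solvent-exposed positions
held fixed, then the solvent-exposed positions, stopping a phase when
the mean per-position Shannon entropy changes by less than 0.01 nats
between rounds. The supplied `contact_energy()` is a deliberately simple
pairwise toy (hydrophobicity complementarity plus a volume budget per
CB–CB contact) that exercises the loop's logic; it makes no physical
claims, and manual curation of designs is represented by the caller
filtering sequences, not automated.

## Synthetic data and what passing tests show

`preset()` provides the study conditions as deterministic structures:
the 228-residue twofold ovoid TIM barrel (13:9 aspect) with a rule-based
designed sequence (small Ala/Val cores on the minor-face strands,
Ile/Leu on the major-face strands, Thr exteriors, a few pinned positions
such as Cys4, Ile60 and Ala93 so the named polar variants PV1–PV5 apply
cleanly), a 184-residue fourfold circular barrel (eight strands of
length 5, all shifts 1), a zero-shear toy wall and a single-wall ovoid
("porin-like") barrel. `make_decoy()` produces noise, flipped-strand
(facing-parity sequence swap) and deleted-strand decoys;
`apply_variant()` applies the named polar variants and layer-ablation
hollow variants (repeat partners auto-mutated; exact layer membership
follows `enumerate_layers()` and can be overridden with explicit
position lists, since only the construction rule, not the residue list,
is specifiable from first principles). `make_curve_panel()` crosses
(ΔG, m) parameter sets — including ΔG = 8.4 kcal/mol, m = 1.6
kcal/mol/M — with noise levels and baseline slopes, deterministically
per seed.

These generators emulate idealized geometry, exact repeat symmetry,
rule-based sequences and homoscedastic Gaussian noise. They do not
emulate crystallographic disorder, side-chain rotamers, frayed real
strand ends, heteroscedastic CD noise, or aggregation artefacts — so
green tests demonstrate the *correctness of the arithmetic and the
estimators under the stated model*, not performance on experimental
structures. Problem sizes used by the test suite and the acceptance
script (a 228-residue model, 20 refit seeds, 30-point curves, 300–1000
design trajectories on 1–2 positions) were chosen to keep a full run in
tens of seconds while leaving every estimator's sampling error well
inside its tolerance.

## Numerical choices and limitations

- Ellipse arc length is tabulated on a 4000-point grid and inverted by
  interpolation; wall perimeter is matched to the closure perimeter
  exactly after rescaling.
- The loop relaxation is deterministic (no jitter), so generation is
  reproducible without a seed; all stochastic components
  (noise decoys, curves, design trajectories, permutation tests) take
  explicit seeds and derive per-unit sub-seeds.
- Ties in `autoregressive_search()` resolve to the smallest candidate
  length, with a warning.
- Degenerate inputs fail loudly: blueprints whose shifts do not sum to
  the declared shear raise a closure error; fewer than three detected
  strands is a barrel error; an unclosed ladder is an open-barrel error;
  non-convergent unfolding fits error with diagnostics.
- Known limitations: the idealized backbone has no physical energy and
  approximate stereochemistry; buried areas depend on the pseudo
  side-chain construction on generated fixtures; the enrichment energy
  is a toy; sequence design does not maintain hydrogen-bond constraints
  because the backbone never moves.
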