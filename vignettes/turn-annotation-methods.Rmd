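---
title: "Annotating RNA tetranucleotide turns from 3D structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating RNA tetranucleotide turns from 3D structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraturns)
```

## The model

RNA tetranucleotide loops fall, almost exhaustively, into two fold
families that are distinguished not by sequence but by which nucleobase
carries a backbone oxygen stacked against its face:

* In a **U-turn** (the classical GNRA/anticodon fold) an OP atom of the
  third residue stacks under the *first* nucleobase, and the first base
  donates a hydrogen bond from its Watson–Crick-edge imino/amino nitrogen
  to an OP atom of the fourth residue (a 5/4/3BPh-family base–phosphate
  contact). A variant, the **U_SH-turn**, keeps the OP–π contact but
  replaces the base–phosphate bond with a 1–4 *trans* Sugar/Hoogsteen pair.
* In a **Z-turn** (the UNCG fold, built on a Z-RNA-like dinucleotide step)
  the O4′ of the third residue stacks under the *fourth* nucleobase. The
  1–4 pair is typically *trans* Sugar/Watson–Crick, residue 3 is C2′-endo
  and the riboses of residues 3–4 run head-to-tail. The fourth base is
  *syn* in the main form (**Z_syn**) and *anti* in the rarer **Z_anti**
  (whose 1–4 pair is usually *cis* Watson–Crick/Watson–Crick, the
  "di-loop" arrangement).

`classify_turn()` applies exactly this decision order: a valid
OP(3)→base(1) contact makes the window U (with the base–phosphate bond) or
U_SH (with a tSH pair); otherwise a valid O4′(3)→base(4) contact makes it
Z_syn or Z_anti by the glycosidic state of residue 4; otherwise any
remaining 1–4 interaction leaves it *uncategorized*. Sugar pucker at
residue 3, the head-to-tail orientation of sugars 3–4 and the 1–4 pair
type are always reported but never gate the decision — the operational
definition rests on the pair/bond evidence and the oxygen–π contact, and
pucker is conserved rather than defining. Z-turns do not require a tSW
pair: any 1–4 pair plus a valid O4′–π contact suffices, with the observed
pair type recorded. For GNRA-type windows, the 1–4 G•A pair is reported
with whichever label (tSW or tSH) the geometry supports; both labels occur
in the literature for this pair and neither is required for the U call,
which rests on the base–phosphate bond.

An **oxygen–π contact** is accepted when the oxygen (OP1/OP2 or O4′) lies
within 3.5 Å of the least-squares nucleobase plane *and* its projection
falls inside the base ring outline dilated in-plane by 0.5 Å (the
allowance for crystallographic coordinate error). The 3.5 Å boundary is
inclusive. For purines the outline is the single nine-vertex outline of
the fused bicycle, so a projection over either ring or the shared edge
counts. The detector also evaluates the reverse O4′(4)→base(3) geometry
and records it as a diagnostic, making the directional choice auditable.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `oxygen_pi` | 3.5 | Å | oxygen–base-plane distance cutoff (inclusive) |
| `polygon_offset` | 0.5 | Å | in-plane ring-outline dilation |
| `interbase_max` | 45 | ° | maximum interbase angle for a 1–4 pair |
| `hbond` | 3.5 | Å | heavy-atom hydrogen-bond cutoff |
| `max_b` | 79 | Å² | per-atom B-factor ceiling for a window |
| `max_resolution` | 3.0 | Å | structure resolution ceiling (X-ray mode) |
| `max_loop` | 8 | nt | maximum hairpin loop length |
| `max_bulge` | 2 | nt | residues a window may skip (bulged out) |

All of them live in one `tt_config()` object; the defaults are the survey
operating point and `annotate_turns()`/`survey_turns()` take the config as
an argument.

Numeric conventions the literature names but does not number are fixed as
the conventional crystallographic windows: *syn* is χ ∈ (−90°, +90°]
(closed on the +90° side; χ = −90° exactly is *anti*), C2′-endo is
pseudorotation phase P ∈ [120°, 200°), C3′-endo is P within ±72° of 0°,
and backbone torsions bin into 120°-wide wells centred on +60° (g+), −60°
(g−) and 180° (t). Pseudorotation uses the Altona–Sundaralingam closed
form on the five endocyclic torsions; near-planar rings (amplitude < 5°)
are flagged "flat" rather than forced into a class.

## Interaction detection

Hydrogen bonds are detected between heavy atoms of the base edges (plus
the 2′-hydroxyl) within 3.5 Å, screened by the angle at the donor.
Protons are inferred, not observed, so the screen is the permissive
plausibility bound used by heavy-atom detectors (≥ 90°); base–phosphate
donors use the same bound because an imino N–H points along the external
bisector of its ring bonds, which lowers the achievable heavy-atom angle.

Leontis–Westhof edges are assigned from which of a residue's atoms supply
the supporting bonds (the 2′-OH votes Sugar); shared corner atoms (O6, N4,
O2...) are disambiguated by the azimuth of the partner's contact centroid
in the residue's standard base frame, measured against per-edge reference
azimuths derived from the shipped edge-atom table. cis/trans comes from
the standard virtual torsion C1′(i)–N(i)–N(j)–C1′(j) (|τ| ≤ 90° is cis).
Stacked bases are excluded from pairing by a 2.5 Å guard on the separation
of ring centroids along either base normal, alongside the 45° interbase
angle ceiling.

Base–phosphate contacts are typed by donor identity following the
published BPh nomenclature: G N1 → 5BPh, G N2 → 3BPh, both → 4BPh,
U N3 → 5BPh; a cytosine N3 donor is only possible when protonated, so
C-starting windows whose N3 reaches an OP are classified U with a
"presumed C+" note — protonation itself is not observable in coordinates.

## Loops and windows

Base pairs are derived from 3D alone (C1′–C1′ pruning at 12 Å, then full
classification). A hairpin is a pair enclosing 3–8 contiguous residues
(author numbering) none of which pairs outside the enclosed span; nested
closings report the innermost loop. Pairs enclosing fewer than three
residues are treated as loop-internal — the UNCG 1–4 tSW pair and the
CUUG "di-loop" cWW pair would otherwise pose as closings of sterically
impossible 1–2 nt loops and hide the real hairpin. This is the one place
the implementation tightens a nominal "loops of length ≥ 1" reading: a
1–2 nt RNA hairpin cannot close, and every reported tetranucleotide turn
lives in a loop of four or more residues.

Candidate windows are the 4-subsequences of a loop that skip at most two
residues (covering bulged pentaloops such as GCAAu and CUUGu and
GAAA-in-7-nt-loop arrangements) and whose first and fourth residues share
a 1–4 interaction — a classified pair or a base-1→phosphate-4 contact.
When several windows of one loop classify, the best-evidenced one is kept
(categorized beats uncategorized; ties go to the shorter oxygen–π
distance), with `all_windows = TRUE` to keep everything.

## Survey machinery

Each surveyed window carries a structural fingerprint: the window sequence,
residue numbers including one flanking residue on each side, chain code,
pucker classes, backbone g+/g−/t strings and syn/anti states over those
six positions, plus the window-average B-factor. Records sharing a
fingerprint are redundant when they come from the same structure
(multi-chain copies) or carry the same chain code in different structures;
groups are closed transitively and the best-resolution record is kept,
ties broken by lowest average B, then lexicographically (pdb, chain,
number) — which keeps the first chain for same-structure copies. Records
without a resolution (NMR) never merge with resolved ones and tie-break on
B directly; the original survey design was X-ray-only, so this is an
extension. Both population and sample standard deviations are reported
for the contact-distance statistics, since surveys in this area do not
always state which they print.

## The synthetic generator

`make_turn()` builds idealized full-atom hairpins from canonical internal
geometry: consensus planar base coordinates, a ribose grown from the
glycosidic bond with its endocyclic torsions set from the requested
pseudorotation phase (so χ and pucker are exact by construction), an
A-form-like stem of cis Watson–Crick pairs closed by C=G, and a loop that
realizes each archetype's defining contacts — the diagnostic oxygen is
placed at the fold's characteristic stacking distance over the target base
(3.0 Å for OP–π, 3.1 Å for O4′–π), hydrogen-bond partners at 2.8–2.9 Å
along donor directions, and remaining placements chosen by deterministic
candidate search maximizing steric clearance. Z templates use χ₄ = +45°
(high-syn) and −140° (anti), keeping a wide margin to the ±90° boundary so
that the syn/anti call is stable under the coordinate noise used in
testing; both values are well inside their conformational wells.

What the generator emulates: the defining interaction geometry, quality
metadata (B-factors, resolution), author numbering, multi-copy corpora,
bulged pentaloops, and controlled perturbations (oxygen displacement along
the base normal, χ₄ flips executed by rotating the sugar about the
glycosidic bond so the pair survives, base mutations by standard-frame
replacement, B-factor inflation, 1–4 pair breaking). What it does not
emulate: energetically relaxed backbones (filler residues are placed for
clearance, not chemistry), solvent and ligands, crystal contacts,
correlated coordinate error (noise is iid Gaussian), or real electron
density. Passing tests therefore demonstrate that the decision rules
respond to the defining geometry exactly as specified — not that the
package's detectors match any particular third-party annotation of
experimental structures.

## Numerical choices and degenerate inputs

* Plane fits use SVD; the normal's sign follows the ring winding, and the
  reported out-of-plane RMS makes distorted bases visible.
* Point-in-dilated-polygon is exact (even–odd crossing plus distance to
  edges), not sampled.
* Incomplete bases raise a typed condition (`tt_incomplete_base`);
  windows containing one are reported *not-assessable* — deliberately
  distinct from "no contact", since both end up uncategorized but for
  different reasons.
* Mirror-imaging coordinates maps pseudorotation phase P to P + 180°
  (endo ↔ exo), the stereochemically correct equivariance.
* If both a 1–3 OP–π and a 3–4 O4′–π contact were ever valid in one
  window, the OP–π branch wins and a note is recorded; the fixture suite
  asserts the archetypes never reach that state.
* Determinism: identical coordinates give identical annotations; the
  generator is bit-reproducible given a seed.

## Problem sizes used in the checks

The packaged checks run on synthetic material sized for a desk machine:
200 noise seeds per archetype at σ = 0.15 Å for the recovery sweep, a
40-structure corpus (10 replicates per archetype at σ = 0.1 Å) for the
distance statistics, 10,000 random points for the projection oracle, and
50 synthetic records for the redundancy oracle. These sizes give the
recovery estimate a standard error of about 1% and the distance means a
standard error of a few hundredths of an Å, which is comfortably inside
the ±0.2 Å spread characteristic of oxygen–π contact distances.

## Known limitations

* Hairpins only: turns embedded in T-loops, anticodon loops of full tRNAs
  or multiloops are out of scope unless they sit in a hairpin of ≤ 8 nt.
* No pseudoknot handling; pairs crossing a candidate loop simply
  disqualify it.
* Cytosine protonation is inferred, never observed.
* The sequence–structure matrix distils reported hairpin occurrences;
  absence there means "not recorded", and `make_turn(override = TRUE)`
  deliberately builds such combinations for testing.
* The distinct UGAA fold with no 1–4 interaction is excluded by
  construction, exactly as the window definition requires.
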