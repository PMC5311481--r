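# tetraturns

Structure-based annotation of RNA tetranucleotide turns from 3D coordinates.

## The problem

Most RNA hairpin stems are capped by tetranucleotide loops, classically
named by sequence: GNRA and UNCG. But sequence does not dictate fold —
GNRA-type sequences are occasionally caught in a UNCG-type fold and vice
versa. `tetraturns` therefore classifies loops by *structure*, not
sequence, using the one feature that cleanly separates the two fold
families: a backbone oxygen stacked against a nucleobase face (an
oxygen–π, lone-pair–π contact):

* **U-turn** — a hydrogen bond from the first nucleobase (a U/G/C⁺ imino
  or amino nitrogen) to an OP atom of the fourth nucleotide (a 5/4/3BPh
  base–phosphate contact), plus an **OP(residue 3)–π contact under base 1**.
  The classical GNRA / anticodon-loop fold.
* **U_SH-turn** — the same OP–π contact, but the 1–4 interaction is a
  *trans* Sugar/Hoogsteen base pair (e.g. U•C in UNAC loops).
* **Z-turn** — an **O4′(residue 3)–π contact under base 4**, a 1–4 pair
  (typically *trans* Sugar/Watson–Crick), C2′-endo pucker at residue 3 and
  head-to-tail riboses 3–4: the UNCG fold built on a Z-RNA-like dinucleotide
  step. The fourth base is *syn* (**Z_syn**) or *anti* (**Z_anti**).
* **uncategorized** — a 1–4 interaction is present but no valid oxygen–π
  contact (partially unfolded turns, GANC-type loops).

An oxygen–π contact is accepted when the oxygen lies within **3.5 Å** of the
least-squares base plane and its projection falls inside the base ring
outline dilated by **0.5 Å**. Windows are drawn from hairpin loops of at
most **8** residues (up to 2 bulged-out positions), screened for atomic
B-factors ≤ **79 Å²** and resolution ≤ **3.0 Å**, and surveys eliminate
redundancy by structural fingerprint (residue numbers with flanks, chain,
pucker classes, backbone g+/g−/t strings, syn/anti states), keeping the
best-resolution, lowest-B representative.

The package reads mmCIF/PDB (via `bio3d`), derives base pairs, hairpins and
windows from coordinates alone, and ships a fully synthetic generator of
idealized turn structures (`make_turn()`) so that every rule is testable
without downloading a single experimental structure.

## Worked example

```r
library(tetraturns)

x <- make_turn("Z_syn")        # idealized cUUCGg hairpin, 2-bp stem
ann <- annotate_turns(x)
ann[, c("seq", "category", "oxy_kind", "oxy_distance", "pair_14",
        "pucker3", "chi4_state", "head_to_tail_34")]
#>    seq category oxy_kind oxy_distance pair_14  pucker3 chi4_state head_to_tail_34
#> 1 UUCG    Z_syn      O4'          3.1     tSW C2'-endo        syn            TRUE
```

One row per classified window: the UUCG loop is a Z-turn — the O4′ of
residue 3 stacks 3.1 Å over base 4 (inside the dilated ring outline), the
1–4 pair is *trans* Sugar/Watson–Crick, residue 3 is C2′-endo, the fourth
base is *syn*, and the riboses of residues 3–4 are head-to-tail. The same
call annotates any mmCIF/PDB file read with `read_structure()`.

Corpus surveys compose annotation, redundancy elimination, counting and
contact statistics:

```r
sv <- survey_turns(list(make_turn("U", pdb_id = "SU01"),
                        make_turn("Z_syn", pdb_id = "SZ01", start_resno = 11)))
glance(sv)
#> # A tibble: 1 × 11
#>   n_records n_nonredundant   n_u n_u_sh n_z_syn n_z_anti n_uncategorized ...
#> 1         2              2     1      0       1        0               0
```

`tidy(sv)` returns the per-window records, `autoplot(sv)` draws the
oxygen–π distance histograms, `autoplot(sv$counts)` the category-by-sequence
count table, and `write_survey(sv, dir)` emits CSV/JSON outputs.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tetraturns.R", package="tetraturns"))')" \
    annotate --out annotations.csv structure1.cif structure2.pdb
```

with `survey` and `fixtures make`/`fixtures perturb` subcommands.

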