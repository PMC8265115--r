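---
title: "Decomposing nonribosomal peptides and polyketides into building blocks"
author: "msblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing nonribosomal peptides and polyketides into building blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msblocks)
```

## Why block databases

Nonribosomal peptides (NRPs) and polyketide (PK) siderophores fragment in
tandem mass spectrometry along their backbone amide and ester bonds, so the
natural unit for spectrum annotation is not the whole molecule but its
sequence of monomer *building blocks*. Downstream annotation software
(CycloBranch) consumes plain-text databases of blocks (acronym + residue
formula), block sequences, and terminal modifications. Producing those
databases by hand means drawing a structure, spotting every peptide bond,
computing residue formulas, and transcribing a sequence notation — all
error-prone. `msblocks` automates the pipeline from a SMILES string to a
database row.

## The decomposition model

`decompose()` runs: parse → bond perception → split → cap → formulas →
order → classify → notation.

**Parsing.** SMILES are parsed through OpenBabel (via ChemmineOB) with
explicit hydrogens, which are folded into per-atom hydrogen counts; the
working graph holds heavy atoms only, with kekulized (definite) bond
orders. Per-atom aromaticity is taken from the notation (lowercase atoms),
because amide perception must ignore ring nitrogens. Multi-component input
is rejected, and decomposition requires a neutral parent: mass-spectral
block bookkeeping is defined on the neutral molecule, and charged sites
would corrupt the hydrogen accounting during capping.

**Cleavable bonds.** A peptide bond is a C–N single bond whose carbon also
bears a double-bonded oxygen. Secondary *and* tertiary amides qualify —
N-methylated residues are ubiquitous in depsipeptides — but a nitrogen
inside an aromatic ring is never cleavable (no chain runs through it
without destroying the ring). An ester bond is a C(=O)–O single bond whose
oxygen carries a second carbon; ester perception is on by default and can
be disabled for pure-peptide work (`include_esters = FALSE`). A candidate
is dropped when cleaving it would leave a fragment of **three or fewer
heavy atoms** (checked symmetrically on both sides by connected-component
search with the bond removed). This is what keeps a terminal acetyl fused
to its residue: acetyl has exactly three heavy atoms, so N-acetylated
terminal residues come out as single modified blocks. Users remain
authoritative: `toggle_bond()` flips any bond in or out of the cleavable
set with no pattern check, and toggling twice restores the annotation
exactly.

**Splitting and capping.** Removing the cleavable bonds partitions the
graph; each fragment is one block occurrence, and each cleaved bond becomes
a directed linkage from the fragment holding the carbonyl carbon (acyl
side) to the fragment holding the N or O. Fragments are capped back to free
monomers: every cleaved N/O site regains a hydrogen, and the **first**
cleaved acyl site regains a hydroxyl, restoring a carboxyl group. Further
acyl sites keep their formyl form. The single-hydroxyl rule is deliberate:
mass spectrometry cannot localize the extra oxygen of a doubly cleaved
block, so the succinyl block of desferrioxamine is stored as succinic
semialdehyde (C4H6O3), not succinic acid.

**Formulas.** Three formulas are tracked per block. The *sitting* formula
is the fragment exactly as embedded in the parent. The *molecular* formula
is the capped free monomer, defined conventionally as residue + H2O when
the block has a C-terminus and residue + H2 when it does not. The *residue*
formula is the catalogued quantity: molecular − H2O for ordinary residues
(isoleucine C6H13NO2 → C6H11NO), and molecular − H2 for blocks with no
oxygen-bearing terminus to dehydrate — putrescine C4H12N2 → C4H10N2, and
the hydroxamate diamine Hpd C5H14N2O → C5H12N2O. Terminus counts combine
cleaved sites with free termini detected on the fragment: a C(=O)OH group
is a C-terminus, a non-aromatic N with at least one hydrogen that is not
acylated within the fragment is an N-terminus. The amine heuristic
deliberately errs on the permissive side — arginine's guanidine N–H groups
count as amines, inflating the N-terminus count of an Arg block — because
nothing downstream depends on N-counts beyond zero/nonzero, while missing a
genuine amine would misclassify PK blocks (the load-bearing case is
`c_termini == 0`).

**Classification.** Starting from *linear*: a cycle in the block graph
(edges ≥ nodes in one connected component) makes the structure *cyclic*; a
block with more than two neighbors makes it *branched*; both together,
*branch-cyclic*. Two or more branching points — or a double branch at one
block — give *other*, which the notation cannot represent. Any block
without a C-terminus marks the molecule as a polyketide, refined to
*linear-polyketide* or *cyclic-polyketide*; a branched polyketide falls
back to *other* because no branched-PK type exists. Ester-linked
(depsipeptide) blocks do **not** trigger the polyketide flag — the flag
depends solely on the missing C-terminus. A lone block is *linear* (or
*linear-polyketide* if it lacks a C-terminus).

**Ordering and notation.** Chains are emitted N-terminus first, following
the acyl→amine direction of the linkages. PK chains break that compass:
desferrioxamine's backbone has nitrogens at both ends, so neither end is
"the" N-terminus. The convention adopted is deterministic and purely
notational: when direction scores tie, the chain starts at the occurrence
containing the lowest atom index of the input string. Cyclic cores are
emitted as one rotation (imports compare rotation-insensitively); when a
ring carries a pendant branch, the rotation is chosen so the branching
block comes last, and the notation wraps the branching block plus its
branch in the escaped group of the CycloBranch format,
`[A]-[B]-[C]-[D]\([E]-[F]\)`, with the branching block E first inside the
parentheses and the branch F read outward. For branched (non-cyclic)
structures the backbone is the longest path through the branching block
(ties toward the arm whose first occurrence has the lowest atom index) —
the format needs *a* backbone, and chain length is the only property a mass
spectrometrist can see.

## Family recommendation

Tanimoto similarity is computed over *sets of block structures*, keyed by
canonical stereo-free SMILES rather than acronyms (acronyms are user data;
structures are ground truth): `T(A,B) = |A∩B| / (|A|+|B|−|A∩B|)`. The
most similar stored sequence wins; among ties the sequence with the closest
total block count (repeats included) is chosen, then the earliest stored
one. Recommendations require `T > 0` — wholly unrelated compounds should
recommend nothing. The alternative text model extracts a search substring
by dropping the final whitespace token of the query name ("pseudacyclin B"
searches "pseudacyclin") and matches stored names case-insensitively.

## Containers and the CycloBranch dialect

A container bundles blocks, sequences and terminal modifications. Stored
masses are never independent state — they are recomputed from formulas on
construction and on import, and an imported mass deviating by more than
1e-4 Da triggers a warning with the formula winning. Terminal-modification
validity follows the sequence type: linear, one N-terminal plus one
C-terminal; cyclic, none; branched and branch-cyclic, a single branch
modification of either polarity; linear polyketide, up to two of any
polarity (its two ends may both be N-type, as in acetylated
desferrioxamine).

The tab-separated export uses a declared column layout (blocks: name,
acronym, residue formula, residue mass, semicolon-joined losses,
references; sequences: type, name, formula, mass, notation, three
modification names, reference; modifications: name, formula, mass, N/C
flag), isolated in one reader/writer pair so a different column order is a
one-file change. Export → import → export is byte-identical. JSON
persistence (`container_save()`/`container_load()`) is the stand-in for a
relational store and carries fields the text format does not (block SMILES,
families, organisms).

## The assembly generator

`assemble()` condenses free monomers — each linkage deletes the hydroxyl
of a donor carboxyl and bonds the carbonyl carbon to an acceptor amine or
hydroxyl, losing one water. It emulates exactly the linkage chemistry the
decomposer must invert: linear and cyclic peptides, side-chain branches
through lysine/ornithine amines, ester linkages through hydroxy acids, and
alternating-orientation PK chains via explicit per-linkage donor/acceptor
sites (the desferrioxamine fixture wires each succinyl to one hydroxamate
and one primary amine). Auto site selection prefers the α-carboxyl and
α-amine; anything else must be named by atom index, which keeps fixtures
unambiguous.

What the generator does *not* emulate: stereochemical variation beyond
markers (identity is stereo-free by design), thioester or glycosidic
linkages, internal block modifications (modified blocks are, by the tool's
own principle, new blocks), protonation/tautomer states, and real
instrument data of any kind. A passing round-trip suite therefore shows
that decomposition inverts condensation chemistry on realistic NRP/PK
topologies — not that bond perception is complete for arbitrary natural
products outside the modeled linkage types.

## Numerical and design choices

* Element masses: a single bundled table of most-abundant-isotope masses
  (H, C, N, O, S, P, F, Cl, Br, I, Se) to ≥ 6 decimals; the acetylation
  check `monoisotopic_mass("C2H2O") == 42.010565` pins the table.
* Canonicalization is delegated to OpenBabel's canonical SMILES writer;
  only determinism and molecule identity are load-bearing. Stereo stripping
  removes `@`, `@@`, `/`, `\` textually and re-normalizes through the
  toolkit; formula invariance is asserted.
* No tautomer or protonation normalization precedes canonicalization;
  inputs are taken as drawn.
* Unknown blocks receive synthesized acronyms: the first three letters of a
  finder-supplied name ("ornithine" → "Orn"), else "B" + discovery index,
  suffixed on collision.
* Randomized suites run on fixed seeds: 100 assembly round trips with 2–10
  blocks drawn from the proteinogenic pool plus Orn, Put, Hpd, Suc, Sar and
  Lac — sizes chosen to cover every topology class while keeping a full
  test run in well under a minute of cheminformatics calls.

## Known limitations

Charged and multi-component parents are rejected rather than normalized.
Free-amine detection can overcount N-termini on guanidine and amide-free
side-chain nitrogens (classification is unaffected). The branch/backbone
split for branched structures is a documented convention, not chemistry.
Sequences of type *other* export without a notation string. Live REST
finder backends are out of scope; the finder interface ships with the
offline fixture backend only.
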