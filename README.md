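# msblocks

Building blocks and sequences of nonribosomal peptides (NRPs) and
polyketides (PKs) for tandem mass spectrometry.

NRPs and PK siderophores — cyclic, branched, and branch-cyclic microbial
natural products — are annotated in tandem MS against databases of monomer
*building blocks* (acronym + residue formula + monoisotopic mass) and block
*sequences*. `msblocks` builds those databases from molecular structures:

* **Bond perception** — cleavable peptide bonds are C–N single bonds whose
  carbon bears a carbonyl oxygen (secondary and tertiary amides; aromatic
  ring nitrogens excluded); ester bonds of depsipeptides are perceived too.
  A candidate whose cleavage would leave ≤ 3 heavy atoms is skipped, so
  terminal groups like acetyl stay fused to their residue. Any bond can be
  toggled manually.
* **Decomposition** — removing cleavable bonds splits the molecular graph
  into block occurrences; fragments are capped back to free monomers (H on
  cleaved amines, one OH restoring a carboxyl) and deduplicated by
  canonical, stereo-free SMILES.
* **Residue formulas** — the standard water-elimination convention,
  `residue = molecular − H2O` (Ile: C6H13NO2 → C6H11NO), switching to
  `molecular − H2` for blocks without a C-terminus such as putrescine
  (C4H12N2 → C4H10N2) or the hydroxamate diamine Hpd of desferrioxamines.
* **Classification** — linear, cyclic, branched, branch-cyclic,
  linear-/cyclic-polyketide (a block lacking a C-terminus marks a PK), or
  other for multiply branched structures.
* **Notation** — CycloBranch sequence format, `[A]-[B]-[C]` and
  `[A]\([B]-[C]\)[D]-[E]` with B the branching block.
* **Family recommendation** — Tanimoto similarity over block-structure
  sets, `T(A,B) = |A∩B| / (|A|+|B|−|A∩B|)`, or name-substring search.
* **Database I/O** — containers of blocks/sequences/modifications with
  JSON persistence and CycloBranch-compatible tab-separated export/import
  (masses always recomputed from formulas).
* **Assembly** — a generator that condenses monomers (amide/ester
  formation, −H2O per linkage) into peptides, depsipeptides, and
  alternating PK chains, used as the independent construction route in the
  test suite.

## Worked example: pseudacyclin A

Pseudacyclin A is a branch-cyclic NRP: a ring cyclo(Pro-Ile-Ile-Orn-Phe)
with N-acetyl-isoleucine attached to the ornithine side chain. Build it
from monomers, then decompose it against the proteinogenic container plus
an offline compound-finder fixture:

```r
library(msblocks)

smi <- assemble(assembly_spec(
  c("Pro", "Ile", "Ile", "Orn", "Phe"), cyclic = TRUE,
  branch = list(at = 4, site = 6, blocks = c("Ile", "Ac"))))

finder <- fixture_finder(system.file("extdata", "compound_fixtures.json",
                                     package = "msblocks"))
decompose(smi, container = proteinogenic_container(), finder = finder)
```

```
<decomposition> CCC(C(C(=O)NCCCC1NC(=O)C(NC(=O)C(NC(=O)C2N(C(=O)C(NC1=O)Cc1ccccc1)CCC2)C(CC)C)C(CC)C)NC(=O)C)C
  parent: C39H61N7O7  739.463247 Da
  type: branch-cyclic   blocks: 5 distinct / 6 occurrence(s)
  sequence: [Phe]-[Pro]-[Ile]-[Ile]\([Orn]-[Nac]\)
  [Nac] N-acetyl-isoleucine  residue C8H13NO2 (155.094629 Da)  CCC(C(C(=O)O)NC(=O)C)C
  [Orn] ornithine  residue C5H10N2O (114.079313 Da)  NC(C(=O)O)CCCN
  [Ile] isoleucine  residue C6H11NO (113.084064 Da)  CCC(C(C(=O)O)N)C
  [Pro] proline  residue C5H7NO (97.052764 Da)  OC(=O)C1CCCN1
  [Phe] phenylalanine  residue C9H9NO (147.068414 Da)  NC(C(=O)O)Cc1ccccc1
```

Six occurrences, five distinct blocks: the tool found six peptide bonds but
left the acetyl–isoleucine amide uncleaved (acetyl would be a 3-heavy-atom
fragment), so N-acetyl-isoleucine is one block. Ile, Pro, and Phe resolved
from the local container; ornithine and N-acetyl-isoleucine from the finder
fixture. The sequence notation places the branching ornithine inside the
escaped parentheses with its pendant block.

The Tanimoto worked example: pseudacyclin B replaces one Ile by Val, so its
block set has six structures against A's five, sharing five —
`tanimoto(set_a, set_b)` returns `5/6 ≈ 0.833`.

A command-line wrapper ships in `inst/cli/msblocks.R`:

```sh
Rscript inst/cli/msblocks.R mass C2H2O        # 42.010565
Rscript inst/cli/msblocks.R decompose --json 'NCC(=O)NCC(=O)O'
```

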