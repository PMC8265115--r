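Package: msblocks
Title: Building Blocks and Sequences of Nonribosomal Peptides and
    Polyketides for Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposes nonribosomal peptide (NRP) and polyketide (PK)
    structures given as SMILES into sequences of building blocks by
    perceiving cleavable amide and ester bonds in the molecular graph.
    Computes residue and molecular formulas with monoisotopic masses,
    classifies molecular topology (linear, cyclic, branched, branch-cyclic
    and the polyketide variants), recommends compound families by Tanimoto
    similarity over monomer sets, and reads and writes CycloBranch-style
    block, sequence and terminal-modification databases for tandem mass
    spectra annotation. A fixture generator assembles peptides and
    polyketides from monomer structures for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
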