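test_that("simple amides are found and free amino acids have none", {
  gg <- parse_smiles("NCC(=O)NCC(=O)O")           # glycylglycine
  ann <- find_cleavable_bonds(gg)
  expect_length(ann$cleavable, 1L)
  expect_equal(unname(ann$provenance), "auto")

  expect_length(find_cleavable_bonds(parse_smiles("NCC(=O)O"))$cleavable, 0L)
  expect_length(find_cleavable_bonds(parse_smiles("NCCCCN"))$cleavable, 0L)
})

test_that("auto-annotated bonds all match the amide/ester pattern via SMARTS", {
  mols <- c(fx_pseudacyclin_a(), fx_depsipeptide(), fx_dfo_b(),
            assemble(c("Ala", "Sar", "Gly")))
  for (smi in mols) {
    g <- parse_smiles(smi)
    ann <- find_cleavable_bonds(g)
    # independent pattern oracle: acyl carbon and heteroatom of every
    # cleavable bond must appear among the toolkit's SMARTS matches
    hits_amide <- ChemmineOB::smartsSearch_OB(
      ChemmineOB::forEachMol("SMILES", smi, identity),
      "[CX3](=O)[NX3]", uniqueMatches = FALSE)
    hits_ester <- ChemmineOB::smartsSearch_OB(
      ChemmineOB::forEachMol("SMILES", smi, identity),
      "[CX3](=O)[OX2][#6]", uniqueMatches = FALSE)
    expect_lte(length(ann$cleavable), hits_amide + hits_ester)
    for (b in ann$cleavable) {
      det <- ann$detail[ann$detail$bond == b, ]
      expect_true(det$kind %in% c("amide", "ester"))
    }
  }
})

test_that("the small-fragment rule skips acetyl on pseudacyclin A", {
  g <- parse_smiles(fx_pseudacyclin_a())
  ann <- find_cleavable_bonds(g)
  expect_length(ann$cleavable, 6L)
  # the skipped bond exists: some amide-pattern bond is absent because its
  # cleavage would leave a 3-heavy-atom acetyl
  d <- decompose(fx_pseudacyclin_a())
  ac_ile <- Filter(function(b) b$residue_formula == "C8H13NO2", d$blocks)
  expect_length(ac_ile, 1L)   # N-acetyl-isoleucine stays one block
})

test_that("the skip rule is symmetric in the two fragment sizes", {
  for (smi in c(fx_pseudacyclin_a(), fx_ornibactin_like())) {
    g <- parse_smiles(smi)
    ann <- find_cleavable_bonds(g)
    for (b in ann$cleavable) {
      memb <- msblocks:::.component_membership(g, b)
      sizes <- tabulate(memb)
      sizes <- sizes[sizes > 0]
      expect_true(length(sizes) == 1L || min(sizes) > 3L)
    }
  }
})

test_that("ester perception is flag-controlled", {
  g <- parse_smiles(fx_depsipeptide())
  with_esters <- find_cleavable_bonds(g, include_esters = TRUE)
  without <- find_cleavable_bonds(g, include_esters = FALSE)
  expect_equal(sort(unique(with_esters$detail$kind)), c("amide", "ester"))
  expect_length(with_esters$cleavable, 2L)
  expect_length(without$cleavable, 1L)
  expect_equal(unique(without$detail$kind), "amide")
})

test_that("toggling is an involution and honors manual provenance", {
  g <- parse_smiles(fx_pseudacyclin_a())
  ann <- find_cleavable_bonds(g)

  # toggling any non-annotated bond on adds it; twice restores exactly
  free_bond <- setdiff(seq_len(nrow(g$bonds)), ann$cleavable)[1]
  once <- toggle_bond(ann, g, free_bond)
  expect_true(free_bond %in% once$cleavable)
  expect_equal(unname(once$provenance[as.character(free_bond)]),
               "manual-added")
  expect_identical(toggle_bond(once, g, free_bond), ann)

  # toggling an auto bond off records manual-removed and removes it
  auto_bond <- ann$cleavable[1]
  off <- toggle_bond(ann, g, auto_bond)
  expect_false(auto_bond %in% off$cleavable)
  expect_equal(unname(off$provenance[as.character(auto_bond)]),
               "manual-removed")
  expect_identical(toggle_bond(off, g, auto_bond), ann)

  expect_error(toggle_bond(ann, g, nrow(g$bonds) + 10L), "unknown bond")
})

test_that("toggling the skipped acetyl amide yields a seventh block", {
  smi <- fx_pseudacyclin_a()
  g <- parse_smiles(smi)
  ann <- find_cleavable_bonds(g)
  # locate the skipped Ac amide: the amide-pattern bond whose cleavage
  # isolates exactly 3 heavy atoms
  el <- g$atoms$element
  carbonyl <- msblocks:::.carbonyl_carbons(g)
  skipped <- NULL
  for (i in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[i] != 1L || i %in% ann$cleavable) next
    e <- c(g$bonds$a1[i], g$bonds$a2[i])
    if (any(e %in% carbonyl & el[e] == "C") && any(el[e] == "N")) {
      sizes <- tabulate(msblocks:::.component_membership(g, i))
      if (min(sizes[sizes > 0]) == 3L) skipped <- c(skipped, i)
    }
  }
  expect_length(skipped, 1L)
  d7 <- decompose(smi, toggle_bonds = skipped)
  expect_equal(nrow(d7$occurrences), 7L)
  expect_length(d7$annotation$cleavable, 7L)
})

test_that("annotation is invariant under atom reordering of the input", {
  for (smi in c(fx_pseudacyclin_a(), fx_depsipeptide(),
                "NCC(=O)NCC(=O)NCC(=O)O")) {
    a <- decompose(smi)
    b <- decompose(canonical_smiles(smi))
    expect_equal(length(a$annotation$cleavable), length(b$annotation$cleavable))
    expect_equal(sort(a$occurrences$smiles), sort(b$occurrences$smiles))
  }
})
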