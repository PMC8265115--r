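test_that("glycylglycine splits into two glycines with one directed linkage", {
  d <- decompose("NCC(=O)NCC(=O)O")
  expect_equal(nrow(d$occurrences), 2L)
  expect_equal(nrow(d$block_graph$edges), 1L)
  expect_equal(unique(d$occurrences$smiles), generic_smiles("NCC(=O)O"))
  expect_equal(unique(d$occurrences$residue), "C2H3NO")
  expect_equal(unique(d$occurrences$molecular), "C2H5NO2")
  expect_equal(d$type, "linear")
  # conservation: 2 residues + H + OH = parent
  expect_equal(
    formula_to_string(formula_add(formula_multiply("C2H3NO", 2), "H2O")),
    d$molecular_formula)
})

test_that("pseudacyclin A decomposes into six blocks, branch-cyclic", {
  d <- decompose(fx_pseudacyclin_a(), container = fx_proteinogenic())
  expect_equal(nrow(d$occurrences), 6L)
  expect_equal(nrow(d$block_graph$edges), 6L)
  expect_equal(length(d$blocks), 5L)   # two Ile occurrences share a structure
  expect_equal(d$type, "branch-cyclic")

  acr <- vapply(d$blocks, `[[`, character(1), "acronym")
  expect_true(all(c("Ile", "Pro", "Phe") %in% acr))       # local hits
  # ornithine and N-acetyl-isoleucine are not proteinogenic: synthesized
  expect_length(grep("^B\\d+$", acr), 2L)
  # ring of five with the branch on ornithine
  expect_length(d$sequence$backbone, 5L)
  expect_length(d$sequence$branch, 1L)
  orn <- d$blocks[[match(generic_smiles("NC(CCCN)C(=O)O"),
                         vapply(d$blocks, `[[`, character(1), "block_smiles"))]]
  expect_equal(d$sequence$backbone[d$sequence$branch_at], orn$acronym)
  # conservation on the branch-cyclic core: residues alone sum to the parent
  sum_res <- Reduce(formula_add, lapply(d$occurrences$residue, as_chem_formula))
  expect_equal(formula_to_string(sum_res), d$molecular_formula)
})

test_that("unknown pseudacyclin blocks resolve through a fixture finder", {
  finder <- fixture_finder(system.file("extdata", "compound_fixtures.json",
                                       package = "msblocks"))
  d <- decompose(fx_pseudacyclin_a(), container = fx_proteinogenic(),
                 finder = finder)
  names_found <- vapply(d$blocks, `[[`, character(1), "name")
  expect_true("ornithine" %in% names_found)
  expect_true("N-acetyl-isoleucine" %in% names_found)
  acr <- vapply(d$blocks, `[[`, character(1), "acronym")
  expect_true("Orn" %in% acr)    # synthesized from the finder name
})

test_that("desferrioxamine core alternates Hpd and Suc with the paper formulas", {
  d <- decompose(fx_dfo_core())
  expect_equal(length(d$blocks), 2L)
  expect_equal(nrow(d$occurrences), 5L)
  expect_equal(d$type, "linear-polyketide")

  by_smiles <- split(d$occurrences, d$occurrences$smiles)
  res <- sort(vapply(d$blocks, `[[`, character(1), "residue_formula"))
  mol <- sort(vapply(d$blocks, `[[`, character(1), "molecular_formula"))
  expect_equal(res, c("C4H4O2", "C5H12N2O"))
  expect_equal(mol, c("C4H6O3", "C5H14N2O"))

  # Hpd has two N-termini and no C-terminus; Suc two C-termini
  hpd <- d$blocks[[match("C5H12N2O",
                         vapply(d$blocks, `[[`, character(1),
                                "residue_formula"))]]
  suc <- d$blocks[[match("C4H4O2",
                         vapply(d$blocks, `[[`, character(1),
                                "residue_formula"))]]
  expect_equal(hpd$c_termini, 0L)
  expect_equal(hpd$n_termini, 2L)
  expect_equal(suc$c_termini, 2L)
  expect_equal(suc$n_termini, 0L)

  # strict alternation along the ordered backbone
  ord_smiles <- d$occurrences$smiles[match(d$order$backbone,
                                           d$occurrences$occ)]
  expect_equal(ord_smiles[c(1, 3, 5)], rep(hpd$block_smiles, 3))
  expect_equal(ord_smiles[c(2, 4)], rep(suc$block_smiles, 2))

  # conservation with two N-type chain ends: residues + H2 = parent
  sum_res <- Reduce(formula_add, lapply(d$occurrences$residue, as_chem_formula))
  expect_equal(formula_to_string(formula_add(sum_res, "H2")),
               d$molecular_formula)
})

test_that("the acetylated desferrioxamine B balances residues + acetyl + H2", {
  parent <- formula_of(fx_dfo_b())
  expect_equal(formula_to_string(parent), "C25H48N6O8")
  total <- formula_add(
    formula_add(formula_multiply("C5H12N2O", 3), formula_multiply("C4H4O2", 2)),
    formula_add("C2H2O", "H2"))
  expect_equal(formula_to_string(total), formula_to_string(parent))
  # a faithful decomposition merges the acetyl into the terminal Hpd block
  d <- decompose(fx_dfo_b())
  expect_equal(length(d$blocks), 3L)
  expect_equal(d$type, "linear-polyketide")
})

test_that("putrescine at a chain end follows the two-hydrogen rule", {
  d <- decompose(fx_ornibactin_like(), container = fx_proteinogenic())
  expect_equal(d$type, "linear-polyketide")
  put <- Filter(function(b) b$molecular_formula == "C4H12N2", d$blocks)
  expect_length(put, 1L)
  put <- put[[1]]
  expect_equal(put$residue_formula, "C4H10N2")
  expect_equal(put$c_termini, 0L)
  diff <- formula_subtract(put$molecular_formula, put$residue_formula)
  expect_equal(formula_to_string(diff), "H2")
  # the putrescine block sits at the C-terminal end of the ordered chain
  last_occ <- d$order$backbone[length(d$order$backbone)]
  expect_equal(d$occurrences$smiles[match(last_occ, d$occurrences$occ)],
               put$block_smiles)
})

test_that("block deduplication is keyed by canonical stereo-free structure", {
  d <- decompose(assemble(c("Ala", "Gly", "Ala", "Gly", "Ala")))
  expect_equal(length(d$blocks), 2L)
  expect_equal(nrow(d$occurrences), 5L)
  expect_equal(length(unique(d$occurrences$smiles)), 2L)
})

test_that("charged parents are rejected with a clear error", {
  expect_error(decompose("[NH3+]CC(=O)O"), "neutral")
  g <- parse_smiles("C[N+](C)(C)CC(=O)[O-]")   # betaine: net zero but charged atoms
  expect_equal(msblocks:::.total_charge(g), 0L)
})

test_that("residue formulas follow water or dihydrogen elimination", {
  expect_equal(formula_to_string(residue_formula("C6H13NO2", 1)), "C6H11NO")
  expect_equal(formula_to_string(residue_formula("C4H12N2", 0)), "C4H10N2")
  expect_equal(formula_to_string(residue_formula("C4H6O3", 2)), "C4H4O2")
  expect_error(residue_formula("C4H10", 1), "negative")
})

test_that("a single unsplittable molecule is one block", {
  d <- decompose("NCC(=O)O")
  expect_equal(nrow(d$occurrences), 1L)
  expect_equal(d$type, "linear")
  expect_equal(d$notation, paste0("[", d$blocks[[1]]$acronym, "]"))
})
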