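test_that("terminal-modification validity rules follow the sequence type", {
  ac <- terminal_modification("Acetyl", "C2H2O", n_terminal = TRUE)
  am <- terminal_modification("Amide", "HN", n_terminal = FALSE)
  expect_equal(ac$monoisotopic_mass, 42.010565, tolerance = 1e-6)

  expect_length(validate_modifications("linear", list(ac, am)), 0L)
  expect_length(validate_modifications("linear", list()), 0L)
  expect_gt(length(validate_modifications("linear", list(ac, ac))), 0L)

  expect_gt(length(validate_modifications("cyclic", list(ac))), 0L)
  expect_gt(length(validate_modifications("cyclic-polyketide", list(am))), 0L)

  expect_length(validate_modifications("branched", list(ac)), 0L)
  expect_length(validate_modifications("branch-cyclic", list(am)), 0L)
  expect_gt(length(validate_modifications("branch-cyclic", list(ac, am))), 0L)

  # a linear polyketide may carry two modifications of the same polarity
  expect_length(validate_modifications("linear-polyketide", list(ac, ac)), 0L)
  expect_gt(length(validate_modifications("linear-polyketide",
                                          list(ac, ac, am))), 0L)
})

test_that("a one-block container exports one row of six fields", {
  cont <- new_container("tiny")
  cont <- container_add_block(cont, building_block(
    "Gly", "glycine", molecular_formula = "C2H5NO2",
    block_smiles = "NCC(=O)O"))
  payload <- export_cyclobranch(cont)$blocks
  rows <- strsplit(sub("\n$", "", payload), "\n")[[1]]
  expect_length(rows, 1L)
  # six fields = five tab separators (trailing fields may be empty)
  expect_equal(lengths(regmatches(rows, gregexpr("\t", rows, fixed = TRUE))),
               5L)
  f <- strsplit(rows, "\t")[[1]]
  expect_equal(f[2], "Gly")
  expect_equal(f[3], "C2H3NO")
  expect_equal(f[4], "57.021464")
})

test_that("the proteinogenic container exports twenty block rows", {
  payload <- export_cyclobranch(fx_proteinogenic())$blocks
  rows <- strsplit(sub("\n$", "", payload), "\n")[[1]]
  expect_length(rows, 20L)
})

# a container exercising every exported field
.rich_container <- function() {
  cont <- new_container("rich")
  cont <- container_add_modification(
    cont, terminal_modification("Acetyl", "C2H2O", n_terminal = TRUE))
  cont <- container_add_modification(
    cont, terminal_modification("Amide", "HN", n_terminal = FALSE))
  cont <- container_add_block(cont, building_block(
    "Ala", "alanine", molecular_formula = "C3H7NO2",
    block_smiles = generic_smiles("N[C@@H](C)C(=O)O"),
    losses = c("H2O", "NH3"), reference = "CID: 602"))
  cont <- container_add_block(cont, building_block(
    "Put", "putrescine", molecular_formula = "C4H12N2", c_termini = 0L,
    n_termini = 2L, block_smiles = "NCCCCN"))
  cont <- container_add_sequence(cont, sequence_record(
    name = "toy peptide", type = "linear", notation = "[Ala]-[Ala]",
    molecular_formula = "C6H12N2O3", families = "toys",
    organisms = "Escherichia coli",
    modifications = list(n = "Acetyl", c = "Amide"),
    reference = "CID: 1"))
  cont <- container_add_sequence(cont, sequence_record(
    name = "toy pk", type = "linear-polyketide", notation = "[Ala]-[Put]",
    molecular_formula = "C7H17N3O",
    modifications = list(n = "Acetyl")))
  cont
}

test_that("export -> import -> export is byte-identical", {
  cont <- .rich_container()
  p1 <- export_cyclobranch(cont)
  back <- import_cyclobranch(p1$blocks, p1$sequences, p1$modifications)
  p2 <- export_cyclobranch(back)
  expect_identical(p1, p2)
})

test_that("randomized containers survive the text round trip", {
  set.seed(57)
  for (rep in 1:5) {
    cont <- new_container("random")
    n_mod <- sample(0:2, 1)
    mods <- character(0)
    for (i in seq_len(n_mod)) {
      nm <- paste0("mod", i)
      cont <- container_add_modification(cont, terminal_modification(
        nm, stats::setNames(sample(1:6, 2), c("C", "H")),
        n_terminal = runif(1) < 0.5))
      mods <- c(mods, nm)
    }
    acrs <- character(0)
    for (i in seq_len(sample(1:6, 1))) {
      acr <- paste0("X", i)
      f <- stats::setNames(c(sample(1:9, 1), sample(1:19, 1), sample(0:3, 1),
                             sample(0:4, 1)), c("C", "H", "N", "O"))
      cont <- container_add_block(cont, building_block(
        acr, name = paste("block", i), molecular_formula = formula_add(f, "H2O"),
        losses = if (runif(1) < 0.3) c("H2O", "NH3") else character(0),
        reference = if (runif(1) < 0.5) paste0("CID: ", i) else NA_character_))
      acrs <- c(acrs, acr)
    }
    bb <- sample(acrs, sample(1:4, 1), replace = TRUE)
    cont <- container_add_sequence(cont, sequence_record(
      name = "seq one", type = "linear",
      notation = paste0("[", bb, "]", collapse = "-"),
      molecular_formula = "C10H20N2O4",
      modifications = if (n_mod > 0) list(n = mods[1]) else list()))
    p1 <- export_cyclobranch(cont)
    p2 <- export_cyclobranch(import_cyclobranch(p1$blocks, p1$sequences,
                                                p1$modifications))
    expect_identical(p1, p2)
  }
})

test_that("import recomputes masses from formulas and flags conflicts", {
  row <- "glycine\tGly\tC2H3NO\t57.021464\t\t"
  cont <- import_cyclobranch(blocks = paste0(row, "\n"))
  expect_equal(cont$blocks[[1]]$residue_mass, 57.021464, tolerance = 1e-6)

  bad <- "glycine\tGly\tC2H3NO\t57.100000\t\t"
  expect_warning(import_cyclobranch(blocks = paste0(bad, "\n")),
                 "formula wins")
  suppressWarnings(cont2 <- import_cyclobranch(blocks = paste0(bad, "\n")))
  expect_equal(cont2$blocks[[1]]$residue_mass, 57.021464, tolerance = 1e-6)
})

test_that("import reports malformed rows with their line number", {
  expect_error(import_cyclobranch(blocks = "a\tb\tc\n"), "line 1")
  two <- "glycine\tGly\tC2H3NO\t57.021464\t\t\nbroken row\n"
  expect_error(import_cyclobranch(blocks = two), "line 2")
  expect_error(import_cyclobranch(blocks = "x\tX\tnot-a-formula\t0\t\t\n"),
               "malformed formula")
})

test_that("semicolon-joined neutral losses import as separate formulas", {
  row <- "glycine\tGly\tC2H3NO\t57.021464\tH2O;NH3\t\n"
  cont <- import_cyclobranch(blocks = row)
  expect_equal(cont$blocks[[1]]$losses, c("H2O", "NH3"))
})

test_that("empty payloads give an empty container", {
  cont <- import_cyclobranch("", "", "")
  expect_length(cont$blocks, 0L)
  expect_length(cont$sequences, 0L)
  expect_length(cont$modifications, 0L)
})

test_that("JSON persistence round-trips every field", {
  cont <- .rich_container()
  path <- withr::local_tempfile(fileext = ".json")
  container_save(cont, path)
  back <- container_load(path)
  expect_identical(export_cyclobranch(back), export_cyclobranch(cont))
  expect_equal(back$blocks[[1]]$reference, "CID: 602")
  expect_equal(back$blocks[[1]]$block_smiles, cont$blocks[[1]]$block_smiles)
  expect_equal(back$sequences[[1]]$organisms, "Escherichia coli")
  expect_equal(back$name, cont$name)
})

test_that("schema and invariant violations are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = 99, name = "x"), path,
                       auto_unbox = TRUE)
  expect_error(container_load(path), "schema version")

  cont <- new_container("dups")
  blk <- building_block("Gly", molecular_formula = "C2H5NO2")
  cont <- container_add_block(cont, blk)
  expect_error(container_add_block(cont, blk), "duplicate")

  cont2 <- new_container("missing-acronym")
  expect_error(container_add_sequence(cont2, sequence_record(
    name = "s", type = "linear", notation = "[Zz]",
    molecular_formula = "CH4")), "unknown block")

  expect_error(container_add_sequence(
    .rich_container(), sequence_record(
      name = "bad mods", type = "cyclic", notation = "[Ala]-[Ala]",
      molecular_formula = "C6H12N2O3",
      modifications = list(n = "Acetyl"))), "invalid modification")
})
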