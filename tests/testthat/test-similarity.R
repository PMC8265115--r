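test_that("pseudacyclin A vs B gives the printed 5/6 similarity", {
  da <- decompose(fx_pseudacyclin_a())
  db <- decompose(fx_pseudacyclin_b())
  set_a <- vapply(da$blocks, `[[`, character(1), "block_smiles")
  set_b <- vapply(db$blocks, `[[`, character(1), "block_smiles")
  expect_length(set_a, 5L)   # {Pro, Ile, Orn, Phe, Ac-Ile}
  expect_length(set_b, 6L)   # one Ile -> Val adds a sixth structure
  expect_equal(tanimoto(set_a, set_b), 5 / 6)
})

test_that("tanimoto is symmetric, bounded, and exact on edge cases", {
  expect_equal(tanimoto(c("x", "y"), c("x", "y")), 1)
  expect_equal(tanimoto(c("x"), c("y")), 0)
  expect_equal(tanimoto(character(0), character(0)), 0)
  set.seed(19)
  pool <- paste0("blk", 1:12)
  for (i in 1:50) {
    a <- sample(pool, sample(0:8, 1))
    b <- sample(pool, sample(0:8, 1))
    # independent set-arithmetic oracle
    uni <- length(union(a, b))
    expected <- if (uni == 0) 0 else length(intersect(a, b)) / uni
    expect_equal(tanimoto(a, b), expected)
    expect_equal(tanimoto(b, a), tanimoto(a, b))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
    if (length(a) > 0) expect_equal(tanimoto(a, a), 1)
  }
})

# container holding desferrioxamine B as Hpd/Suc blocks with two families
.dfo_container <- function() {
  cont <- new_container("siderophore shelf")
  cont <- container_add_block(cont, building_block(
    "Hpd", "N-hydroxy-1,5-pentanediamine", molecular_formula = "C5H14N2O",
    block_smiles = generic_smiles("NCCCCCNO"), n_termini = 2L,
    c_termini = 0L))
  cont <- container_add_block(cont, building_block(
    "Suc", "succinic semialdehyde", molecular_formula = "C4H6O3",
    block_smiles = generic_smiles("O=CCCC(=O)O"), n_termini = 0L,
    c_termini = 2L))
  container_add_sequence(cont, sequence_record(
    name = "desferrioxamine B", type = "linear-polyketide",
    notation = "[Hpd]-[Suc]-[Hpd]-[Suc]-[Hpd]",
    molecular_formula = "C25H48N6O8",
    families = c("ferrioxamines", "siderophores")))
}

test_that("desferrioxamine E inherits both families of desferrioxamine B", {
  cont <- .dfo_container()
  d <- decompose(fx_dfo_e())
  rec <- recommend_families_tanimoto(d, cont)
  expect_setequal(rec$families, c("ferrioxamines", "siderophores"))
  expect_equal(rec$sequence_name, "desferrioxamine B")
  expect_equal(rec$score, 1)
})

test_that("ties resolve toward the closest total block count", {
  cont <- new_container("ties")
  for (a in c("P", "Q", "R")) {
    cont <- container_add_block(cont, building_block(
      a, molecular_formula = "C2H5NO2", block_smiles = paste0("smi-", a)))
  }
  mk <- function(name, notation, fam) sequence_record(
    name = name, type = "linear", notation = notation,
    molecular_formula = "C4H8N2O3", families = fam)
  # same block set {P, Q}, totals 6 vs 2
  cont <- container_add_sequence(cont, mk(
    "long", "[P]-[Q]-[P]-[Q]-[P]-[Q]", "family-long"))
  cont <- container_add_sequence(cont, mk("short", "[P]-[Q]", "family-short"))
  q <- list(set = c("smi-P", "smi-Q"), total = 2L)
  expect_equal(recommend_families_tanimoto(q, cont)$families, "family-short")
  q6 <- list(set = c("smi-P", "smi-Q"), total = 6L)
  expect_equal(recommend_families_tanimoto(q6, cont)$families, "family-long")
})

test_that("no recommendation from empty or unrelated containers", {
  empty <- new_container("empty")
  q <- list(set = "anything", total = 1L)
  expect_length(recommend_families_tanimoto(q, empty)$families, 0L)
  cont <- .dfo_container()
  unrelated <- list(set = "some-other-structure", total = 3L)
  expect_length(recommend_families_tanimoto(unrelated, cont)$families, 0L)
})

test_that("text search drops the last name token and matches case-insensitively", {
  cont <- new_container("names")
  cont <- container_add_sequence(cont, sequence_record(
    name = "pseudacyclin A", type = "other", molecular_formula = "C39H61N7O7",
    families = "pseudacyclins"))
  rec <- recommend_families_text("pseudacyclin B", cont)
  expect_equal(rec$families, "pseudacyclins")
  expect_equal(rec$substring, "pseudacyclin")

  cont2 <- new_container("names2")
  cont2 <- container_add_sequence(cont2, sequence_record(
    name = "desferrioxamine B", type = "other",
    molecular_formula = "C25H48N6O8", families = "ferrioxamines"))
  expect_equal(recommend_families_text("ferrioxamine", cont2)$families,
               "ferrioxamines")
  expect_length(recommend_families_text("unrelated compound",
                                        new_container("e"))$families, 0L)
})
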