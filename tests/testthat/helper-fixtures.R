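# Fixture molecules assembled in code from monomer structures, plus random
# assembly-spec generators for the property suites. Everything is built at
# test time; nothing binary is stored.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(key, build) {
  if (!exists(key, envir = .fx_cache)) assign(key, build(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_proteinogenic <- function() fx("proteinogenic", proteinogenic_container)

# pseudacyclin A: cyclo(Pro-Ile-Ile-Orn-Phe), N-acetyl-isoleucine on the
# ornithine delta-amine (atom 6 of the Orn SMILES)
fx_pseudacyclin_spec <- function(third = "Ile") {
  assembly_spec(c("Pro", "Ile", third, "Orn", "Phe"), cyclic = TRUE,
                branch = list(at = 4, site = 6, blocks = c("Ile", "Ac")))
}
fx_pseudacyclin_a <- function() fx("psa", function() assemble(fx_pseudacyclin_spec()))
fx_pseudacyclin_b <- function() fx("psb", function() assemble(fx_pseudacyclin_spec("Val")))

# desferrioxamine B core (des-acetyl): Hpd-Suc-Hpd-Suc-Hpd; the hydroxamate
# nitrogen of Hpd is atom 7, the primary amine atom 1
fx_dfo_linkages <- function() {
  data.frame(donor = c(2, 2, 4, 4), acceptor = c(1, 3, 3, 5),
             donor_site = NA_integer_, acceptor_site = c(7, 1, 7, 1))
}
fx_dfo_core <- function() fx("dfo_core", function()
  assemble(assembly_spec(c("Hpd", "Suc", "Hpd", "Suc", "Hpd"),
                         linkages = fx_dfo_linkages())))
fx_dfo_b <- function() fx("dfo_b", function() {
  lk <- rbind(fx_dfo_linkages(),
              data.frame(donor = 6, acceptor = 5, donor_site = NA_integer_,
                         acceptor_site = 7))
  assemble(assembly_spec(c("Hpd", "Suc", "Hpd", "Suc", "Hpd", "Ac"),
                         linkages = lk))
})

# desferrioxamine E: the cyclic trimer of Hpd-Suc
fx_dfo_e <- function() fx("dfo_e", function() {
  lk <- data.frame(donor = c(2, 2, 4, 4, 6, 6),
                   acceptor = c(1, 3, 3, 5, 5, 1),
                   donor_site = NA_integer_,
                   acceptor_site = c(7, 1, 7, 1, 7, 1))
  assemble(assembly_spec(rep(c("Hpd", "Suc"), 3), linkages = lk))
})

# ornibactin-like linear chain terminated by putrescine
fx_ornibactin_like <- function() fx("orni", function()
  assemble(c("Orn", "Asp", "Ser", "Orn", "Put")))

# small depsipeptide with one backbone ester (glycolyl via lactic acid)
fx_depsipeptide <- function() fx("depsi", function()
  assemble(c("Gly", "Lac", "Ala")))

# ---- random assembly specs for property suites -------------------------

# amino acids that keep auto site selection unambiguous in chains
.chain_pool <- c("Gly", "Ala", "Val", "Leu", "Ile", "Pro", "Phe", "Trp",
                 "Met", "Ser", "Thr", "Tyr", "Asn", "Gln", "Asp", "Glu",
                 "His", "Sar")

random_assembly_case <- function() {
  class <- sample(c("linear", "cyclic", "branched", "put"), 1,
                  prob = c(0.35, 0.25, 0.2, 0.2))
  if (class == "linear") {
    blocks <- sample(.chain_pool, sample(2:8, 1), replace = TRUE)
    spec <- assembly_spec(blocks)
    list(spec = spec, monomers = blocks, type = "linear", caps = "H2O")
  } else if (class == "cyclic") {
    blocks <- sample(.chain_pool, sample(2:7, 1), replace = TRUE)
    spec <- assembly_spec(blocks, cyclic = TRUE)
    list(spec = spec, monomers = blocks, type = "cyclic", caps = "")
  } else if (class == "branched") {
    n_back <- sample(3:5, 1)
    interior <- 2:(n_back - 1L)
    at <- interior[sample.int(length(interior), 1)]
    backbone <- sample(.chain_pool, n_back, replace = TRUE)
    hub <- sample(c("Lys", "Orn"), 1)
    backbone[at] <- hub
    site <- if (hub == "Lys") 7L else 6L       # side-chain amine atom
    branch <- sample(.chain_pool, sample(1:3, 1), replace = TRUE)
    spec <- assembly_spec(backbone,
                          branch = list(at = at, site = site, blocks = branch))
    list(spec = spec, monomers = c(backbone, branch), type = "branched",
         caps = "H2O")
  } else {
    blocks <- c(sample(.chain_pool, sample(2:6, 1), replace = TRUE), "Put")
    spec <- assembly_spec(blocks)
    list(spec = spec, monomers = blocks, type = "linear-polyketide",
         caps = "H2")
  }
}

# expected block-structure multiset of a case: capped blocks equal the free
# monomers, compared on canonical stereo-free SMILES
expected_block_multiset <- function(monomers) {
  sort(vapply(monomers, function(m) fx(paste0("gs_", m), function()
    generic_smiles(monomer_smiles(m))), character(1)))
}

# round-trip check used by both the unit and acceptance suites
check_roundtrip_case <- function(case) {
  smi <- assemble(case$spec)
  d <- decompose(smi)
  ok_type <- identical(d$type, case$type)
  got <- sort(d$occurrences$smiles)
  ok_blocks <- identical(got, unname(expected_block_multiset(case$monomers)))
  # formula conservation: residues plus the class's chain-end caps
  sum_res <- Reduce(formula_add, lapply(d$occurrences$residue, as_chem_formula))
  expected <- if (nzchar(case$caps)) formula_add(sum_res, case$caps) else sum_res
  ok_formula <- formula_equal(expected, formula_of(d$graph))
  list(ok = ok_type && ok_blocks && ok_formula, ok_type = ok_type,
       ok_blocks = ok_blocks, ok_formula = ok_formula, smiles = smi,
       type = d$type)
}

# random well-formed block sequences for the notation round trip
random_block_sequence <- function() {
  acr <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c(LETTERS, letters, 0:9), sample(1:4, 1), replace = TRUE),
          collapse = ""), character(1))
  if (runif(1) < 0.5) {
    block_sequence(acr(sample(1:8, 1)), type = "linear")
  } else {
    n_back <- sample(2:6, 1)
    block_sequence(acr(n_back), branch = acr(sample(1:4, 1)),
                   branch_at = sample(seq_len(n_back), 1), type = "branched")
  }
}
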