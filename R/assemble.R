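#' @title Assembly of peptides and polyketides from monomers
#'
#' @description The fixture generator condenses free monomers into a single
#' molecule: each linkage removes the hydroxyl of a donor carboxyl group and
#' bonds its carbonyl carbon to an acceptor amine nitrogen (amide) or
#' hydroxyl oxygen (ester), i.e. a condensation with loss of one water per
#' linkage. It is the independent construction route used to exercise the
#' decomposition: building a molecule from known blocks and decomposing it
#' must recover the block multiset and topology.
#' @name assembly
NULL

#' Monomer table
#'
#' The twenty proteinogenic amino acids plus the non-proteinogenic monomers
#' used throughout the examples: ornithine (Orn), putrescine (Put),
#' N-hydroxy-1,5-pentanediamine (Hpd), succinic acid (the Suc donor),
#' acetic acid (Ac), sarcosine (Sar) and lactic acid (Lac).
#'
#' @return Data frame with `acronym`, `name`, `smiles`, `proteinogenic`.
#' @export
msb_monomers <- function() {
  read_tbl <- function(...) {
    data.frame(..., stringsAsFactors = FALSE)
  }
  aa <- rbind(
    read_tbl(acronym = "Gly", name = "glycine",       smiles = "NCC(=O)O"),
    read_tbl(acronym = "Ala", name = "alanine",       smiles = "N[C@@H](C)C(=O)O"),
    read_tbl(acronym = "Val", name = "valine",        smiles = "N[C@@H](C(C)C)C(=O)O"),
    read_tbl(acronym = "Leu", name = "leucine",       smiles = "N[C@@H](CC(C)C)C(=O)O"),
    read_tbl(acronym = "Ile", name = "isoleucine",    smiles = "N[C@@H]([C@@H](C)CC)C(=O)O"),
    read_tbl(acronym = "Pro", name = "proline",       smiles = "OC(=O)[C@@H]1CCCN1"),
    read_tbl(acronym = "Phe", name = "phenylalanine", smiles = "N[C@@H](Cc1ccccc1)C(=O)O"),
    read_tbl(acronym = "Trp", name = "tryptophan",    smiles = "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O"),
    read_tbl(acronym = "Met", name = "methionine",    smiles = "N[C@@H](CCSC)C(=O)O"),
    read_tbl(acronym = "Cys", name = "cysteine",      smiles = "N[C@@H](CS)C(=O)O"),
    read_tbl(acronym = "Ser", name = "serine",        smiles = "N[C@@H](CO)C(=O)O"),
    read_tbl(acronym = "Thr", name = "threonine",     smiles = "N[C@@H]([C@H](O)C)C(=O)O"),
    read_tbl(acronym = "Tyr", name = "tyrosine",      smiles = "N[C@@H](Cc1ccc(O)cc1)C(=O)O"),
    read_tbl(acronym = "Asn", name = "asparagine",    smiles = "N[C@@H](CC(N)=O)C(=O)O"),
    read_tbl(acronym = "Gln", name = "glutamine",     smiles = "N[C@@H](CCC(N)=O)C(=O)O"),
    read_tbl(acronym = "Asp", name = "aspartic acid", smiles = "OC(=O)[C@@H](N)CC(O)=O"),
    read_tbl(acronym = "Glu", name = "glutamic acid", smiles = "OC(=O)[C@@H](N)CCC(O)=O"),
    read_tbl(acronym = "Lys", name = "lysine",        smiles = "N[C@@H](CCCCN)C(=O)O"),
    read_tbl(acronym = "Arg", name = "arginine",      smiles = "N[C@@H](CCCNC(N)=N)C(=O)O"),
    read_tbl(acronym = "His", name = "histidine",     smiles = "N[C@@H](Cc1c[nH]cn1)C(=O)O")
  )
  aa$proteinogenic <- TRUE
  extra <- rbind(
    read_tbl(acronym = "Orn", name = "ornithine",  smiles = "N[C@@H](CCCN)C(=O)O"),
    read_tbl(acronym = "Put", name = "putrescine", smiles = "NCCCCN"),
    read_tbl(acronym = "Hpd", name = "N-hydroxy-1,5-pentanediamine",
             smiles = "NCCCCCNO"),
    read_tbl(acronym = "Suc", name = "succinic acid", smiles = "OC(=O)CCC(=O)O"),
    read_tbl(acronym = "Ac",  name = "acetic acid",   smiles = "CC(=O)O"),
    read_tbl(acronym = "Sar", name = "sarcosine",     smiles = "CNCC(=O)O"),
    read_tbl(acronym = "Lac", name = "lactic acid",   smiles = "C[C@H](O)C(=O)O")
  )
  extra$proteinogenic <- FALSE
  rbind(aa, extra)
}

#' Look up a monomer SMILES by acronym
#'
#' @param acronym Acronym in [msb_monomers()].
#' @return SMILES string.
#' @export
monomer_smiles <- function(acronym) {
  tab <- msb_monomers()
  i <- match(acronym, tab$acronym)
  if (is.na(i)) stop("unknown monomer acronym: ", acronym, call. = FALSE)
  tab$smiles[i]
}

#' Build an assembly specification
#'
#' Blocks are given as SMILES strings (or acronyms from [msb_monomers()]).
#' By default block i donates its carboxyl to the amine of block i+1; with
#' `cyclic = TRUE` the last block also donates to the first. A single pendant
#' branch attaches its innermost block's carboxyl to an explicit acceptor
#' site of a backbone block. Explicit `linkages` override the chain default
#' entirely (needed for polyketides, where linkage direction alternates).
#'
#' Site positions are 1-based heavy-atom indices into the block's own
#' SMILES, as parsed by [parse_smiles()]; `NA` selects automatically (the
#' alpha carboxyl/amine is preferred, then the first chemically compatible
#' site).
#'
#' @param blocks Character vector of block SMILES or monomer acronyms.
#' @param cyclic Close the chain head-to-tail?
#' @param branch Optional list: `at` (backbone block index), `site` (acceptor
#'   atom in that block, or `NA`), `blocks` (branch block SMILES/acronyms,
#'   innermost first).
#' @param linkages Optional data frame with columns `donor`, `acceptor`
#'   (block indices) and optional `donor_site`, `acceptor_site`.
#' @return An `assembly_spec`.
#' @export
assembly_spec <- function(blocks, cyclic = FALSE, branch = NULL,
                          linkages = NULL) {
  tab <- msb_monomers()
  resolve <- function(x) ifelse(x %in% tab$acronym,
                                tab$smiles[match(x, tab$acronym)], x)
  blocks <- resolve(as.character(blocks))
  n <- length(blocks)
  stopifnot(n >= 1L)
  if (is.null(linkages)) {
    linkages <- if (n > 1L) {
      data.frame(donor = seq_len(n - 1L), acceptor = seq_len(n - 1L) + 1L,
                 donor_site = NA_integer_, acceptor_site = NA_integer_)
    } else {
      data.frame(donor = integer(0), acceptor = integer(0),
                 donor_site = integer(0), acceptor_site = integer(0))
    }
    if (cyclic) {
      if (n < 2L) stop("a cycle needs at least two blocks", call. = FALSE)
      linkages <- rbind(linkages,
                        data.frame(donor = n, acceptor = 1L,
                                   donor_site = NA_integer_,
                                   acceptor_site = NA_integer_))
    }
  } else {
    linkages <- as.data.frame(linkages)
    if (is.null(linkages$donor_site)) linkages$donor_site <- NA_integer_
    if (is.null(linkages$acceptor_site)) linkages$acceptor_site <- NA_integer_
  }
  if (!is.null(branch)) {
    stopifnot(!is.null(branch$at), !is.null(branch$blocks),
              length(branch$blocks) >= 1L)
    br <- resolve(as.character(branch$blocks))
    ids <- n + seq_along(br)
    blocks <- c(blocks, br)
    linkages <- rbind(linkages, data.frame(
      donor = ids[1], acceptor = branch$at,
      donor_site = NA_integer_,
      acceptor_site = if (is.null(branch$site)) NA_integer_ else
        as.integer(branch$site)))
    if (length(ids) > 1L) {
      linkages <- rbind(linkages, data.frame(
        donor = ids[-1], acceptor = ids[-length(ids)],
        donor_site = NA_integer_, acceptor_site = NA_integer_))
    }
  }
  structure(list(blocks = blocks, linkages = linkages, cyclic = isTRUE(cyclic),
                 branch = branch),
            class = "assembly_spec")
}

#' Assemble a molecule from an assembly specification
#'
#' @param spec An `assembly_spec` (or arguments forwarded to
#'   [assembly_spec()]).
#' @param ... Forwarded to [assembly_spec()] when `spec` is a block vector.
#' @return Canonical SMILES of the condensed molecule.
#' @examples
#' assemble(c("Gly", "Gly"))   # glycylglycine
#' @export
assemble <- function(spec, ...) {
  if (!inherits(spec, "assembly_spec")) spec <- assembly_spec(spec, ...)
  graphs <- lapply(spec$blocks, parse_smiles)
  offsets <- cumsum(c(0L, vapply(graphs, function(g) nrow(g$atoms),
                                 integer(1))))
  atoms <- do.call(rbind, lapply(graphs, `[[`, "atoms"))
  bonds <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    b <- graphs[[i]]$bonds
    b$a1 <- b$a1 + offsets[i]; b$a2 <- b$a2 + offsets[i]
    b
  }))
  if (any(atoms$charge != 0L)) {
    stop("assembly requires neutral blocks", call. = FALSE)
  }

  used_donor_c <- integer(0)     # global carbonyl-carbon indices consumed
  used_acceptor <- integer(0)    # global acceptor atoms consumed
  drop_atoms <- integer(0)       # hydroxyl oxygens removed by condensation
  new_bonds <- NULL

  for (i in seq_len(nrow(spec$linkages))) {
    lk <- spec$linkages[i, ]
    dg <- graphs[[lk$donor]]; ag <- graphs[[lk$acceptor]]
    doff <- offsets[lk$donor]; aoff <- offsets[lk$acceptor]
    local_used <- function(used, off, g) {
      u <- used[used > off & used <= off + nrow(g$atoms)]
      u - off
    }

    site <- .pick_carboxyl(dg, lk$donor_site,
                           used = local_used(used_donor_c, doff, dg))
    if (is.na(site$c)) {
      stop("block ", lk$donor, " has no free carboxyl group to donate",
           call. = FALSE)
    }
    acc <- .pick_acceptor(ag, lk$acceptor_site,
                          used = local_used(used_acceptor, aoff, ag))
    if (is.na(acc)) {
      stop("block ", lk$acceptor, " has no free amine or hydroxyl acceptor",
           call. = FALSE)
    }
    used_donor_c <- c(used_donor_c, site$c + doff)
    used_acceptor <- c(used_acceptor, acc + aoff)
    drop_atoms <- c(drop_atoms, site$oh + doff)
    new_bonds <- rbind(new_bonds,
                       data.frame(a1 = site$c + doff, a2 = acc + aoff,
                                  order = 1L))
  }

  keep <- setdiff(seq_len(nrow(atoms)), drop_atoms)
  remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
  all_bonds <- rbind(bonds, new_bonds)
  ok <- all_bonds$a1 %in% keep & all_bonds$a2 %in% keep
  all_bonds <- all_bonds[ok, , drop = FALSE]
  all_bonds$a1 <- remap[all_bonds$a1]; all_bonds$a2 <- remap[all_bonds$a2]
  .graph_to_canonical_smiles(atoms[keep, , drop = FALSE], all_bonds)
}

# carboxyl groups of a block graph: carbonyl C with a single-bonded,
# terminal O-H; alpha carboxyls (C neighbor carrying an amine N) preferred
.pick_carboxyl <- function(graph, site, used = integer(0)) {
  el <- graph$atoms$element; nH <- graph$atoms$nH
  nb <- .neighbors(graph)
  carbonyl <- .carbonyl_carbons(graph)
  b <- graph$bonds
  oh_of <- function(cc) {
    for (x in nb[[cc]]) {
      if (el[x] == "O" && nH[x] >= 1L && length(nb[[x]]) == 1L) {
        bo <- b$order[(b$a1 == cc & b$a2 == x) | (b$a1 == x & b$a2 == cc)]
        if (any(bo == 1L)) return(x)
      }
    }
    NA_integer_
  }
  cands <- setdiff(carbonyl[!is.na(vapply(carbonyl, oh_of, integer(1)))], used)
  if (!is.na(site)) {
    if (!(site %in% cands)) {
      stop("atom ", site, " is not a free carboxyl carbon", call. = FALSE)
    }
    cands <- site
  } else if (length(cands) > 1L) {
    is_alpha <- vapply(cands, function(cc) {
      any(vapply(nb[[cc]], function(x) {
        el[x] == "C" && any(el[nb[[x]]] == "N")
      }, logical(1)))
    }, logical(1))
    if (any(is_alpha)) cands <- cands[is_alpha]
  }
  if (length(cands) == 0L) return(list(c = NA_integer_, oh = NA_integer_))
  cc <- min(cands)
  list(c = cc, oh = oh_of(cc))
}

# acceptor site: amine N (>=1 H, not amide, not aromatic, no double bond),
# alpha amines preferred; hydroxyl O as ester fallback
.pick_acceptor <- function(graph, site, used = integer(0)) {
  el <- graph$atoms$element; nH <- graph$atoms$nH
  arom <- graph$atoms$aromatic
  nb <- .neighbors(graph)
  carbonyl <- .carbonyl_carbons(graph)
  b <- graph$bonds
  has_double <- rep(FALSE, nrow(graph$atoms))
  dbl <- b[b$order >= 2L, , drop = FALSE]
  has_double[c(dbl$a1, dbl$a2)] <- TRUE

  is_amine <- function(a) {
    el[a] == "N" && !arom[a] && nH[a] >= 1L && !has_double[a] &&
      !any(nb[[a]] %in% carbonyl)
  }
  is_hydroxyl <- function(a) {
    el[a] == "O" && nH[a] >= 1L && length(nb[[a]]) == 1L &&
      !any(nb[[a]] %in% carbonyl)
  }
  if (!is.na(site)) {
    if (site < 1L || site > nrow(graph$atoms)) {
      stop("acceptor site ", site, " is out of range for a block with ",
           nrow(graph$atoms), " heavy atoms", call. = FALSE)
    }
    if (site %in% used) stop("acceptor site ", site, " already used",
                             call. = FALSE)
    if (!(is_amine(site) || is_hydroxyl(site))) {
      stop("atom ", site, " is not a free amine or hydroxyl", call. = FALSE)
    }
    return(site)
  }
  amines <- setdiff(which(vapply(seq_len(nrow(graph$atoms)), is_amine,
                                 logical(1))), used)
  if (length(amines) > 1L) {
    is_alpha <- vapply(amines, function(a) {
      any(vapply(nb[[a]], function(x) {
        el[x] == "C" && any(nb[[x]] %in% carbonyl)
      }, logical(1)))
    }, logical(1))
    if (any(is_alpha)) amines <- amines[is_alpha]
  }
  if (length(amines) > 0L) return(min(amines))
  ohs <- setdiff(which(vapply(seq_len(nrow(graph$atoms)), is_hydroxyl,
                              logical(1))), used)
  if (length(ohs) > 0L) return(min(ohs))
  NA_integer_
}
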