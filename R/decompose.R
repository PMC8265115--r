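#' @title Decomposition of a molecule into building blocks
#'
#' @description Removing the cleavable bonds partitions the molecular graph
#' into connected fragments, one per building-block occurrence. Each cleaved
#' bond contributes a directed linkage from the fragment holding the carbonyl
#' carbon (acyl side) to the fragment holding the nitrogen or oxygen
#' (amine/alkoxy side). Fragments are capped back to free monomers: every
#' cleaved amine or alkoxy site regains a hydrogen, and the first cleaved acyl
#' site regains a hydroxyl (restoring a carboxyl group); further acyl sites
#' keep their formyl form, since mass spectrometry cannot place the extra
#' oxygen. Residue formulas follow the water-elimination convention: molecular
#' formula minus H2O for blocks with a C-terminus, minus H2 for blocks without
#' one (the polyketide case, e.g. putrescine).
#' @name decomposition
NULL

#' Building-block record
#'
#' @param acronym Short unique label used in sequence notation.
#' @param name Full compound name (may be empty).
#' @param molecular_formula Formula of the free (capped) monomer.
#' @param block_smiles Canonical stereo-free SMILES of the free monomer.
#' @param n_termini,c_termini Terminus counts of the block as found in the
#'   parent structure.
#' @param losses Character vector of neutral-loss formulas (user metadata,
#'   passed through).
#' @param reference Optional external reference, e.g. `"CID: 602"`.
#' @return A `building_block` with residue formula and both monoisotopic
#'   masses derived from the molecular formula.
#' @export
building_block <- function(acronym, name = "", molecular_formula,
                           block_smiles = NA_character_,
                           n_termini = 1L, c_termini = 1L,
                           losses = character(0), reference = NA_character_) {
  stopifnot(is.character(acronym), nzchar(acronym))
  mol <- as_chem_formula(molecular_formula)
  res <- residue_formula(mol, c_termini)
  structure(list(
    acronym = acronym,
    name = name,
    molecular_formula = formula_to_string(mol),
    residue_formula = formula_to_string(res),
    residue_mass = monoisotopic_mass(res),
    block_smiles = block_smiles,
    n_termini = as.integer(n_termini),
    c_termini = as.integer(c_termini),
    losses = losses,
    reference = reference
  ), class = "building_block")
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf("<building_block> %s (%s) residue %s %.6f Da  [n=%d, c=%d]\n",
              x$acronym, if (nzchar(x$name)) x$name else "unnamed",
              x$residue_formula, x$residue_mass, x$n_termini, x$c_termini))
  invisible(x)
}

#' Residue formula of a building block
#'
#' Water elimination for blocks with a C-terminus; elimination of two
#' hydrogens for blocks without one (polyketide blocks such as putrescine,
#' which contains no oxygen to eliminate).
#'
#' @param molecular_formula Molecular formula of the free monomer.
#' @param c_termini Number of C-termini of the block.
#' @return A `chem_formula`.
#' @examples
#' residue_formula("C6H13NO2", 1)  # Ile -> C6H11NO
#' residue_formula("C4H12N2", 0)   # Put -> C4H10N2
#' @export
residue_formula <- function(molecular_formula, c_termini) {
  formula_subtract(molecular_formula,
                   if (c_termini >= 1L) "H2O" else "H2")
}

# ---- splitting ---------------------------------------------------------

#' Split an annotated molecule into building-block occurrences
#'
#' @param graph A `mol_graph` of the neutral parent molecule.
#' @param annotation A `bond_annotation` (possibly empty: the whole molecule
#'   is then a single block).
#' @return A `block_graph`: list with `occurrences` (data frame: `occ`,
#'   capped `smiles`, `n_termini`, `c_termini`, `sitting`, `molecular`,
#'   `residue` formula strings, `first_atom`), `edges` (data frame: `from`
#'   acyl-side occurrence, `to` amine/alkoxy-side occurrence, `bond`,
#'   `kind`), the atom `membership` vector, and the parent `graph`.
#' @export
split_blocks <- function(graph, annotation) {
  stopifnot(inherits(graph, "mol_graph"), inherits(annotation, "bond_annotation"))
  if (.total_charge(graph) != 0L) {
    stop("decomposition requires a neutral parent molecule (total charge ",
         .total_charge(graph), ")", call. = FALSE)
  }
  cleaved <- annotation$cleavable
  memb_raw <- .component_membership(graph, cleaved)
  # relabel components in order of their lowest atom index
  first_seen <- unique(memb_raw)
  relabel <- integer(max(memb_raw))
  relabel[first_seen] <- seq_along(first_seen)
  membership <- relabel[memb_raw]
  n_occ <- length(first_seen)

  el <- graph$atoms$element
  carbonyl <- .carbonyl_carbons(graph)

  edges <- data.frame(from = integer(0), to = integer(0), bond = integer(0),
                      kind = character(0), acyl_atom = integer(0),
                      het_atom = integer(0), stringsAsFactors = FALSE)
  for (i in cleaved) {
    e <- c(graph$bonds$a1[i], graph$bonds$a2[i])
    det <- annotation$detail[annotation$detail$bond == i, , drop = FALSE]
    if (nrow(det) == 1L) {
      acyl <- det$acyl; het <- det$het; kind <- det$kind
    } else {
      cc <- e[e %in% carbonyl & el[e] == "C"]
      if (length(cc) >= 1L) {
        acyl <- cc[1]; het <- setdiff(e, acyl)[1]
        kind <- if (el[het] == "N") "amide" else if (el[het] == "O") "ester" else "manual"
      } else {
        acyl <- min(e); het <- max(e); kind <- "manual"
      }
    }
    edges <- rbind(edges, data.frame(
      from = membership[acyl], to = membership[het], bond = i, kind = kind,
      acyl_atom = acyl, het_atom = het, stringsAsFactors = FALSE))
  }

  engaged_atoms <- c(edges$acyl_atom, edges$het_atom)
  occs <- lapply(seq_len(n_occ), function(k) {
    atoms <- which(membership == k)
    acyl_sites <- edges$acyl_atom[edges$from == k & edges$acyl_atom %in% atoms]
    # an occurrence can be on the acyl side of one bond and acceptor of another
    acc_sites <- edges$het_atom[edges$to == k & edges$het_atom %in% atoms]
    free <- .free_termini(graph, atoms, exclude = engaged_atoms)
    cap <- cap_termini(graph, atoms, acyl_sites, acc_sites)
    n_t <- length(acc_sites) + free$n
    c_t <- length(acyl_sites) + free$c
    res <- residue_formula(cap$molecular, c_t)
    data.frame(occ = k, smiles = cap$smiles,
               n_termini = n_t, c_termini = c_t,
               sitting = formula_to_string(cap$sitting),
               molecular = formula_to_string(cap$molecular),
               residue = formula_to_string(res),
               first_atom = min(atoms), stringsAsFactors = FALSE)
  })
  occurrences <- do.call(rbind, occs)

  structure(list(graph = graph, membership = membership,
                 occurrences = occurrences,
                 edges = edges[, c("from", "to", "bond", "kind"),
                               drop = FALSE]),
            class = "block_graph")
}

# free C-termini (carboxyls) and N-termini (amines with >= 1 H) on atoms of a
# fragment that are not endpoints of any cleaved bond
.free_termini <- function(graph, atoms, exclude) {
  el <- graph$atoms$element
  nH <- graph$atoms$nH
  arom <- graph$atoms$aromatic
  nb <- .neighbors(graph)
  b <- graph$bonds
  has_double <- rep(FALSE, nrow(graph$atoms))
  dbl <- b[b$order >= 2L, , drop = FALSE]
  has_double[c(dbl$a1, dbl$a2)] <- TRUE
  carbonyl <- .carbonyl_carbons(graph)

  candidates <- setdiff(atoms, exclude)
  n_count <- 0L; c_count <- 0L
  for (a in candidates) {
    if (el[a] == "C" && a %in% carbonyl) {
      # free carboxyl: additionally a single-bonded O-H with no other heavy atom
      for (x in nb[[a]]) {
        if (el[x] == "O" && nH[x] >= 1L && length(nb[[x]]) == 1L &&
            x %in% atoms) {
          bo <- b$order[(b$a1 == a & b$a2 == x) | (b$a1 == x & b$a2 == a)]
          if (any(bo == 1L)) { c_count <- c_count + 1L; break }
        }
      }
    } else if (el[a] == "N" && !arom[a] && nH[a] >= 1L && !has_double[a]) {
      # free amine: not acylated within the fragment
      acylated <- any(vapply(nb[[a]], function(x)
        x %in% atoms && x %in% carbonyl, logical(1)))
      if (!acylated) n_count <- n_count + 1L
    }
  }
  list(n = n_count, c = c_count)
}

#' Cap a fragment back to a free monomer
#'
#' Every cleaved amine/alkoxy site regains a hydrogen; the first cleaved acyl
#' site regains a hydroxyl (carboxyl restoration), any further acyl site only
#' a hydrogen. The returned molecular formula follows the residue convention
#' (residue + H2O with a C-terminus, residue + H2 without).
#'
#' @param graph Parent `mol_graph`.
#' @param atoms Atom indices of the fragment.
#' @param acyl_sites Fragment atoms that were the carbonyl carbon of a cleaved
#'   bond.
#' @param acceptor_sites Fragment atoms that were the N/O side of a cleaved
#'   bond.
#' @return List with `smiles` (canonical, stereo-free block structure),
#'   `molecular` and `sitting` (`chem_formula`s; `sitting` is the fragment as
#'   embedded in the parent).
#' @export
cap_termini <- function(graph, atoms, acyl_sites = integer(0),
                        acceptor_sites = integer(0)) {
  stopifnot(all(acyl_sites %in% atoms), all(acceptor_sites %in% atoms))
  sub_atoms <- graph$atoms[atoms, , drop = FALSE]
  idx_map <- integer(nrow(graph$atoms))
  idx_map[atoms] <- seq_along(atoms)
  in_frag <- graph$bonds$a1 %in% atoms & graph$bonds$a2 %in% atoms
  sub_bonds <- graph$bonds[in_frag, , drop = FALSE]
  sub_bonds$a1 <- idx_map[sub_bonds$a1]
  sub_bonds$a2 <- idx_map[sub_bonds$a2]

  sitting <- .new_formula(c(table(sub_atoms$element), H = sum(sub_atoms$nH)))

  # structural capping: one hydroxyl on the lowest-index engaged acyl carbon
  if (length(acyl_sites) > 0L) {
    hydroxyl_at <- idx_map[min(acyl_sites)]
    sub_atoms <- rbind(sub_atoms,
                       data.frame(element = "O", charge = 0L, nH = 1L,
                                  aromatic = FALSE, stringsAsFactors = FALSE))
    sub_bonds <- rbind(sub_bonds,
                       data.frame(a1 = hydroxyl_at, a2 = nrow(sub_atoms),
                                  order = 1L))
  }
  smiles <- .graph_to_canonical_smiles(sub_atoms, sub_bonds)
  if (grepl("[@/\\\\]", smiles)) smiles <- generic_smiles(smiles)

  caps <- formula_multiply("H", length(acceptor_sites))
  if (length(acyl_sites) > 0L) {
    caps <- formula_add(caps, "HO")
    caps <- formula_add(caps, formula_multiply("H", length(acyl_sites) - 1L))
  }
  molecular <- formula_add(sitting, caps)
  list(smiles = smiles, molecular = molecular, sitting = sitting)
}

#' @export
print.block_graph <- function(x, ...) {
  cat("<block_graph> ", nrow(x$occurrences), " occurrence(s), ",
      nrow(x$edges), " linkage(s)\n", sep = "")
  print(x$occurrences[, c("occ", "smiles", "n_termini", "c_termini",
                          "residue")])
  invisible(x)
}
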