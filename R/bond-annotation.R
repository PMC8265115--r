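#' @title Cleavable-bond perception
#'
#' @description Amide (peptide) bonds are C–N single bonds whose carbon also
#' carries a double-bonded oxygen; secondary and tertiary (N-alkylated) amides
#' both qualify, but nitrogens belonging to an aromatic ring do not. Ester
#' bonds are C(=O)–O single bonds whose oxygen is bonded to a second carbon.
#' A candidate bond is dropped when hypothetically cleaving it would leave a
#' fragment of three or fewer heavy atoms, so small terminal groups such as
#' acetyl never become blocks of their own.
#' @name bond_annotation
NULL

# carbonyl carbons: C with at least one double bond to O
.carbonyl_carbons <- function(graph) {
  b <- graph$bonds
  el <- graph$atoms$element
  dbl <- b[b$order == 2L, , drop = FALSE]
  cc <- c(dbl$a1[el[dbl$a1] == "C" & el[dbl$a2] == "O"],
          dbl$a2[el[dbl$a2] == "C" & el[dbl$a1] == "O"])
  unique(cc)
}

# neighbors of each atom (list of integer vectors)
.neighbors <- function(graph) {
  n <- nrow(graph$atoms)
  nb <- vector("list", n)
  b <- graph$bonds
  for (i in seq_len(nrow(b))) {
    nb[[b$a1[i]]] <- c(nb[[b$a1[i]]], b$a2[i])
    nb[[b$a2[i]]] <- c(nb[[b$a2[i]]], b$a1[i])
  }
  nb
}

# component sizes after deleting a set of bond indices
.component_membership <- function(graph, drop_bonds = integer(0)) {
  keep <- setdiff(seq_len(nrow(graph$bonds)), drop_bonds)
  b <- graph$bonds[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = b$a1, to = b$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$atoms))))
  igraph::components(g)$membership
}

#' Find cleavable peptide and ester bonds
#'
#' @param graph A `mol_graph`.
#' @param include_esters Perceive depsipeptide ester bonds as cleavable too
#'   (default `TRUE`).
#' @return A `bond_annotation`: list with `cleavable` (integer bond indices),
#'   `provenance` (named character, `"auto"`/`"manual-added"`/
#'   `"manual-removed"`), and `detail` (data frame of auto matches with the
#'   acyl-carbon and heteroatom endpoint of each bond and its kind).
#' @examples
#' g <- parse_smiles("NCC(=O)NCC(=O)O")   # glycylglycine
#' find_cleavable_bonds(g)$cleavable      # the one backbone amide
#' @export
find_cleavable_bonds <- function(graph, include_esters = TRUE) {
  stopifnot(inherits(graph, "mol_graph"))
  el <- graph$atoms$element
  arom <- graph$atoms$aromatic
  carbonyl <- .carbonyl_carbons(graph)
  nb <- .neighbors(graph)
  b <- graph$bonds

  detail <- data.frame(bond = integer(0), kind = character(0),
                       acyl = integer(0), het = integer(0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(b))) {
    if (b$order[i] != 1L) next
    e <- c(b$a1[i], b$a2[i])
    cc <- e[e %in% carbonyl & el[e] == "C"]
    if (length(cc) == 0L) next
    cc <- cc[1]
    other <- setdiff(e, cc)
    if (el[other] == "N" && !arom[other]) {
      detail <- rbind(detail, data.frame(bond = i, kind = "amide",
                                         acyl = cc, het = other,
                                         stringsAsFactors = FALSE))
    } else if (include_esters && el[other] == "O" && !arom[other]) {
      # ester: the oxygen must carry a second carbon (alkoxy side)
      if (any(el[setdiff(nb[[other]], cc)] == "C")) {
        detail <- rbind(detail, data.frame(bond = i, kind = "ester",
                                           acyl = cc, het = other,
                                           stringsAsFactors = FALSE))
      }
    }
  }

  # small-fragment skip rule: cleaving must not produce a piece of <= 3
  # heavy atoms (a ring bond leaves the graph connected and always passes)
  keep <- vapply(detail$bond, function(i) {
    memb <- .component_membership(graph, i)
    sizes <- tabulate(memb)
    length(sizes[sizes > 0L]) == 1L || min(sizes[sizes > 0L]) > 3L
  }, logical(1))
  detail <- detail[keep, , drop = FALSE]
  rownames(detail) <- NULL

  prov <- rep("auto", nrow(detail))
  names(prov) <- as.character(detail$bond)
  structure(list(cleavable = detail$bond, provenance = prov, detail = detail),
            class = "bond_annotation")
}

#' Toggle the cleavability of a bond
#'
#' Flips a bond in or out of the cleavable set. Manual additions are not
#' pattern-checked: the user is authoritative. Toggling twice restores the
#' original annotation.
#'
#' @param annotation A `bond_annotation`.
#' @param graph The `mol_graph` the annotation belongs to.
#' @param bond Bond index (1-based, as in `graph$bonds`).
#' @return The updated `bond_annotation`.
#' @export
toggle_bond <- function(annotation, graph, bond) {
  stopifnot(inherits(annotation, "bond_annotation"),
            inherits(graph, "mol_graph"))
  if (!(is.numeric(bond) && length(bond) == 1L && bond == round(bond) &&
        bond >= 1L && bond <= nrow(graph$bonds))) {
    stop("unknown bond index: ", format(bond), call. = FALSE)
  }
  bond <- as.integer(bond)
  key <- as.character(bond)
  prov <- annotation$provenance
  if (bond %in% annotation$cleavable) {
    annotation$cleavable <- setdiff(annotation$cleavable, bond)
    if (identical(unname(prov[key]), "auto")) {
      prov[key] <- "manual-removed"
    } else {
      prov <- prov[names(prov) != key]
    }
  } else {
    annotation$cleavable <- sort(c(annotation$cleavable, bond))
    if (identical(unname(prov[key]), "manual-removed")) {
      prov[key] <- "auto"     # restoring an auto-detected bond
    } else {
      prov[key] <- "manual-added"
    }
  }
  annotation$provenance <- prov
  annotation
}

#' @export
print.bond_annotation <- function(x, ...) {
  cat("<bond_annotation> ", length(x$cleavable), " cleavable bond(s): ",
      paste(x$cleavable, collapse = ", "), "\n", sep = "")
  invisible(x)
}
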