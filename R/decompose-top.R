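#' Decompose a molecule into building blocks
#'
#' Full pipeline: parse the SMILES, perceive cleavable amide/ester bonds
#' (with optional manual toggles), split into fragments, cap them to free
#' monomers, deduplicate block structures by canonical stereo-free SMILES,
#' resolve block metadata against a local container and then an optional
#' compound finder, order occurrences from N- to C-terminus, classify the
#' topology and render the sequence notation.
#'
#' @param smiles Neutral, single-component SMILES string.
#' @param container Optional `msb_container` consulted first for known block
#'   structures.
#' @param finder Optional compound-finder backend (see [fixture_finder()])
#'   consulted for blocks missing from the container.
#' @param include_esters Perceive ester (depsipeptide) bonds (default `TRUE`).
#' @param toggle_bonds Integer bond indices to toggle manually after
#'   auto-annotation.
#' @return A `decomposition`: list with `blocks` (deduplicated
#'   `building_block`s), `sequence` (a `block_sequence`), `notation` string
#'   (`NA` for type `other`), `type`, `occurrences` (per-occurrence table
#'   with acronyms), `molecular_formula` and `monoisotopic_mass` of the
#'   parent, plus the underlying `graph`, `annotation` and `block_graph`.
#' @examples
#' d <- decompose("NCC(=O)NCC(=O)O")  # glycylglycine
#' d$notation
#' @export
decompose <- function(smiles, container = NULL, finder = NULL,
                      include_esters = TRUE, toggle_bonds = integer(0)) {
  graph <- parse_smiles(smiles)
  annotation <- find_cleavable_bonds(graph, include_esters = include_esters)
  for (b in toggle_bonds) annotation <- toggle_bond(annotation, graph, b)
  bg <- split_blocks(graph, annotation)
  type <- classify_structure(bg)

  occ <- bg$occurrences
  distinct <- occ[!duplicated(occ$smiles), , drop = FALSE]

  resolved <- lapply(distinct$smiles, resolve_block_metadata,
                     container = container, finder = finder)
  acronyms <- character(nrow(distinct))
  blocks <- vector("list", nrow(distinct))
  for (k in seq_len(nrow(distinct))) {
    r <- resolved[[k]]
    acr <- if (!is.na(r$acronym)) r$acronym else
      if (!is.na(r$name) && nzchar(r$name)) .acronym_from_name(r$name) else
        paste0("B", k)
    acr <- .uniquify_acronym(acr, acronyms[seq_len(k - 1L)])
    acronyms[k] <- acr
    blocks[[k]] <- building_block(
      acronym = acr,
      name = if (is.na(r$name)) "" else r$name,
      molecular_formula = distinct$molecular[k],
      block_smiles = distinct$smiles[k],
      n_termini = distinct$n_termini[k],
      c_termini = distinct$c_termini[k],
      losses = r$losses,
      reference = r$reference)
  }
  occ$acronym <- acronyms[match(occ$smiles, distinct$smiles)]

  ord <- order_blocks(bg, type)
  seq_obj <- if (is.null(ord$backbone)) {
    block_sequence(occ$acronym[match(ord$order, occ$occ)], type = type)
  } else {
    block_sequence(
      occ$acronym[match(ord$backbone, occ$occ)],
      branch = if (is.null(ord$branch)) NULL else
        occ$acronym[match(ord$branch, occ$occ)],
      branch_at = ord$branch_at,
      cyclic = ord$cyclic, type = type)
  }
  notation <- if (type == "other") NA_character_ else to_notation(seq_obj)

  parent_formula <- formula_of(graph)
  structure(list(
    smiles = smiles,
    blocks = blocks,
    sequence = seq_obj,
    notation = notation,
    type = type,
    occurrences = occ,
    order = ord,
    molecular_formula = formula_to_string(parent_formula),
    monoisotopic_mass = monoisotopic_mass(parent_formula),
    graph = graph,
    annotation = annotation,
    block_graph = bg
  ), class = "decomposition")
}

# "ornithine" -> "Orn", "N-acetyl-isoleucine" -> "Nac"
.acronym_from_name <- function(name) {
  base <- gsub("[^A-Za-z0-9]", "", trimws(name))
  base <- substr(base, 1L, 3L)
  if (!nzchar(base)) return("B")
  paste0(toupper(substr(base, 1, 1)), tolower(substr(base, 2, nchar(base))))
}

.uniquify_acronym <- function(acr, taken) {
  if (!(acr %in% taken)) return(acr)
  k <- 2L
  while (paste0(acr, k) %in% taken) k <- k + 1L
  paste0(acr, k)
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition> ", x$smiles, "\n", sep = "")
  cat("  parent: ", x$molecular_formula, "  ",
      sprintf("%.6f", x$monoisotopic_mass), " Da\n", sep = "")
  cat("  type: ", x$type, "   blocks: ", length(x$blocks),
      " distinct / ", nrow(x$occurrences), " occurrence(s)\n", sep = "")
  if (!is.na(x$notation)) cat("  sequence: ", x$notation, "\n", sep = "")
  for (b in x$blocks) {
    cat(sprintf("  [%s] %s  residue %s (%.6f Da)  %s\n", b$acronym,
                if (nzchar(b$name)) b$name else "-", b$residue_formula,
                b$residue_mass, b$block_smiles))
  }
  invisible(x)
}
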