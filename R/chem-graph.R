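#' @importFrom ChemmineOB convertFormat
NULL

# Single entry point to the OpenBabel conversions used by the package.
# ChemmineOB returns "" (possibly whitespace) when a conversion fails, and
# emits its own diagnostics on stderr; we turn that into a structured error.
.ob_convert <- function(from, to, source,
                        options = data.frame(names = character(0),
                                             args = character(0),
                                             stringsAsFactors = FALSE),
                        what = source) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, source,
                                                    options = options))
  if (is.null(out) || !nzchar(trimws(out))) {
    stop("cheminformatics toolkit could not convert input: '",
         substr(what, 1L, 200L), "'", call. = FALSE)
  }
  out
}

# First whitespace-delimited token of a SMILES output line (the rest is the
# molecule title that OpenBabel appends).
.first_token <- function(x) sub("[ \t\r\n].*$", "", trimws(x))

#' Parse a SMILES string into a molecular graph
#'
#' The molecule is parsed with explicit hydrogens, which are then folded into
#' per-atom hydrogen counts, so the graph holds heavy atoms only. Aromatic
#' rings are kekulized (bond orders are definite), and per-atom aromaticity is
#' recorded from the input notation so that bond perception can ignore ring
#' nitrogens. Heavy-atom indices follow the order of appearance in the input
#' string and are 1-based.
#'
#' @param smiles A syntactically valid, single-component SMILES string.
#' @return A `mol_graph`: list with `atoms` (data frame: `element`, `charge`,
#'   `nH`, `aromatic`), `bonds` (data frame: `a1`, `a2`, `order`), and the
#'   input `smiles`.
#' @examples
#' g <- parse_smiles("NCC(=O)O")  # glycine: 5 heavy atoms, 4 bonds
#' formula_of(g)
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) stop("empty SMILES string", call. = FALSE)
  mol <- .ob_convert("SMI", "MOL", smiles,
                     options = data.frame(names = "h", args = "",
                                          stringsAsFactors = FALSE))
  parsed <- .parse_molblock(mol)
  g <- .fold_hydrogens(parsed$atoms, parsed$bonds)

  if (nrow(g$atoms) == 0L) {
    stop("SMILES '", smiles, "' contains no heavy atoms", call. = FALSE)
  }
  if (.n_components(nrow(g$atoms), g$bonds) > 1L) {
    stop("multi-component SMILES rejected: '", smiles, "'", call. = FALSE)
  }

  arom <- .smiles_atom_aromaticity(smiles)
  if (length(arom) == nrow(g$atoms)) {
    g$atoms$aromatic <- arom
  } else {
    # defensive: toolkit/tokenizer disagreement on atom count
    g$atoms$aromatic <- FALSE
  }
  structure(list(atoms = g$atoms, bonds = g$bonds, smiles = smiles),
            class = "mol_graph")
}

# ---- molblock reading --------------------------------------------------

.parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || is.na(n_bonds)) {
    stop("malformed molblock counts line", call. = FALSE)
  }
  atom_lines <- lines[seq_len(n_atoms) + 4L]
  bond_lines <- if (n_bonds > 0L) lines[seq_len(n_bonds) + 4L + n_atoms] else character(0)

  element <- trimws(substr(atom_lines, 32, 34))
  charge_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge_code[is.na(charge_code)] <- 0L
  old_chg <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- ifelse(charge_code %in% names(old_chg) == FALSE, 0L,
                   old_chg[as.character(charge_code)])
  charge[is.na(charge)] <- 0L

  # "M  CHG" property lines override the atom-block charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0L) {
    charge <- rep(0L, n_atoms)
    for (ln in chg_lines) {
      nums <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      n <- nums[1]
      for (k in seq_len(n)) {
        charge[nums[2 * k]] <- nums[2 * k + 1L]
      }
    }
  }

  a1 <- as.integer(substr(bond_lines, 1, 3))
  a2 <- as.integer(substr(bond_lines, 4, 6))
  order <- as.integer(substr(bond_lines, 7, 9))
  list(atoms = data.frame(element = element, charge = as.integer(charge),
                          stringsAsFactors = FALSE),
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

# Fold explicit hydrogen atoms into per-heavy-atom counts; reindex heavy atoms
.fold_hydrogens <- function(atoms, bonds) {
  is_h <- atoms$element == "H"
  heavy_idx <- which(!is_h)
  new_index <- integer(nrow(atoms))
  new_index[heavy_idx] <- seq_along(heavy_idx)

  nH <- integer(length(heavy_idx))
  keep <- logical(nrow(bonds))
  if (nrow(bonds) > 0L) {
    for (i in seq_len(nrow(bonds))) {
      h1 <- is_h[bonds$a1[i]]; h2 <- is_h[bonds$a2[i]]
      if (h1 && h2) stop("hydrogen-hydrogen bond unsupported", call. = FALSE)
      if (h1 || h2) {
        heavy <- if (h1) bonds$a2[i] else bonds$a1[i]
        nH[new_index[heavy]] <- nH[new_index[heavy]] + 1L
      } else {
        keep[i] <- TRUE
      }
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  bonds$a1 <- new_index[bonds$a1]
  bonds$a2 <- new_index[bonds$a2]
  rownames(bonds) <- NULL
  atoms <- atoms[heavy_idx, , drop = FALSE]
  atoms$nH <- nH
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

.n_components <- function(n_atoms, bonds) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(bonds) > 0L) bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms)))
  igraph::components(g)$no
}

# ---- aromaticity from the notation -------------------------------------

# Per-heavy-atom aromatic flags, in order of appearance in the SMILES text.
# Bracket atoms that are explicit hydrogens are dropped (they are folded).
.smiles_atom_aromaticity <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  flags <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket in SMILES", call. = FALSE)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(inner, regexpr("[A-Za-z][a-z]?", inner))
      if (length(sym) == 1L) {
        first <- substr(sym, 1, 1)
        if (!(toupper(sym) == "H" && first == "H")) {
          flags <- c(flags, first %in% letters)
        }
      }
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "F", "I", "B")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        flags <- c(flags, FALSE)
        i <- i + 2L
      } else {
        flags <- c(flags, FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("c", "n", "o", "p", "s", "b")) {
      flags <- c(flags, TRUE)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  flags
}

# ---- molblock writing --------------------------------------------------

# Minimal V2000 writer for heavy-atom graphs. Hydrogens are left implicit:
# OpenBabel assigns them by standard valence on read, which is exactly the
# capping semantics needed for fragments (a nitrogen that lost a bond gains
# a hydrogen, an added hydroxyl oxygen gains one, and so on).
.write_molblock <- function(atoms, bonds) {
  header <- c("", " msblocks", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(atoms), nrow(bonds))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, atoms$element)
  bond_lines <- if (nrow(bonds) > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else character(0)
  chg <- which(atoms$charge != 0L)
  chg_lines <- character(0)
  while (length(chg) > 0L) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_len(min(8L, length(chg)))]
    chg_lines <- c(chg_lines,
                   paste0("M  CHG", sprintf("%3d", length(take)),
                          paste0(sprintf("%4d%4d", take, atoms$charge[take]),
                                 collapse = "")))
  }
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", ""),
        collapse = "\n")
}

# Canonical SMILES of a heavy-atom subgraph (implicit hydrogens by valence).
.graph_to_canonical_smiles <- function(atoms, bonds) {
  mol <- .write_molblock(atoms, bonds)
  .first_token(.ob_convert("MOL", "CAN", mol, what = "<fragment molblock>"))
}

# ---- user-facing graph operations --------------------------------------

#' Molecular formula of a graph
#'
#' Counts every heavy atom plus its attached hydrogens.
#'
#' @param graph A `mol_graph` from [parse_smiles()], or a SMILES string.
#' @return A `chem_formula`.
#' @examples
#' formula_of("NCCCCN")  # putrescine, C4H12N2
#' @export
formula_of <- function(graph) {
  if (is.character(graph)) graph <- parse_smiles(graph)
  stopifnot(inherits(graph, "mol_graph"))
  counts <- c(table(graph$atoms$element), H = sum(graph$atoms$nH))
  .new_formula(counts)
}

#' Canonical SMILES
#'
#' Deterministic canonical form: any two SMILES spellings of the same molecule
#' map to the same string, and the operation is idempotent.
#'
#' @param smiles A valid SMILES string.
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .first_token(.ob_convert("SMI", "CAN", smiles))
}

#' Remove stereochemical markup from a SMILES string
#'
#' Drops tetrahedral (`@`, `@@`) and double-bond (`/`, `\`) markers; the
#' heavy-atom graph, bond orders and molecular formula are unchanged. Mass
#' spectra carry no stereochemical information, so block identities are
#' compared on the stereo-free structure.
#'
#' @param smiles A valid SMILES string.
#' @return A stereo-free SMILES of the same molecule.
#' @export
strip_stereo <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  stripped <- gsub("@", "", gsub("[/\\\\]", "", smiles), fixed = TRUE)
  # rewrite through the toolkit to clean now-redundant bracket atoms
  out <- .first_token(.ob_convert("SMI", "SMI", stripped, what = smiles))
  if (grepl("[@/\\\\]", out)) {
    stop("stereo markers survived stripping of '", smiles, "'", call. = FALSE)
  }
  out
}

#' Canonical, stereo-free ("generic") SMILES
#'
#' The structure key used for building-block identity, deduplication and
#' Tanimoto set membership.
#'
#' @param smiles A valid SMILES string.
#' @return Canonical SMILES of the stereo-stripped molecule.
#' @export
generic_smiles <- function(smiles) {
  canonical_smiles(strip_stereo(smiles))
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n  ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, formula ", formula_to_string(formula_of(x)),
      "\n", sep = "")
  invisible(x)
}

# total formal charge of the parsed molecule
.total_charge <- function(graph) sum(graph$atoms$charge)
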