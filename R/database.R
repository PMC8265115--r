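#' @title Containers and CycloBranch database I/O
#'
#' @description A container is the unit of import/export: a named collection
#' of building blocks, sequence records and terminal modifications (plus
#' family and organism vocabularies). Stored monoisotopic masses are never
#' independent state: they are always recomputed from formulas, both on
#' construction and on import.
#' @name database
NULL

.CONTAINER_SCHEMA <- 1L

#' Create an empty container
#'
#' @param name Container name.
#' @param visibility `"private"` or `"public"`.
#' @return An `msb_container`.
#' @export
new_container <- function(name, visibility = c("private", "public")) {
  visibility <- match.arg(visibility)
  structure(list(name = name, blocks = list(), sequences = list(),
                 modifications = list(), families = character(0),
                 organisms = character(0), visibility = visibility),
            class = "msb_container")
}

#' Terminal modification
#'
#' A mass/formula delta applied at a chain end (e.g. acetylation, C2H2O,
#' +42.010565 Da) rather than stored inside a block.
#'
#' @param name Modification name or acronym.
#' @param formula Formula of the delta.
#' @param n_terminal `TRUE` for an N-terminal modification, `FALSE` for
#'   C-terminal.
#' @return A `terminal_modification`; its mass is computed from the formula.
#' @export
terminal_modification <- function(name, formula, n_terminal = TRUE) {
  f <- as_chem_formula(formula)
  structure(list(name = name, formula = formula_to_string(f),
                 monoisotopic_mass = monoisotopic_mass(f),
                 n_terminal = isTRUE(n_terminal)),
            class = "terminal_modification")
}

#' Sequence record
#'
#' @param name Compound name.
#' @param type One of [SEQUENCE_TYPES].
#' @param notation Sequence notation string (`NA` for type `other`).
#' @param molecular_formula Formula of the neutral molecule.
#' @param families,organisms Character vectors.
#' @param modifications Named list with optional entries `n`, `c`, `branch`:
#'   names of terminal modifications.
#' @param reference External reference string, e.g. `"CID: 602"`.
#' @param smiles Structure SMILES (optional; not carried by the CycloBranch
#'   text format).
#' @return A `sequence_record`; mass recomputed from the formula.
#' @export
sequence_record <- function(name, type, notation = NA_character_,
                            molecular_formula, families = character(0),
                            organisms = character(0),
                            modifications = list(), reference = NA_character_,
                            smiles = NA_character_) {
  stopifnot(type %in% SEQUENCE_TYPES)
  f <- as_chem_formula(molecular_formula)
  if (type != "other") {
    if (is.na(notation)) stop("notation required unless type is 'other'",
                              call. = FALSE)
    parse_notation(notation)   # must parse
  }
  mods <- list(n = NA_character_, c = NA_character_, branch = NA_character_)
  for (slot in intersect(names(modifications), names(mods))) {
    if (!is.null(modifications[[slot]]) && !is.na(modifications[[slot]]))
      mods[[slot]] <- modifications[[slot]]
  }
  structure(list(name = name, type = type, notation = notation,
                 molecular_formula = formula_to_string(f),
                 monoisotopic_mass = monoisotopic_mass(f),
                 families = as.character(families),
                 organisms = as.character(organisms),
                 modifications = mods, reference = reference,
                 smiles = smiles),
            class = "sequence_record")
}

# ---- membership --------------------------------------------------------

#' Add items to a container
#'
#' `container_add_block()` enforces acronym uniqueness;
#' `container_add_sequence()` checks that the notation references only
#' container acronyms and that the modification assignment is valid for the
#' sequence type.
#'
#' @param container An `msb_container`.
#' @param block,record,modification Items to add.
#' @return The updated container.
#' @export
container_add_block <- function(container, block) {
  stopifnot(inherits(container, "msb_container"),
            inherits(block, "building_block"))
  if (block$acronym %in% vapply(container$blocks, `[[`, character(1), "acronym")) {
    stop("duplicate block acronym in container: ", block$acronym,
         call. = FALSE)
  }
  container$blocks <- c(container$blocks, list(block))
  container
}

#' @rdname container_add_block
#' @export
container_add_modification <- function(container, modification) {
  stopifnot(inherits(modification, "terminal_modification"))
  container$modifications <- c(container$modifications, list(modification))
  container
}

#' @rdname container_add_block
#' @export
container_add_sequence <- function(container, record) {
  stopifnot(inherits(record, "sequence_record"))
  if (!is.na(record$notation)) {
    seq <- parse_notation(record$notation)
    known <- vapply(container$blocks, `[[`, character(1), "acronym")
    missing <- setdiff(c(seq$backbone, seq$branch), known)
    if (length(missing) > 0L) {
      stop("sequence references unknown block acronym(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  mods <- .resolve_mods(record, container)
  viol <- validate_modifications(record$type, mods)
  if (length(viol) > 0L) {
    stop("invalid modification assignment: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  container$families <- union(container$families, record$families)
  container$organisms <- union(container$organisms, record$organisms)
  container$sequences <- c(container$sequences, list(record))
  container
}

.resolve_mods <- function(record, container) {
  names_used <- unlist(record$modifications, use.names = FALSE)
  names_used <- names_used[!is.na(names_used)]
  defs <- container$modifications
  def_names <- vapply(defs, `[[`, character(1), "name")
  out <- list()
  for (nm in names_used) {
    i <- match(nm, def_names)
    if (is.na(i)) stop("unknown terminal modification: ", nm, call. = FALSE)
    out <- c(out, list(defs[[i]]))
  }
  out
}

#' Find a block by acronym or structure
#'
#' @param container An `msb_container`.
#' @param acronym Block acronym.
#' @param smiles Canonical stereo-free SMILES (compare with
#'   [generic_smiles()]).
#' @return The `building_block`, or `NULL`.
#' @export
container_find_block <- function(container, acronym) {
  for (b in container$blocks) if (identical(b$acronym, acronym)) return(b)
  NULL
}

#' @rdname container_find_block
#' @export
container_find_block_by_smiles <- function(container, smiles) {
  for (b in container$blocks) {
    if (!is.na(b$block_smiles) && identical(b$block_smiles, smiles)) return(b)
  }
  NULL
}

# ---- modification validity rules ---------------------------------------

#' Validate a terminal-modification assignment
#'
#' Linear sequences may carry one N-terminal and one C-terminal
#' modification; cyclic ones none at all (a ring has no ends); branched and
#' branch-cyclic sequences a single branch modification of either polarity;
#' a linear polyketide up to two modifications, same-polarity pairs allowed
#' (its two ends can both be N-type).
#'
#' @param type One of [SEQUENCE_TYPES].
#' @param mods List of `terminal_modification` objects assigned to the
#'   sequence.
#' @return Character vector of violations; empty when the assignment is
#'   valid.
#' @export
validate_modifications <- function(type, mods) {
  stopifnot(type %in% SEQUENCE_TYPES)
  stopifnot(all(vapply(mods, inherits, logical(1), "terminal_modification")))
  n_mods <- length(mods)
  n_n <- sum(vapply(mods, `[[`, logical(1), "n_terminal"))
  n_c <- n_mods - n_n
  v <- character(0)
  if (type %in% c("cyclic", "cyclic-polyketide", "other")) {
    if (n_mods > 0L)
      v <- c(v, paste0(type, " sequences admit no terminal modifications"))
  } else if (type == "linear") {
    if (n_n > 1L) v <- c(v, "more than one N-terminal modification")
    if (n_c > 1L) v <- c(v, "more than one C-terminal modification")
  } else if (type %in% c("branched", "branch-cyclic")) {
    if (n_mods > 1L)
      v <- c(v, paste0(type, " sequences admit a single branch modification"))
  } else if (type == "linear-polyketide") {
    if (n_mods > 2L)
      v <- c(v, "a linear polyketide admits at most two modifications")
  }
  v
}

# ---- CycloBranch tab-separated export/import ---------------------------

.fmt_mass <- function(x) sprintf("%.6f", x)
.na_empty <- function(x) ifelse(is.na(x) | is.null(x), "", x)

#' Export a container to CycloBranch-style text payloads
#'
#' One row per item, tab-separated values, Unix newlines. Blocks carry name,
#' acronym, residue formula (Hill order), residue monoisotopic mass, neutral
#' losses (semicolon-joined) and references; sequences carry type, name,
#' molecular formula, mass, notation and the three modification names plus a
#' reference; modifications carry name, formula, mass and an `N`/`C` flag.
#'
#' @param container An `msb_container` passing its invariants.
#' @return List of three strings: `blocks`, `sequences`, `modifications`.
#' @export
export_cyclobranch <- function(container) {
  stopifnot(inherits(container, "msb_container"))
  acrs <- vapply(container$blocks, `[[`, character(1), "acronym")
  if (anyDuplicated(acrs)) {
    stop("container invariant violated: duplicate block acronyms",
         call. = FALSE)
  }
  for (rec in container$sequences) {
    if (!is.na(rec$notation)) {
      seq <- parse_notation(rec$notation)
      missing <- setdiff(c(seq$backbone, seq$branch), acrs)
      if (length(missing) > 0L) {
        stop("container invariant violated: sequence '", rec$name,
             "' references unknown acronym(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }

  block_rows <- vapply(container$blocks, function(b) {
    paste(c(b$name, b$acronym, b$residue_formula, .fmt_mass(b$residue_mass),
            paste(b$losses, collapse = ";"), .na_empty(b$reference)),
          collapse = "\t")
  }, character(1))
  seq_rows <- vapply(container$sequences, function(s) {
    paste(c(s$type, s$name, s$molecular_formula,
            .fmt_mass(s$monoisotopic_mass), .na_empty(s$notation),
            .na_empty(s$modifications$n), .na_empty(s$modifications$c),
            .na_empty(s$modifications$branch), .na_empty(s$reference)),
          collapse = "\t")
  }, character(1))
  mod_rows <- vapply(container$modifications, function(m) {
    paste(c(m$name, m$formula, .fmt_mass(m$monoisotopic_mass),
            if (m$n_terminal) "N" else "C"), collapse = "\t")
  }, character(1))

  join <- function(rows) if (length(rows) == 0L) "" else
    paste0(paste(rows, collapse = "\n"), "\n")
  list(blocks = join(block_rows), sequences = join(seq_rows),
       modifications = join(mod_rows))
}

#' Import a container from CycloBranch-style text payloads
#'
#' Masses are recomputed from the formulas; a stored mass deviating by more
#' than 1e-4 Da triggers a warning and the formula-derived value wins.
#'
#' @param blocks,sequences,modifications Payload strings (as produced by
#'   [export_cyclobranch()]); empty strings are allowed.
#' @param name Name for the reconstructed container.
#' @return An `msb_container`.
#' @export
import_cyclobranch <- function(blocks = "", sequences = "",
                               modifications = "", name = "imported") {
  cont <- new_container(name)
  split_rows <- function(payload) {
    if (is.null(payload) || !nzchar(payload)) return(character(0))
    strsplit(sub("\n$", "", payload), "\n", fixed = TRUE)[[1]]
  }
  fields <- function(row, n_expected, what, line) {
    n_found <- lengths(regmatches(row, gregexpr("\t", row, fixed = TRUE))) + 1L
    if (n_found != n_expected) {
      stop("malformed ", what, " row at line ", line, ": expected ",
           n_expected, " tab-separated fields, found ", n_found,
           call. = FALSE)
    }
    f <- strsplit(row, "\t", fixed = TRUE)[[1]]
    length(f) <- n_expected                   # trailing empties
    f[is.na(f)] <- ""
    f
  }
  check_mass <- function(formula, stored, what, line) {
    recomputed <- monoisotopic_mass(formula)
    stored_num <- suppressWarnings(as.numeric(stored))
    if (!is.na(stored_num) && abs(stored_num - recomputed) > 1e-4) {
      warning(what, " at line ", line, ": stored mass ", stored,
              " deviates from formula-derived ", .fmt_mass(recomputed),
              "; the formula wins", call. = FALSE)
    }
    recomputed
  }

  rows <- split_rows(modifications)
  for (i in seq_along(rows)) {
    f <- fields(rows[i], 4L, "modification", i)
    check_mass(f[2], f[3], "modification", i)
    cont <- container_add_modification(
      cont, terminal_modification(f[1], f[2], n_terminal = f[4] == "N"))
  }

  rows <- split_rows(blocks)
  for (i in seq_along(rows)) {
    f <- fields(rows[i], 6L, "block", i)
    res <- parse_formula(f[3])
    check_mass(res, f[4], "block", i)
    # stored residue formula -> molecular formula by the terminus convention;
    # the text format does not carry terminus counts, NRP blocks are assumed
    blk <- building_block(
      acronym = f[2], name = f[1],
      molecular_formula = formula_add(res, "H2O"),
      block_smiles = NA_character_,
      n_termini = 1L, c_termini = 1L,
      losses = if (nzchar(f[5])) strsplit(f[5], ";", fixed = TRUE)[[1]]
               else character(0),
      reference = if (nzchar(f[6])) f[6] else NA_character_)
    cont <- container_add_block(cont, blk)
  }

  rows <- split_rows(sequences)
  for (i in seq_along(rows)) {
    f <- fields(rows[i], 9L, "sequence", i)
    if (!f[1] %in% SEQUENCE_TYPES) {
      stop("unknown sequence type '", f[1], "' at line ", i, call. = FALSE)
    }
    check_mass(f[3], f[4], "sequence", i)
    rec <- sequence_record(
      name = f[2], type = f[1],
      notation = if (nzchar(f[5])) f[5] else NA_character_,
      molecular_formula = f[3],
      modifications = list(n = if (nzchar(f[6])) f[6] else NA,
                           c = if (nzchar(f[7])) f[7] else NA,
                           branch = if (nzchar(f[8])) f[8] else NA),
      reference = if (nzchar(f[9])) f[9] else NA_character_)
    cont <- container_add_sequence(cont, rec)
  }
  cont
}

#' Write/read CycloBranch payloads as files
#'
#' @param container An `msb_container`.
#' @param outdir Output directory (created if missing); files
#'   `blocks.tsv`, `sequences.tsv`, `modifications.tsv`.
#' @return Invisibly, the paths written.
#' @export
export_cyclobranch_files <- function(container, outdir) {
  payloads <- export_cyclobranch(container)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- file.path(outdir, c("blocks.tsv", "sequences.tsv",
                               "modifications.tsv"))
  writeLines(sub("\n$", "", payloads$blocks), paths[1], useBytes = TRUE)
  writeLines(sub("\n$", "", payloads$sequences), paths[2], useBytes = TRUE)
  writeLines(sub("\n$", "", payloads$modifications), paths[3], useBytes = TRUE)
  invisible(paths)
}

#' @rdname export_cyclobranch_files
#' @param blocks_file,sequences_file,modifications_file Paths to payload
#'   files.
#' @param name Container name.
#' @export
import_cyclobranch_files <- function(blocks_file, sequences_file,
                                     modifications_file, name = "imported") {
  read_payload <- function(p) {
    if (is.null(p) || !file.exists(p)) return("")
    txt <- paste(readLines(p, warn = FALSE), collapse = "\n")
    if (nzchar(txt)) paste0(txt, "\n") else ""
  }
  import_cyclobranch(read_payload(blocks_file), read_payload(sequences_file),
                     read_payload(modifications_file), name = name)
}

# ---- JSON persistence --------------------------------------------------

#' Save/load a container as JSON
#'
#' Lossless, deterministic serialization of every container field (the
#' stand-in for a relational store). Masses are recomputed on load.
#'
#' @param container An `msb_container`.
#' @param path File path.
#' @return `container_save()` returns the path invisibly; `container_load()`
#'   returns the container.
#' @export
container_save <- function(container, path) {
  stopifnot(inherits(container, "msb_container"))
  payload <- list(
    schema_version = .CONTAINER_SCHEMA,
    name = container$name,
    visibility = container$visibility,
    families = as.list(container$families),
    organisms = as.list(container$organisms),
    blocks = lapply(container$blocks, function(b) b[c(
      "acronym", "name", "molecular_formula", "residue_formula",
      "residue_mass", "block_smiles", "n_termini", "c_termini", "losses",
      "reference")]),
    sequences = lapply(container$sequences, function(s) s[c(
      "name", "type", "notation", "molecular_formula", "monoisotopic_mass",
      "families", "organisms", "modifications", "reference", "smiles")]),
    modifications = lapply(container$modifications, function(m) m[c(
      "name", "formula", "monoisotopic_mass", "n_terminal")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname container_save
#' @export
container_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$schema_version) || j$schema_version != .CONTAINER_SCHEMA) {
    stop("container schema version mismatch: found ",
         if (is.null(j$schema_version)) "none" else j$schema_version,
         ", expected ", .CONTAINER_SCHEMA, call. = FALSE)
  }
  cont <- new_container(j$name, visibility = j$visibility)
  cont$families <- as.character(unlist(j$families))
  cont$organisms <- as.character(unlist(j$organisms))
  for (m in j$modifications) {
    cont <- container_add_modification(
      cont, terminal_modification(m$name, m$formula,
                                  n_terminal = isTRUE(m$n_terminal)))
  }
  for (b in j$blocks) {
    cont <- container_add_block(cont, building_block(
      acronym = b$acronym, name = b$name,
      molecular_formula = b$molecular_formula,
      block_smiles = if (is.null(b$block_smiles)) NA_character_ else b$block_smiles,
      n_termini = b$n_termini, c_termini = b$c_termini,
      losses = as.character(unlist(b$losses)),
      reference = if (is.null(b$reference)) NA_character_ else b$reference))
  }
  for (s in j$sequences) {
    cont <- container_add_sequence(cont, sequence_record(
      name = s$name, type = s$type,
      notation = if (is.null(s$notation)) NA_character_ else s$notation,
      molecular_formula = s$molecular_formula,
      families = as.character(unlist(s$families)),
      organisms = as.character(unlist(s$organisms)),
      modifications = lapply(s$modifications, function(x)
        if (is.null(x)) NA_character_ else x),
      reference = if (is.null(s$reference)) NA_character_ else s$reference,
      smiles = if (is.null(s$smiles)) NA_character_ else s$smiles))
  }
  cont
}

#' @export
print.msb_container <- function(x, ...) {
  cat("<msb_container> '", x$name, "' (", x$visibility, "): ",
      length(x$blocks), " block(s), ", length(x$sequences), " sequence(s), ",
      length(x$modifications), " modification(s)\n", sep = "")
  invisible(x)
}
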