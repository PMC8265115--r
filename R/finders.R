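#' @title Compound finders
#'
#' @description A finder backend answers single-facet compound queries (by
#' name, formula, mass with tolerance, identifier, or structure). The fixture
#' backend is an offline, pure lookup over a JSON (or in-memory) table and is
#' the reference implementation of the interface; live REST backends for
#' public repositories can be added as new classes implementing
#' [find_compounds()] without touching the core.
#' @name finders
NULL

#' Create an offline fixture finder
#'
#' @param source Path to a JSON file holding a list of compound records
#'   (fields `name`, `smiles`, `formula`, `mass`, `database`, `id`; missing
#'   `formula`/`mass` are derived from the SMILES), or a data frame with the
#'   same columns.
#' @return A `fixture_finder`.
#' @export
fixture_finder <- function(source) {
  if (is.character(source)) {
    stopifnot(file.exists(source))
    recs <- jsonlite::read_json(source, simplifyVector = FALSE)
    source <- do.call(rbind, lapply(recs, function(r) {
      data.frame(name = r$name %||% NA_character_,
                 smiles = r$smiles %||% NA_character_,
                 formula = r$formula %||% NA_character_,
                 mass = r$mass %||% NA_real_,
                 database = r$database %||% NA_character_,
                 id = as.character(r$id %||% NA_character_),
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(source))
  needed <- c("name", "smiles", "formula", "mass", "database", "id")
  for (col in setdiff(needed, names(source))) source[[col]] <- NA
  src <- source[, needed, drop = FALSE]
  if (any(is.na(src$name) & is.na(src$smiles))) {
    stop("every finder record needs a name or a SMILES", call. = FALSE)
  }
  # derive canonical keys and missing formula/mass once, up front
  src$generic <- NA_character_
  for (i in seq_len(nrow(src))) {
    if (!is.na(src$smiles[i])) {
      src$generic[i] <- generic_smiles(src$smiles[i])
      f <- formula_of(src$smiles[i])
      if (is.na(src$formula[i])) src$formula[i] <- formula_to_string(f)
      if (is.na(src$mass[i])) src$mass[i] <- monoisotopic_mass(f)
    } else if (!is.na(src$formula[i]) && is.na(src$mass[i])) {
      src$mass[i] <- monoisotopic_mass(src$formula[i])
    }
  }
  structure(list(table = src), class = "fixture_finder")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Query a finder backend
#'
#' Exactly one query facet must be supplied. The fixture backend matches by
#' case-insensitive name, Hill formula string, monoisotopic mass within
#' `tolerance`, `"DB: id"` identifier, or canonical stereo-free structure.
#'
#' @param backend A finder backend.
#' @param name,formula,mass,identifier,smiles Query facets.
#' @param tolerance Mass half-window in Da (only with `mass`).
#' @return Data frame of hits with columns `name`, `smiles`, `formula`,
#'   `mass`, `database`, `id` (zero rows when nothing matches).
#' @export
find_compounds <- function(backend, name = NULL, formula = NULL, mass = NULL,
                           identifier = NULL, smiles = NULL,
                           tolerance = 0.01) {
  UseMethod("find_compounds")
}

#' @export
find_compounds.fixture_finder <- function(backend, name = NULL,
                                          formula = NULL, mass = NULL,
                                          identifier = NULL, smiles = NULL,
                                          tolerance = 0.01) {
  facets <- list(name = name, formula = formula, mass = mass,
                 identifier = identifier, smiles = smiles)
  set <- !vapply(facets, is.null, logical(1))
  if (sum(set) != 1L) {
    stop("exactly one query facet must be set (got ", sum(set), ")",
         call. = FALSE)
  }
  tab <- backend$table
  hit <- switch(names(facets)[set],
    name = !is.na(tab$name) & tolower(tab$name) == tolower(name),
    formula = !is.na(tab$formula) &
      tab$formula == formula_to_string(as_chem_formula(formula)),
    mass = !is.na(tab$mass) & abs(tab$mass - mass) <= tolerance,
    identifier = {
      ref <- paste0(tab$database, ": ", tab$id)
      !is.na(tab$database) & tolower(ref) == tolower(identifier)
    },
    smiles = !is.na(tab$generic) & tab$generic == generic_smiles(smiles))
  out <- tab[hit, c("name", "smiles", "formula", "mass", "database", "id"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve building-block metadata
#'
#' The block structure is looked up in the local container first (by
#' canonical stereo-free SMILES); only unmatched structures are sent to the
#' finder backend. Backend failures degrade to the no-match path with a
#' warning. With no match anywhere, the caller synthesizes an acronym.
#'
#' @param block_smiles Canonical stereo-free SMILES of the block.
#' @param container Optional `msb_container` searched first.
#' @param finder Optional finder backend.
#' @return List with `acronym`, `name`, `reference` (each possibly `NA`),
#'   `losses`, and `source` (`"local"`, `"finder"` or `"none"`).
#' @export
resolve_block_metadata <- function(block_smiles, container = NULL,
                                   finder = NULL) {
  if (!is.null(container)) {
    local <- container_find_block_by_smiles(container, block_smiles)
    if (!is.null(local)) {
      return(list(acronym = local$acronym, name = local$name,
                  reference = local$reference, losses = local$losses,
                  source = "local"))
    }
  }
  if (!is.null(finder)) {
    hits <- tryCatch(find_compounds(finder, smiles = block_smiles),
                     error = function(e) {
                       warning("finder backend failed: ", conditionMessage(e),
                               call. = FALSE)
                       NULL
                     })
    if (!is.null(hits) && nrow(hits) > 0L) {
      h <- hits[1L, ]
      ref <- if (!is.na(h$database)) paste0(h$database, ": ", h$id) else
        NA_character_
      return(list(acronym = NA_character_, name = h$name, reference = ref,
                  losses = character(0), source = "finder"))
    }
  }
  list(acronym = NA_character_, name = NA_character_,
       reference = NA_character_, losses = character(0), source = "none")
}
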