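#' Tanimoto similarity of two block sets
#'
#' `T(A, B) = |A intersect B| / (|A| + |B| - |A intersect B|)` over the sets
#' of building blocks of two structures. Block identity is structural
#' (canonical stereo-free SMILES), not the acronym string. Two empty sets
#' have similarity 0 by convention.
#'
#' @param blocks_a,blocks_b Character vectors of block identities (treated as
#'   sets; duplicates are ignored).
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c("a", "b", "c"), c("a", "b", "d"))  # 2/4
#' @export
tanimoto <- function(blocks_a, blocks_b) {
  a <- unique(blocks_a); b <- unique(blocks_b)
  if (length(a) == 0L && length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

# block-identity set and total block count of a stored sequence record,
# resolved through the container's block table; NULL when unresolvable
.sequence_block_set <- function(record, container) {
  if (is.na(record$notation) || !nzchar(record$notation)) return(NULL)
  seq <- tryCatch(parse_notation(record$notation), error = function(e) NULL)
  if (is.null(seq)) return(NULL)
  acronyms <- c(seq$backbone, seq$branch)
  keys <- vapply(acronyms, function(a) {
    blk <- container_find_block(container, a)
    if (is.null(blk) || is.na(blk$block_smiles)) NA_character_ else
      blk$block_smiles
  }, character(1))
  if (anyNA(keys)) return(NULL)
  list(set = unique(keys), total = length(acronyms))
}

#' Recommend families by Tanimoto similarity over block sets
#'
#' Scores the query against every stored sequence; the most similar sequence
#' wins, ties broken toward the sequence with the closest total block count
#' (repeats included), remaining ties toward the earliest stored sequence.
#' All families of the winner are recommended. A maximum similarity of 0, or
#' an empty container, yields no recommendation.
#'
#' @param query A `decomposition`, or a list with `set` (block identities)
#'   and `total` (occurrence count).
#' @param container An `msb_container` holding sequences with families.
#' @return List with `families` (character), `sequence_name` of the matched
#'   record (or `NA`) and `score`.
#' @export
recommend_families_tanimoto <- function(query, container) {
  if (inherits(query, "decomposition")) {
    query <- list(
      set = unique(vapply(query$blocks, `[[`, character(1), "block_smiles")),
      total = nrow(query$occurrences))
  }
  stopifnot(is.list(query), !is.null(query$set), !is.null(query$total))
  empty <- list(families = character(0), sequence_name = NA_character_,
                score = 0)
  if (length(container$sequences) == 0L) return(empty)

  best <- NULL; best_score <- 0; best_diff <- Inf
  for (rec in container$sequences) {
    sb <- .sequence_block_set(rec, container)
    if (is.null(sb)) next
    score <- tanimoto(query$set, sb$set)
    diff <- abs(query$total - sb$total)
    if (score > best_score ||
        (score == best_score && score > 0 && diff < best_diff)) {
      best <- rec; best_score <- score; best_diff <- diff
    }
  }
  if (is.null(best) || best_score <= 0) return(empty)
  list(families = unique(best$families), sequence_name = best$name,
       score = best_score)
}

#' Recommend families by compound-name substring search
#'
#' The search substring is the query name with its final whitespace-delimited
#' token removed (so "pseudacyclin B" searches for "pseudacyclin"); a
#' single-token name is used whole. Matching is case-insensitive substring
#' containment against stored sequence names; families of every matched
#' sequence are returned.
#'
#' @param query_name Name of the new compound.
#' @param container An `msb_container`.
#' @return List with `families`, `matched` (names of matching sequences) and
#'   the `substring` used.
#' @export
recommend_families_text <- function(query_name, container) {
  stopifnot(is.character(query_name), nzchar(query_name))
  tokens <- strsplit(trimws(query_name), "\\s+")[[1]]
  s <- if (length(tokens) >= 2L)
    paste(tokens[-length(tokens)], collapse = " ") else tokens
  fams <- character(0); matched <- character(0)
  for (rec in container$sequences) {
    if (grepl(tolower(s), tolower(rec$name), fixed = TRUE)) {
      matched <- c(matched, rec$name)
      fams <- c(fams, rec$families)
    }
  }
  list(families = unique(fams), matched = matched, substring = s)
}
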