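#' Block sequence
#'
#' Ordered building-block acronyms plus topology, in the representation used
#' by the CycloBranch sequence notation. The backbone carries every chain or
#' ring block including the branching block; `branch` holds only the pendant
#' blocks, ordered outward from the attachment point.
#'
#' @param backbone Character vector of acronyms, N- to C-terminal (one
#'   rotation for cyclic types).
#' @param branch Character vector of pendant-branch acronyms, or `NULL`.
#' @param branch_at Position (1-based) of the branching block in `backbone`.
#' @param cyclic Is the backbone a ring (last block bonded to the first)?
#' @param type One of [SEQUENCE_TYPES].
#' @return A `block_sequence`.
#' @export
block_sequence <- function(backbone, branch = NULL, branch_at = NA_integer_,
                           cyclic = FALSE, type = "linear") {
  stopifnot(type %in% SEQUENCE_TYPES)
  if (!is.null(branch) &&
      !type %in% c("branched", "branch-cyclic", "other")) {
    stop("a branch requires a branched, branch-cyclic or other type",
         call. = FALSE)
  }
  if (!is.null(branch) && !(branch_at >= 1L && branch_at <= length(backbone))) {
    stop("branch_at must index a backbone position", call. = FALSE)
  }
  structure(list(backbone = as.character(backbone),
                 branch = if (is.null(branch)) NULL else as.character(branch),
                 branch_at = as.integer(branch_at),
                 cyclic = isTRUE(cyclic), type = type),
            class = "block_sequence")
}

.check_acronyms <- function(acronyms) {
  bad <- grepl("[][()\\\\-]", acronyms)
  if (any(bad)) {
    stop("illegal characters in acronym(s): ",
         paste(acronyms[bad], collapse = ", "), call. = FALSE)
  }
}

#' Render CycloBranch sequence notation
#'
#' Linear and cyclic sequences render as `[A]-[B]-[C]`; for cyclic types the
#' last block is implicitly bonded to the first. Branched and branch-cyclic
#' sequences wrap the branching block and its pendant chain in an escaped
#' parenthesis group: `[A]\\([B]-[C]\\)[D]-[E]`, where B is the branching
#' block and C the last block of the branch.
#'
#' @param seq A `block_sequence`.
#' @return Notation string.
#' @examples
#' to_notation(block_sequence(c("A", "B", "C", "D", "E")))
#' @export
to_notation <- function(seq) {
  stopifnot(inherits(seq, "block_sequence"))
  if (seq$type == "other") {
    stop("sequences of type 'other' have no notation", call. = FALSE)
  }
  .check_acronyms(c(seq$backbone, seq$branch))
  wrap <- function(a) paste0("[", a, "]")
  if (is.null(seq$branch)) {
    return(paste(wrap(seq$backbone), collapse = "-"))
  }
  at <- seq$branch_at
  before <- seq$backbone[seq_len(at - 1L)]
  after <- if (at < length(seq$backbone))
    seq$backbone[(at + 1L):length(seq$backbone)] else character(0)
  group <- paste(wrap(c(seq$backbone[at], seq$branch)), collapse = "-")
  paste0(if (length(before)) paste(wrap(before), collapse = "-") else "",
         "\\(", group, "\\)",
         if (length(after)) paste(wrap(after), collapse = "-") else "")
}

#' Parse CycloBranch sequence notation
#'
#' Inverse of [to_notation()] up to the cyclic flag and exact type, which the
#' notation does not carry: the result is typed `branched` when a branch
#' group is present and `linear` otherwise; callers holding the stored type
#' (e.g. the database importer) restore it afterwards.
#'
#' @param text Notation string.
#' @return A `block_sequence` skeleton.
#' @examples
#' parse_notation("[A]\\([B]-[C]\\)[D]-[E]")
#' @export
parse_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  backbone <- character(0); branch <- character(0)
  branch_at <- NA_integer_
  in_group <- FALSE; group_done <- FALSE; group_pos <- 0L
  expect_item <- TRUE
  i <- 1L
  fail <- function(msg, pos) {
    stop("notation parse error at position ", pos, ": ", msg, call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      if (!expect_item) fail("unexpected '['", i)
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed '['", i)
      acr <- if (j - i > 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "")
        else ""
      if (!nzchar(acr)) fail("empty acronym", i)
      if (in_group) {
        group_pos <- group_pos + 1L
        if (group_pos == 1L) {
          backbone <- c(backbone, acr)       # branching block stays on backbone
          branch_at <- length(backbone)
        } else {
          branch <- c(branch, acr)
        }
      } else {
        backbone <- c(backbone, acr)
      }
      expect_item <- FALSE
      i <- j + 1L
    } else if (ch == "-") {
      if (expect_item) fail("unexpected '-'", i)
      expect_item <- TRUE
      i <- i + 1L
    } else if (ch == "\\") {
      if (i == n) fail("dangling escape", i)
      nxt <- chars[i + 1L]
      if (nxt == "(") {
        if (in_group || group_done) fail("nested or repeated branch group", i)
        in_group <- TRUE; group_pos <- 0L
        expect_item <- TRUE
        i <- i + 2L
      } else if (nxt == ")") {
        if (!in_group) fail("unmatched '\\)'", i)
        if (group_pos < 2L) fail("branch group needs a branching block and a branch", i)
        in_group <- FALSE; group_done <- TRUE
        expect_item <- TRUE
        i <- i + 2L
      } else {
        fail(paste0("unknown escape '\\", nxt, "'"), i)
      }
    } else {
      fail(paste0("unexpected character '", ch, "'"), i)
    }
  }
  if (in_group) fail("unclosed branch group", n)
  if (length(backbone) == 0L) fail("no blocks", 1L)
  block_sequence(backbone,
                 branch = if (group_done) branch else NULL,
                 branch_at = branch_at,
                 cyclic = FALSE,
                 type = if (group_done) "branched" else "linear")
}

#' @export
print.block_sequence <- function(x, ...) {
  txt <- if (x$type == "other") "<no notation for type 'other'>" else
    to_notation(x)
  cat("<block_sequence> ", txt, if (x$cyclic) " (cyclic)" else "",
      "  type: ", x$type, "\n", sep = "")
  invisible(x)
}

#' Total number of block occurrences in a sequence
#'
#' @param seq A `block_sequence`.
#' @return Integer count (backbone plus branch).
#' @export
sequence_length <- function(seq) {
  length(seq$backbone) + length(seq$branch)
}
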