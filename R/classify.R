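#' Structure types
#'
#' The seven structure types a decomposed molecule can take. Polyketide types
#' are triggered solely by the presence of a building block without a
#' C-terminus (a block flanked by amine groups, e.g. Hpd or Put); a branched
#' polyketide has no dedicated type and falls back to `other`, as do multiply
#' branched structures.
#'
#' @export
SEQUENCE_TYPES <- c("linear", "cyclic", "branched", "branch-cyclic",
                    "linear-polyketide", "cyclic-polyketide", "other")

# occurrence-level igraph (undirected) of a block_graph
.block_igraph <- function(block_graph, directed = FALSE) {
  igraph::graph_from_data_frame(
    d = block_graph$edges[, c("from", "to"), drop = FALSE],
    directed = directed,
    vertices = data.frame(name = block_graph$occurrences$occ))
}

#' Classify the topology of a decomposed molecule
#'
#' Starting from a linear assumption: a cycle in the block graph makes the
#' structure cyclic, a block with more than two neighbors makes it branched,
#' both together branch-cyclic. More than one branching point (or a double
#' branch at one block) is `other`. Any block lacking a C-terminus marks the
#' molecule as a polyketide, refined to linear or cyclic; a branched
#' polyketide is `other`.
#'
#' @param block_graph A `block_graph` from [split_blocks()].
#' @return One of [SEQUENCE_TYPES].
#' @examples
#' d <- decompose("NCC(=O)NCC(=O)NCC(=O)O")  # triglycine
#' d$type
#' @export
classify_structure <- function(block_graph) {
  stopifnot(inherits(block_graph, "block_graph"))
  g <- .block_igraph(block_graph)
  if (igraph::components(g)$no != 1L) {
    stop("block graph is disconnected", call. = FALSE)
  }
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)

  cyclic <- m >= n
  excess <- pmax(deg - 2L, 0L)
  branched <- any(excess > 0L)
  multi_branched <- sum(excess) >= 2L
  polyketide <- any(block_graph$occurrences$c_termini == 0L)

  if (multi_branched) return("other")
  if (polyketide && branched) return("other")
  if (polyketide) return(if (cyclic) "cyclic-polyketide" else "linear-polyketide")
  if (cyclic && branched) return("branch-cyclic")
  if (cyclic) return("cyclic")
  if (branched) return("branched")
  "linear"
}

# ---- ordering ----------------------------------------------------------

# score an occurrence ordering: number of consecutive pairs (u, v) realized
# by a directed acyl->amine linkage u -> v (N-to-C flow)
.direction_score <- function(block_graph, path, wrap = FALSE) {
  e <- block_graph$edges
  pairs <- cbind(path[-length(path)], path[-1])
  if (wrap && length(path) > 1L) pairs <- rbind(pairs, c(path[length(path)], path[1]))
  sum(apply(pairs, 1L, function(p) any(e$from == p[1] & e$to == p[2])))
}

.first_atom <- function(block_graph, occ) {
  block_graph$occurrences$first_atom[match(occ, block_graph$occurrences$occ)]
}

# orient a path N-terminus first: prefer the direction realizing more
# acyl->amine linkages, break ties toward the end with the lowest original
# atom index (the deterministic convention for two-N-termini chains)
.orient_path <- function(block_graph, path) {
  if (length(path) < 2L) return(path)
  fwd <- .direction_score(block_graph, path)
  bwd <- .direction_score(block_graph, rev(path))
  if (bwd > fwd) return(rev(path))
  if (fwd > bwd) return(path)
  if (.first_atom(block_graph, path[1]) <=
      .first_atom(block_graph, path[length(path)])) path else rev(path)
}

#' Order block occurrences from N-terminus to C-terminus
#'
#' Linear chains are emitted from the N-terminal end (ties between two
#' N-type ends resolved toward the occurrence with the lowest original atom
#' index). Cyclic cores are emitted as a single rotation following the
#' acyl-to-amine direction, rotated so that a branching block comes last.
#' Pendant branches are emitted from the attachment point outward.
#'
#' @param block_graph A `block_graph`.
#' @param type Optional pre-computed structure type (recomputed otherwise).
#' @return List with `backbone` (occurrence ids in order), `branch`
#'   (occurrence ids of the pendant chain, outward, or `NULL`), `branch_at`
#'   (position of the branching block in `backbone`, or `NA`), `cyclic`, and
#'   `order` (all occurrences, backbone then branch).
#' @export
order_blocks <- function(block_graph, type = NULL) {
  stopifnot(inherits(block_graph, "block_graph"))
  if (is.null(type)) type <- classify_structure(block_graph)
  und <- .block_igraph(block_graph)
  occ_ids <- block_graph$occurrences$occ
  n <- length(occ_ids)

  as_ids <- function(v) as.integer(igraph::as_ids(v))

  if (type == "other") {
    start <- occ_ids[which.min(.first_atom(block_graph, occ_ids))]
    ord <- as_ids(igraph::dfs(und, root = as.character(start))$order)
    return(list(backbone = NULL, branch = NULL, branch_at = NA_integer_,
                cyclic = FALSE, order = ord))
  }

  deg <- igraph::degree(und)
  cyclic <- igraph::ecount(und) >= n

  if (!cyclic && all(deg <= 2L)) {                      # plain chain
    if (n == 1L) {
      backbone <- occ_ids
    } else {
      ends <- occ_ids[deg[as.character(occ_ids)] <= 1L]
      p <- igraph::shortest_paths(und, from = as.character(ends[1]),
                                  to = as.character(ends[2]))$vpath[[1]]
      backbone <- .orient_path(block_graph, as_ids(p))
    }
    return(list(backbone = backbone, branch = NULL, branch_at = NA_integer_,
                cyclic = FALSE, order = backbone))
  }

  if (!cyclic) {                                        # singly branched tree
    bn <- occ_ids[deg[as.character(occ_ids)] >= 3L]
    arms <- .arms_from(und, bn)
    arms <- arms[order(-lengths(arms),
                       vapply(arms, function(a) .first_atom(block_graph, a[1]),
                              numeric(1)))]
    spine <- c(rev(arms[[1]]), bn, arms[[2]])
    backbone <- .orient_path(block_graph, spine)
    branch <- arms[[3]]
    return(list(backbone = backbone, branch = branch,
                branch_at = match(bn, backbone), cyclic = FALSE,
                order = c(backbone, branch)))
  }

  # cyclic core (pure ring or ring + one pendant chain)
  ring <- occ_ids[igraph::coreness(und)[as.character(occ_ids)] >= 2L]
  pend <- setdiff(occ_ids, ring)

  if (length(pend) == 0L) {                             # pure cycle
    backbone <- .walk_ring(block_graph, und, ring,
                           start = ring[which.min(.first_atom(block_graph, ring))])
    return(list(backbone = backbone, branch = NULL, branch_at = NA_integer_,
                cyclic = TRUE, order = backbone))
  }

  # branch-cyclic: unique attachment (degree-3 ring node)
  bn <- occ_ids[deg[as.character(occ_ids)] >= 3L]
  arms <- .arms_from(und, bn)
  branch <- arms[[which(vapply(arms, function(a) a[1] %in% pend, logical(1)))]]
  rot <- .walk_ring(block_graph, und, ring, start = bn)
  backbone <- c(rot[-1], rot[1])                        # branching block last
  list(backbone = backbone, branch = branch,
       branch_at = match(bn, backbone), cyclic = TRUE,
       order = c(backbone, branch))
}

# paths from (but excluding) a hub node to each leaf, ordered outward
.arms_from <- function(und, hub) {
  g2 <- igraph::delete_vertices(und, as.character(hub))
  comps <- igraph::components(g2)
  nb <- as.integer(igraph::as_ids(igraph::neighbors(und, as.character(hub))))
  lapply(seq_len(comps$no), function(k) {
    members <- as.integer(names(comps$membership)[comps$membership == k])
    start <- intersect(nb, members)[1]
    sub <- igraph::induced_subgraph(g2, as.character(members))
    sdeg <- igraph::degree(sub)
    leaf <- if (length(members) == 1L) members else
      setdiff(as.integer(names(sdeg)[sdeg <= 1L]), start)
    if (length(leaf) == 0L) leaf <- start
    p <- igraph::shortest_paths(sub, from = as.character(start),
                                to = as.character(leaf[1]))$vpath[[1]]
    as.integer(igraph::as_ids(p))
  })
}

# one deterministic rotation of a ring, following the dominant acyl->amine
# direction, beginning at `start`
.walk_ring <- function(block_graph, und, ring, start) {
  nb <- as.integer(igraph::as_ids(igraph::neighbors(und, as.character(start))))
  nb <- intersect(nb, ring)
  if (length(ring) == 1L) return(start)
  if (length(ring) == 2L) {
    return(.one_of(block_graph, start, setdiff(nb, start)))
  }
  walk_from <- function(second) {
    path <- c(start, second)
    while (length(path) < length(ring)) {
      cur <- path[length(path)]
      nxt <- setdiff(intersect(
        as.integer(igraph::as_ids(igraph::neighbors(und, as.character(cur)))),
        ring), path)
      path <- c(path, nxt[1])
    }
    path
  }
  cands <- lapply(unique(nb), walk_from)
  scores <- vapply(cands, function(p) .direction_score(block_graph, p, wrap = TRUE),
                   numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    seconds <- vapply(cands[best], function(p) .first_atom(block_graph, p[2]),
                      numeric(1))
    best <- best[which.min(seconds)]
  }
  cands[[best[1]]]
}

.one_of <- function(block_graph, start, rest) c(start, rest[1])
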