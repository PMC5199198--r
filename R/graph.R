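#' Build a directed redundancy graph from comparison records
#'
#' Nodes are proteomes; a directed edge X -> Y means "X is redundant to Y"
#' and is created for every performed comparison with subject Y, query X and
#' similarity at or above the threshold. The threshold is applied with a
#' 1e-12 absolute tolerance so a similarity computed as exactly 0.9 is not
#' lost to floating-point representation. Skipped and below-threshold
#' comparisons produce no edge; proteomes without edges remain as isolated
#' nodes.
#'
#' @param comparisons A tibble of comparison records as returned by
#'   [compare_group()] (`subject_id`, `query_id`, `similarity`,
#'   `performed`).
#' @param metadata A metadata tibble as returned by [read_metadata_table()]
#'   or [proteomes_metadata]; every proteome mentioned in `comparisons` must
#'   be present, and every metadata row becomes a node.
#' @param threshold Minimum similarity for an edge (default 0.9).
#' @return An object of class `redundancy_graph`: a list with `nodes` (the
#'   metadata tibble), `edges` (tibble `from`, `to`, `similarity`) and
#'   `threshold`.
#' @export
build_graph <- function(comparisons, metadata, threshold = 0.9) {
  comparisons <- tibble::as_tibble(comparisons)
  metadata <- tibble::as_tibble(metadata)
  validate_metadata(metadata)
  mentioned <- unique(c(comparisons$subject_id, comparisons$query_id))
  unknown <- setdiff(mentioned, metadata$proteome_id)
  if (length(unknown) > 0) {
    abort(sprintf("Comparison references proteome(s) absent from metadata: %s",
                  paste(unknown, collapse = ", ")))
  }
  perf <- comparisons[comparisons$performed %in% TRUE, ]
  if (nrow(perf) > 0 &&
      any(perf$similarity < 0 | perf$similarity > 1, na.rm = TRUE)) {
    abort("Similarities of performed comparisons must be in [0, 1].")
  }
  keep <- perf$similarity >= threshold - 1e-12 &
    perf$subject_id != perf$query_id
  edges <- tibble::tibble(
    from = perf$query_id[keep],   # the redundant proteome
    to = perf$subject_id[keep],   # the proteome it is redundant to
    similarity = perf$similarity[keep]
  )
  structure(list(nodes = metadata, edges = edges, threshold = threshold),
            class = "redundancy_graph")
}

#' @export
print.redundancy_graph <- function(x, ...) {
  cat(sprintf("<redundancy_graph> %d nodes, %d edges (threshold %.3g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

# Original out-/in-neighbour lists, named by node id.
adjacency <- function(graph) {
  ids <- graph$nodes$proteome_id
  out <- lapply(stats::setNames(ids, ids), function(i) {
    unique(graph$edges$to[graph$edges$from == i])
  })
  inn <- lapply(stats::setNames(ids, ids), function(i) {
    unique(graph$edges$from[graph$edges$to == i])
  })
  list(out = out, inn = inn)
}

#' Initial reduction state for a redundancy graph
#'
#' All nodes surviving, nothing removed, nothing represented.
#'
#' @param graph A `redundancy_graph`.
#' @param protected Ids of proteomes immune to removal (reference proteomes
#'   and any user-supplied immune list); must be a subset of the nodes.
#' @param seed Integer seed for the final tie-break.
#' @return An object of class `reduction_state`.
#' @export
new_reduction_state <- function(graph, protected = character(0), seed = 0L) {
  ids <- graph$nodes$proteome_id
  bad <- setdiff(protected, ids)
  if (length(bad) > 0) {
    abort(sprintf("Protected id(s) not in graph: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(surviving = ids, removed = character(0),
         surviving_neighbours = list(), represented = list(),
         protected = protected, seed = as.integer(seed)),
    class = "reduction_state"
  )
}

#' Rank vector of a surviving node
#'
#' The quintuple used to rank proteomes for elimination, in comparison
#' order: indegree (number of surviving proteomes redundant to this one —
#' higher is better), outdegree (number of surviving proteomes this one is
#' redundant to — lower is better), priority score (2 for reference
#' proteomes, 1 otherwise), annotation level, and previous redundancy state
#' (1 non-redundant, 0 redundant). Degrees are counted on the surviving
#' subgraph, so ranks change as nodes are eliminated.
#'
#' @param graph A `redundancy_graph`.
#' @param state A `reduction_state`.
#' @param node A surviving node id.
#' @return A named integer vector `(indegree, outdegree, priority_score,
#'   annotation_level, previous_state)`.
#' @export
rank_vector <- function(graph, state, node) {
  if (!node %in% state$surviving) {
    abort(sprintf("Node '%s' is not in the surviving set.", node))
  }
  e <- graph$edges
  alive_from <- e$from %in% state$surviving
  alive_to <- e$to %in% state$surviving
  indeg <- sum(e$to == node & alive_from)
  outdeg <- sum(e$from == node & alive_to)
  md <- graph$nodes[graph$nodes$proteome_id == node, ]
  c(indegree = indeg, outdegree = outdeg,
    priority_score = md$priority_score[1],
    annotation_level = md$annotation_level[1],
    previous_state = md$previous_state[1])
}

#' Compare two rank vectors
#'
#' Lexicographic over the five components: higher indegree wins; then lower
#' outdegree; then higher priority score; then higher annotation level; then
#' higher previous state; otherwise a tie.
#'
#' @param a,b Rank vectors as returned by [rank_vector()] (numeric vectors
#'   of length 5 in the same component order).
#' @return `"a-higher"`, `"b-higher"` or `"tie"`.
#' @examples
#' compare_rank(c(4, 5, 1, 0, 1), c(5, 4, 1, 0, 1))  # "b-higher"
#' @export
compare_rank <- function(a, b) {
  stopifnot(length(a) == 5, length(b) == 5)
  # flip outdegree so that "greater is better" holds componentwise
  ka <- c(a[1], -a[2], a[3], a[4], a[5])
  kb <- c(b[1], -b[2], b[3], b[4], b[5])
  for (i in 1:5) {
    if (ka[i] > kb[i]) return("a-higher")
    if (ka[i] < kb[i]) return("b-higher")
  }
  "tie"
}

#' Can a node be removed without breaking domination?
#'
#' A node is removable iff it is not protected, it has at least one
#' surviving out-neighbour (which will represent it), and it is not the
#' last surviving neighbour of any already-removed node — every removed
#' proteome must keep a direct edge to some survivor, so the final set
#' dominates all removed nodes.
#'
#' @inheritParams rank_vector
#' @return `TRUE` or `FALSE`.
#' @export
is_removable <- function(graph, state, node) {
  if (!node %in% state$surviving) {
    abort(sprintf("Node '%s' is not in the surviving set.", node))
  }
  if (node %in% state$protected) return(FALSE)
  out_nb <- unique(graph$edges$to[graph$edges$from == node])
  if (!any(out_nb %in% setdiff(state$surviving, node))) return(FALSE)
  for (r in state$removed) {
    if (length(setdiff(state$surviving_neighbours[[r]], node)) == 0) {
      return(FALSE)
    }
  }
  TRUE
}

#' Select the weakest removable node
#'
#' Among removable nodes, returns the one ranking lowest under
#' [compare_rank()]. Ties are broken by removing the node whose represented
#' set is smaller (the node connected to the more comprehensive set of
#' removed proteomes is kept); remaining ties are resolved by the ambient
#' random number generator, which [reduce_graph()] seeds for
#' reproducibility.
#'
#' @inheritParams rank_vector
#' @return A node id, or `NULL` when no node is removable.
#' @export
select_weakest <- function(graph, state) {
  cand <- state$surviving[vapply(state$surviving, is_removable,
                                 logical(1), graph = graph, state = state)]
  if (length(cand) == 0) return(NULL)
  ranks <- lapply(cand, rank_vector, graph = graph, state = state)
  weakest <- cand[1]
  wrank <- ranks[[1]]
  tied <- weakest
  for (i in seq_along(cand)[-1]) {
    cmp <- compare_rank(ranks[[i]], wrank)
    if (cmp == "b-higher") {          # cand[i] ranks lower
      weakest <- cand[i]
      wrank <- ranks[[i]]
      tied <- weakest
    } else if (cmp == "tie") {
      tied <- c(tied, cand[i])
    }
  }
  if (length(tied) == 1) return(tied)
  rep_size <- vapply(tied, function(id) {
    length(state$represented[[id]] %||% character(0))
  }, integer(1))
  tied <- tied[rep_size == min(rep_size)]
  if (length(tied) == 1) return(tied)
  tied[sample.int(length(tied), 1)]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Remove one node from the surviving set
#'
#' Moves the node to the removed list, records its surviving out-neighbours
#' as its representatives (each gains the node in its represented set), and
#' deletes the node from the surviving-neighbour sets of previously removed
#' proteomes. Representation is always via original direct edges — it is
#' never re-routed transitively.
#'
#' @inheritParams rank_vector
#' @return The updated `reduction_state`.
#' @export
remove_node <- function(graph, state, node) {
  if (!is_removable(graph, state, node)) {
    abort(sprintf("Node '%s' is not removable.", node))
  }
  out_nb <- unique(graph$edges$to[graph$edges$from == node])
  keepers <- intersect(out_nb, setdiff(state$surviving, node))
  state$surviving <- setdiff(state$surviving, node)
  state$removed <- c(state$removed, node)
  state$surviving_neighbours[[node]] <- keepers
  for (k in keepers) {
    state$represented[[k]] <- c(state$represented[[k]] %||% character(0),
                                node)
  }
  for (r in setdiff(state$removed, node)) {
    state$surviving_neighbours[[r]] <-
      setdiff(state$surviving_neighbours[[r]], node)
  }
  state
}

#' Reduce a redundancy graph to a dominating set
#'
#' Iterative weakest-node elimination: ranks are recomputed on the surviving
#' subgraph, the lowest-ranking removable node is eliminated, and the loop
#' repeats until no further reduction is possible. The survivors form a
#' dominating set of the removed nodes — every removed proteome keeps a
#' direct edge to at least one survivor, its representative — and protected
#' nodes always survive. The result is deterministic for a given seed.
#'
#' @inheritParams new_reduction_state
#' @return The final `reduction_state`, with class `prm_reduction`
#'   prepended. Its `surviving_neighbours` entries give each removed
#'   proteome's surviving representatives.
#' @export
reduce_graph <- function(graph, protected = character(0), seed = 0L) {
  state <- new_reduction_state(graph, protected, seed)
  state <- with_private_seed(seed, {
    repeat {
      w <- select_weakest(graph, state)
      if (is.null(w)) break
      state <- remove_node(graph, state, w)
    }
    state
  })
  class(state) <- c("prm_reduction", class(state))
  state
}

#' @export
print.prm_reduction <- function(x, ...) {
  cat(sprintf("<prm_reduction> %d surviving, %d removed (%d protected)\n",
              length(x$surviving), length(x$removed), length(x$protected)))
  invisible(x)
}

#' Exact minimum dominating set size (test oracle)
#'
#' Exhaustive search over vertex subsets containing the protected nodes for
#' the smallest set D such that every node outside D has an out-edge into D.
#' Exponential in the node count; refuses graphs with more than 15 nodes.
#' Used to check that the elimination heuristic never reports an impossibly
#' small set.
#'
#' @param graph A `redundancy_graph`.
#' @param protected Node ids that must be inside the dominating set.
#' @return The minimal dominating-set size (integer).
#' @export
brute_force_dominating_set <- function(graph, protected = character(0)) {
  ids <- graph$nodes$proteome_id
  n <- length(ids)
  if (n > 15) abort("Exhaustive search is limited to 15 nodes.")
  if (n == 0) return(0L)
  prot_mask <- bitwShiftL(1L, which(ids %in% protected) - 1L)
  prot_mask <- if (length(prot_mask)) Reduce(bitwOr, prot_mask) else 0L
  # out-neighbour bitmasks
  out_mask <- integer(n)
  for (i in seq_len(n)) {
    nb <- which(ids %in% graph$edges$to[graph$edges$from == ids[i]])
    out_mask[i] <- if (length(nb)) {
      Reduce(bitwOr, bitwShiftL(1L, nb - 1L))
    } else 0L
  }
  best <- n
  for (mask in 0:(2^n - 1)) {
    if (bitwAnd(mask, prot_mask) != prot_mask) next
    size <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (size >= best) next
    ok <- TRUE
    for (i in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) next
      if (bitwAnd(out_mask[i], mask) == 0L) { ok <- FALSE; break }
    }
    if (ok) best <- size
  }
  as.integer(best)
}

#' Check that a reduction state is a valid domination of the removed nodes
#'
#' Every removed node must retain an original out-edge to a survivor, the
#' surviving and removed sets must partition the nodes, and protected nodes
#' must survive.
#'
#' @param graph A `redundancy_graph`.
#' @param state A `reduction_state` / `prm_reduction`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_reduction <- function(graph, state) {
  ids <- graph$nodes$proteome_id
  if (!setequal(c(state$surviving, state$removed), ids) ||
      length(intersect(state$surviving, state$removed)) > 0) {
    abort("surviving and removed do not partition the node set.")
  }
  if (!all(state$protected %in% state$surviving)) {
    abort("A protected node was removed.")
  }
  for (r in state$removed) {
    nb <- state$surviving_neighbours[[r]]
    out_nb <- unique(graph$edges$to[graph$edges$from == r])
    if (length(nb) == 0 || !all(nb %in% state$surviving) ||
        !all(nb %in% out_nb)) {
      abort(sprintf("Removed node '%s' is not dominated by a survivor.", r))
    }
  }
  invisible(TRUE)
}
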