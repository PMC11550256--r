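# Finite posets stored with their full reflexive-transitive closure (the
# ground sets here are small: |T(N-ring)| = |Sigma| + r - 1 for a binary
# network), plus the cover graph both by definition (transitive reduction)
# and by the leaf-removal / reticulation-edge-contraction construction that
# realises the Hasse diagram of a tree-child network's internal-tree-node
# poset as a minor of the network.

#' Construct a poset
#'
#' Builds a partially ordered set from a set of elements and a list of
#' comparable pairs; the relation is closed under reflexivity and
#' transitivity, and antisymmetry is verified (a cycle raises an error).
#'
#' @param elements Atomic vector of distinct elements (sorted internally;
#'   the sorted order also fixes the bitmask order of the downset DP).
#' @param relations Two-column matrix of pairs `(x, y)` meaning `x` precedes
#'   `y`; may be `NULL` or empty for an antichain.
#' @return An object of class `poset` with fields `elements` and `leq`
#'   (logical closure matrix).
#' @examples
#' P <- poset(letters[1:4], rbind(c("a", "c"), c("b", "c"), c("b", "d")))
#' maximal_elements(P)
#' @export
poset <- function(elements, relations = NULL) {
  if (anyDuplicated(elements)) stop_input("poset: duplicated elements")
  elements <- sort(elements)
  n <- length(elements)
  key <- as.character(elements)
  leq <- diag(n) > 0
  dimnames(leq) <- list(key, key)
  if (!is.null(relations) && length(relations) > 0L) {
    if (is.data.frame(relations)) relations <- as.matrix(relations)
    if (!is.matrix(relations) || ncol(relations) != 2L) {
      stop_input("poset: relations must be a two-column matrix")
    }
    i <- match(as.character(relations[, 1L]), key)
    j <- match(as.character(relations[, 2L]), key)
    if (anyNA(i) || anyNA(j)) stop_input("poset: relation over unknown elements")
    leq[cbind(i, j)] <- TRUE
    # Warshall closure
    for (k in seq_len(n)) {
      leq <- leq | (leq[, k] %o% leq[k, ])
    }
  }
  if (any(leq & t(leq) & !diag(n))) {
    stop_input("poset: relation is not antisymmetric (contains a cycle)")
  }
  structure(list(elements = elements, leq = leq), class = "poset")
}

#' @export
print.poset <- function(x, ...) {
  n <- length(x$elements)
  cat(sprintf("poset: %d elements, %d strict comparable pairs\n",
              n, sum(x$leq) - n))
  invisible(x)
}

poset_size <- function(P) length(P$elements)

strict_matrix <- function(P) P$leq & !diag(poset_size(P))

#' Maximal and minimal elements of a poset
#'
#' @param P A [poset()].
#' @return Vector of elements with no strictly larger (resp. smaller)
#'   element.
#' @export
maximal_elements <- function(P) {
  s <- strict_matrix(P)
  P$elements[rowSums(s) == 0L]
}

#' @rdname maximal_elements
#' @export
minimal_elements <- function(P) {
  s <- strict_matrix(P)
  P$elements[colSums(s) == 0L]
}

#' Order-dual of a poset
#'
#' Same ground set with all comparabilities reversed; an involution.  The
#' reversal bijection between linear extensions of a poset and of its dual
#' means the two have the same number of extensions.
#'
#' @param P A [poset()].
#' @return A [poset()].
#' @export
dualize <- function(P) {
  out <- P
  out$leq <- t(P$leq)
  dimnames(out$leq) <- dimnames(P$leq)
  out
}

subposet <- function(P, keep) {
  key <- as.character(keep)
  out <- P
  out$elements <- P$elements[match(keep, P$elements)]
  ord <- order(out$elements)
  out$elements <- out$elements[ord]
  out$leq <- P$leq[as.character(out$elements), as.character(out$elements), drop = FALSE]
  out
}

#' Reachability poset of a node subset
#'
#' Endows a subset `X` of the nodes of a network (a DAG) with the partial
#' order `x` precedes `y` iff a directed path from `x` to `y` exists in the
#' network; paths may pass through nodes outside `X`.
#'
#' @param N A [phylo_network()].
#' @param X Node identifiers (or names); defaults to the internal tree nodes
#'   `T(N-ring)`.
#' @return A [poset()] on the node identifiers in `X`.
#' @export
reachability_poset <- function(N, X = internal_tree_nodes(N)) {
  ids <- if (length(X) == 0L) integer(0) else resolve_node(N, X, several.ok = TRUE)
  if (length(ids) == 0L) return(poset(integer(0)))
  g <- as_igraph(N)
  d <- igraph::distances(g, v = as.character(ids), to = as.character(ids),
                         mode = "out")
  ids <- sort(ids)
  d <- d[as.character(ids), as.character(ids), drop = FALSE]
  P <- poset(ids)
  P$leq <- is.finite(d)
  dimnames(P$leq) <- list(as.character(ids), as.character(ids))
  P
}

# ---- cover graphs ---------------------------------------------------------

new_cover_graph <- function(nodes, edges) {
  nodes <- sort(nodes)
  if (length(edges) == 0L) {
    edges <- matrix(vector(mode = mode(nodes), length = 0L), ncol = 2L)
  }
  colnames(edges) <- c("from", "to")
  structure(list(nodes = nodes, edges = edges), class = "cover_graph")
}

#' @export
print.cover_graph <- function(x, ...) {
  cat(sprintf("cover_graph: %d nodes, %d cover edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Cover graph (Hasse diagram) by transitive reduction
#'
#' Computes the cover relation directly from its definition: `x` is covered
#' by `y` iff `x` strictly precedes `y` and no `z` lies strictly between.
#' Cubic in the number of elements; this is the independent oracle against
#' which the contraction construction of [contracted_cover_graph()] is
#' verified.
#'
#' @param P A [poset()] with at most ~200 elements.
#' @return A `cover_graph` object: fields `nodes` and `edges` (two-column
#'   matrix of cover pairs, oriented from smaller to larger).
#' @export
cover_graph <- function(P) {
  if (poset_size(P) > 200L) stop_guard("cover_graph: oracle limited to 200 elements")
  s <- strict_matrix(P)
  implied <- (s %*% s) > 0
  covers <- s & !implied
  idx <- which(covers, arr.ind = TRUE)
  edges <- cbind(P$elements[idx[, 1L]], P$elements[idx[, 2L]])
  ord <- order(edges[, 1L], edges[, 2L])
  new_cover_graph(P$elements, edges[ord, , drop = FALSE])
}

#' Cover graph of the internal-tree-node poset by edge contraction
#'
#' For a binary tree-child network, the Hasse diagram of the reachability
#' poset on internal tree nodes can be read off the network itself: remove
#' all leaves, discard reticulations whose child is a leaf, and contract
#' every remaining reticulation into its (unique, tree-type) child.  The
#' construction iterates linearly over the nodes, building a quotient map
#' `quot`: leaves map to the sentinel `-1`, each internal tree node to a
#' fresh index (ascending identifier order), and each surviving reticulation
#' to the index of its child.  The result is isomorphic to the transitive
#' reduction of the reachability poset ([cover_graph()] of
#' [reachability_poset()]) and, being obtained by deletions and edge
#' contractions, is a minor of the network — hence its tree-width is at most
#' that of the network.
#'
#' @param N A pristine binary tree-child [phylo_network()].
#' @return A list with components `cover` (a `cover_graph` whose nodes are
#'   the representative internal tree node identifiers), `quot` (named
#'   integer vector over all network nodes, sentinel `-1`), and
#'   `index_to_node` (integer vector mapping cover indices to representative
#'   node identifiers).
#' @export
contracted_cover_graph <- function(N) {
  if (!is_tree_child(N)) {
    stop_domain(paste0("contracted_cover_graph: network is not tree-child; ",
                       "a reticulation's child need not be a tree node, so the ",
                       "contraction need not produce the Hasse diagram"))
  }
  indeg <- in_degrees(N)
  outdeg <- out_degrees(N)
  nodes <- sort(N$nodes)
  quot <- rep(-1L, length(nodes))
  names(quot) <- as.character(nodes)

  internal_tree <- sort(N$nodes[outdeg >= 1L & indeg <= 1L])
  quot[as.character(internal_tree)] <- seq_along(internal_tree)

  rets <- N$nodes[indeg >= 2L]
  for (h in rets) {
    ch <- node_children(N, h)
    if (length(ch) != 1L) {
      stop_domain("contracted_cover_graph: reticulation without a unique child")
    }
    # reticulations whose child is a leaf have out-degree 0 after leaf
    # removal and are discarded; otherwise contract h into its tree child
    quot[as.character(h)] <- if (outdeg[as.character(ch)] == 0L) -1L else
      quot[as.character(ch)]
  }

  qa <- quot[as.character(N$edges[, "parent"])]
  qb <- quot[as.character(N$edges[, "child"])]
  keep <- qa > 0L & qb > 0L & qa != qb
  edges <- unique(cbind(qa[keep], qb[keep]))

  # The raw quotient can carry a transitively implied edge: if a reticulation
  # h (contracted into its child v) has parents u and y with u also an
  # ancestor of y, the network edge u->h yields the quotient edge u->[v]
  # even though u strictly precedes y which strictly precedes v.  Such an
  # edge is not a cover relation, so a transitive-reduction pass over the
  # contracted DAG itself (never touching the original network) prunes it.
  m <- length(internal_tree)
  if (m > 0L && nrow(edges) > 0L) {
    adj <- matrix(FALSE, m, m)
    adj[edges] <- TRUE
    reach <- adj
    for (k in seq_len(m)) reach <- reach | (reach[, k] %o% reach[k, ]) > 0
    covers <- adj & !((reach %*% reach) > 0)
    idx <- which(covers, arr.ind = TRUE)
    edges <- idx
  }
  edges <- cbind(internal_tree[edges[, 1L]], internal_tree[edges[, 2L]])
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  list(cover = new_cover_graph(internal_tree, edges),
       quot = quot,
       index_to_node = internal_tree)
}

#' Poset generated by a cover graph
#'
#' Reflexive-transitive closure of a DAG of cover relations; inverse of
#' [cover_graph()].
#'
#' @param cg A `cover_graph`.
#' @return A [poset()].
#' @export
poset_from_cover <- function(cg) {
  poset(cg$nodes, cg$edges)
}

#' Export a cover graph
#'
#' Writes the cover graph as an edge-list TSV (`from<TAB>to`) and, when a
#' quotient map is given, a JSON sidecar mapping each cover-graph node to
#' its contracted class of network nodes.
#'
#' @param ccg Result of [contracted_cover_graph()].
#' @param N The network it was computed from (for node names).
#' @param path File to write the TSV to; the sidecar gets extension
#'   `.classes.json`.
#' @return Invisibly, the TSV text.
#' @export
write_cover_graph <- function(ccg, N, path) {
  nm <- function(v) N$node_names[as.character(v)]
  edges <- ccg$cover$edges
  txt <- if (nrow(edges) == 0L) character(0) else
    paste0(nm(edges[, 1L]), "\t", nm(edges[, 2L]))
  writeLines(txt, path)
  classes <- lapply(seq_along(ccg$index_to_node), function(i) {
    unname(nm(as.integer(names(ccg$quot))[ccg$quot == i]))
  })
  names(classes) <- nm(ccg$index_to_node)
  jsonlite::write_json(classes, paste0(path, ".classes.json"))
  invisible(txt)
}
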