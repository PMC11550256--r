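# Rooted binary phylogenetic networks: a directed acyclic graph with a single
# root, leaves carrying taxon labels, and reticulations (in-degree >= 2 nodes)
# modelling hybridization.  Node identifiers are stable opaque integers that
# are assigned once at construction/parse time and never renumbered: cherry
# reductions return literal subnetworks, so the same identifier denotes the
# same node across a whole reduction sequence.

#' Construct a phylogenetic network
#'
#' Builds a rooted phylogenetic network from a parent-to-child edge list.
#' Nodes may be given as character names (identifiers are then assigned in
#' order of first appearance) or directly as positive integers.  Self-loops
#' and parallel edges are rejected; all other invariants (single root,
#' acyclicity, binary degrees, leaf labelling) are checked by
#' [validate_network()], which reports rather than throws, so that degenerate
#' graphs can be built and inspected.
#'
#' @param edges Two-column matrix or data frame of parent/child pairs
#'   (character names or integer ids).  May be `NULL` for a single-node
#'   network.
#' @param nodes Optional vector of all node names/ids; required for isolated
#'   nodes (e.g. the single-node network), otherwise inferred from `edges`.
#' @param leaf_labels Named character vector mapping leaf node names/ids to
#'   taxon labels.  Default `NULL` labels every leaf with its own node name.
#'   Use `character(0)` for an unlabelled network.
#' @return An object of class `phylo_network` with fields `nodes`, `edges`,
#'   `root`, `node_names` and `leaf_labels`.
#' @examples
#' N <- phylo_network(rbind(c("r", "a"), c("r", "b")))
#' network_level(N)
#' @export
phylo_network <- function(edges = NULL, nodes = NULL, leaf_labels = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.null(edges) && (!is.matrix(edges) || ncol(edges) != 2L)) {
    stop_input("phylo_network: edges must be a two-column matrix (parent, child)")
  }
  if (is.null(edges)) edges <- matrix(character(0), ncol = 2L)

  universe <- unique(c(t(edges), nodes))
  if (length(universe) == 0L) stop_input("phylo_network: no nodes given")

  if (is.numeric(universe)) {
    if (any(universe != trunc(universe)) || any(universe < 1)) {
      stop_input("phylo_network: integer node ids must be positive integers")
    }
    ids <- sort(as.integer(universe))
    names_vec <- paste0("n", ids)
    emat <- matrix(as.integer(edges), ncol = 2L)
  } else {
    universe <- as.character(universe)
    ids <- seq_along(universe)
    names_vec <- universe
    emat <- matrix(match(as.character(edges), universe), ncol = 2L)
    if (anyNA(emat)) stop_input("phylo_network: edge endpoint not in node set")
  }
  names(names_vec) <- as.character(ids)
  colnames(emat) <- c("parent", "child")

  if (nrow(emat) > 0L) {
    if (any(emat[, 1L] == emat[, 2L])) stop_input("phylo_network: self-loops are not allowed")
    if (anyDuplicated(paste(emat[, 1L], emat[, 2L]))) {
      stop_input("phylo_network: parallel edges are not allowed")
    }
  }

  N <- structure(list(nodes = ids, edges = emat, root = NA_integer_,
                      node_names = names_vec, leaf_labels = character(0)),
                 class = "phylo_network")
  indeg <- in_degrees(N)
  roots <- N$nodes[indeg == 0L]
  N$root <- if (length(roots) == 1L) roots else NA_integer_

  leaves <- network_leaves(N)
  if (is.null(leaf_labels)) {
    lab <- N$node_names[as.character(leaves)]
    names(lab) <- as.character(leaves)
  } else if (length(leaf_labels) == 0L) {
    lab <- character(0)
  } else {
    if (is.null(names(leaf_labels))) {
      stop_input("phylo_network: leaf_labels must be named by node")
    }
    who <- resolve_node(N, names(leaf_labels), several.ok = TRUE)
    lab <- as.character(leaf_labels)
    names(lab) <- as.character(who)
  }
  N$leaf_labels <- lab
  N
}

#' @export
print.phylo_network <- function(x, ...) {
  cat(sprintf("phylo_network: %d nodes, %d edges, %d leaves, %d reticulations\n",
              length(x$nodes), nrow(x$edges), length(network_leaves(x)),
              length(reticulation_nodes(x))))
  if (!is.na(x$root)) cat("root:", x$node_names[as.character(x$root)], "\n")
  invisible(x)
}

# ---- degree and neighbourhood helpers ------------------------------------

in_degrees <- function(N) {
  d <- tabulate(match(N$edges[, "child"], N$nodes), nbins = length(N$nodes))
  names(d) <- as.character(N$nodes)
  d
}

out_degrees <- function(N) {
  d <- tabulate(match(N$edges[, "parent"], N$nodes), nbins = length(N$nodes))
  names(d) <- as.character(N$nodes)
  d
}

node_children <- function(N, v) N$edges[N$edges[, "parent"] == v, "child"]

node_parents <- function(N, v) N$edges[N$edges[, "child"] == v, "parent"]

#' @export
network_leaves <- function(N) N$nodes[out_degrees(N) == 0L]

#' Reticulation and tree nodes of a network
#'
#' `reticulation_nodes()` returns the nodes of in-degree at least 2;
#' `tree_nodes()` the nodes of in-degree at most 1.  Together they partition
#' the node set.  Roles are always evaluated on *current* degrees, so a
#' former reticulation that lost a parent during a reduction counts as a
#' tree node thereafter.
#'
#' @param N A [phylo_network()].
#' @return Integer vector of node identifiers.
#' @export
reticulation_nodes <- function(N) N$nodes[in_degrees(N) >= 2L]

#' @rdname reticulation_nodes
#' @export
tree_nodes <- function(N) N$nodes[in_degrees(N) <= 1L]

#' Internal tree nodes
#'
#' The set of tree nodes that survive leaf removal: nodes of out-degree at
#' least 1 and in-degree at most 1.  This is the ground set of the
#' reachability poset whose linear extensions are counted by
#' [count_cherry_sequences()].
#'
#' @param N A [phylo_network()].
#' @return Integer vector of node identifiers (ascending).
#' @export
internal_tree_nodes <- function(N) {
  sort(N$nodes[out_degrees(N) >= 1L & in_degrees(N) <= 1L])
}

resolve_node <- function(N, v, several.ok = FALSE) {
  if (!several.ok && length(v) != 1L) stop_input("expected a single node")
  if (is.character(v)) {
    id <- N$nodes[match(v, N$node_names)]
  } else {
    id <- as.integer(v)
    id[!(id %in% N$nodes)] <- NA_integer_
  }
  if (anyNA(id)) {
    stop_input(sprintf("unknown node identifier: %s",
                       paste(v[is.na(id)], collapse = ", ")))
  }
  id
}

as_igraph <- function(N, directed = TRUE) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(N$edges[, "parent"]),
                   to = as.character(N$edges[, "child"])),
    directed = directed,
    vertices = data.frame(name = as.character(N$nodes))
  )
}

# nodes reachable from v by directed paths (including v itself); plain
# worklist BFS -- called on every reduction step, so kept dependency-free
reachable_from <- function(N, v) {
  seen <- v
  frontier <- v
  while (length(frontier) > 0L) {
    nxt <- unique(N$edges[N$edges[, "parent"] %in% frontier, "child"])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  as.integer(seen)
}

# ---- classification and validation ---------------------------------------

#' Classify a node by its current degrees
#'
#' Role is a pure function of in/out-degree: in-degree >= 2 gives a
#' reticulation, out-degree 0 a leaf, in-degree 0 (with children) the root,
#' anything else an internal tree node.
#'
#' @param N A [phylo_network()].
#' @param v A node identifier or node name.
#' @return One of `"root"`, `"internal_tree"`, `"leaf"`, `"reticulation"`.
#' @export
classify_node <- function(N, v) {
  id <- resolve_node(N, v)
  classify_nodes(N)[[as.character(id)]]
}

#' @rdname classify_node
#' @return `classify_nodes()`: named character vector over all nodes.
#' @export
classify_nodes <- function(N) {
  indeg <- in_degrees(N)
  outdeg <- out_degrees(N)
  role <- ifelse(indeg >= 2L, "reticulation",
          ifelse(outdeg == 0L, "leaf",
          ifelse(indeg == 0L, "root", "internal_tree")))
  names(role) <- as.character(N$nodes)
  role
}

#' Validate a network
#'
#' Checks the invariants of a rooted binary phylogenetic network and returns
#' a report of violations instead of throwing.  `"pristine"` mode enforces
#' the full definition (bijective leaf labelling, no elementary nodes,
#' reticulations of out-degree exactly 1); `"reduced"` mode, meant for
#' subnetworks produced by cherry reductions, drops the labelling and
#' elementary-node rules and evaluates degree constraints against current
#' degrees only.
#'
#' @param N A [phylo_network()].
#' @param mode `"pristine"` or `"reduced"`.
#' @return Character vector of violated invariants; empty when valid.
#' @export
validate_network <- function(N, mode = c("pristine", "reduced")) {
  mode <- match.arg(mode)
  bad <- character(0)
  indeg <- in_degrees(N)
  outdeg <- out_degrees(N)

  roots <- N$nodes[indeg == 0L]
  if (length(roots) != 1L) {
    bad <- c(bad, sprintf("rooted: expected exactly one in-degree-0 node, found %d",
                          length(roots)))
  }
  g <- as_igraph(N)
  if (!igraph::is_dag(g)) bad <- c(bad, "acyclic: directed graph contains a cycle")
  if (length(roots) == 1L && igraph::is_dag(g)) {
    reach <- reachable_from(N, roots)
    if (length(reach) != length(N$nodes)) {
      bad <- c(bad, "rooted: not every node is reachable from the root")
    }
  }

  single <- length(N$nodes) == 1L
  for (i in seq_along(N$nodes)) {
    v <- N$nodes[i]
    di <- indeg[i]; do <- outdeg[i]
    if (di >= 2L && do != 1L) {
      bad <- c(bad, sprintf("binary: reticulation %s has out-degree %d (expected 1)",
                            N$node_names[as.character(v)], do))
    } else if (di == 0L && !single && !(do == 2L)) {
      bad <- c(bad, sprintf("binary: root %s has out-degree %d (expected 2)",
                            N$node_names[as.character(v)], do))
    } else if (di == 1L && do >= 1L && do != 2L) {
      if (!(mode == "pristine" && do == 1L)) {
        # (1,1) is reported below as an elementary node in pristine mode
        bad <- c(bad, sprintf("binary: internal tree node %s has out-degree %d (expected 2)",
                              N$node_names[as.character(v)], do))
      }
    }
  }

  if (mode == "pristine") {
    elem <- N$nodes[indeg == 1L & outdeg == 1L]
    for (v in elem) {
      bad <- c(bad, sprintf("elementary: node %s has in-degree 1 and out-degree 1",
                            N$node_names[as.character(v)]))
    }
    leaves <- network_leaves(N)
    lab <- N$leaf_labels[as.character(leaves)]
    if (anyNA(lab)) {
      bad <- c(bad, sprintf("labels: %d leaves are unlabelled", sum(is.na(lab))))
    }
    lab <- lab[!is.na(lab)]
    if (anyDuplicated(lab)) {
      bad <- c(bad, sprintf("labels: duplicated leaf labels: %s",
                            paste(unique(lab[duplicated(lab)]), collapse = ", ")))
    }
  }
  bad
}

#' Tree-child test
#'
#' A network is tree-child when every internal node (out-degree >= 1) has at
#' least one child of tree type (in-degree <= 1), evaluated on current
#' degrees.  Every phylogenetic tree is tree-child, and every tree-child
#' network is orchard.
#'
#' @param N A [phylo_network()].
#' @return `TRUE` or `FALSE`.
#' @export
is_tree_child <- function(N) {
  indeg <- in_degrees(N)
  internal <- N$nodes[out_degrees(N) >= 1L]
  for (v in internal) {
    ch <- node_children(N, v)
    if (!any(indeg[as.character(ch)] <= 1L)) return(FALSE)
  }
  TRUE
}

#' Remove all leaves
#'
#' Returns the graph obtained by deleting every out-degree-0 node together
#' with its incident edges.  For a single-node network the result is empty.
#' The internal tree nodes of this stripped graph form the ground set of the
#' poset central to this package.
#'
#' @param N A [phylo_network()].
#' @return A `phylo_network` (possibly with zero nodes, class preserved).
#' @export
strip_leaves <- function(N) {
  keep <- N$nodes[out_degrees(N) >= 1L]
  subnetwork(N, keep)
}

# literal subnetwork on a node subset: identifiers, names and labels survive
subnetwork <- function(N, keep) {
  emat <- N$edges[N$edges[, "parent"] %in% keep & N$edges[, "child"] %in% keep, ,
                  drop = FALSE]
  N2 <- N
  N2$nodes <- sort(as.integer(keep))
  N2$edges <- emat
  N2$node_names <- N$node_names[as.character(N2$nodes)]
  N2$leaf_labels <- N$leaf_labels[names(N$leaf_labels) %in% as.character(N2$nodes)]
  indeg <- in_degrees(N2)
  roots <- N2$nodes[indeg == 0L]
  N2$root <- if (length(roots) == 1L) roots else NA_integer_
  N2
}

# ---- blobs and level ------------------------------------------------------

#' Blobs (nontrivial biconnected components) and network level
#'
#' A blob is a maximal biconnected component of the underlying undirected
#' graph with at least 3 nodes (bridges are trivial and carry no
#' reticulation).  The level of a network is the maximum number of
#' reticulations over its blobs, 0 for trees.
#'
#' @param N A [phylo_network()].
#' @return `network_blobs()`: a list of blobs, each a list with `nodes`
#'   (identifiers) and `reticulation_count`.  `network_level()`: a
#'   non-negative integer.
#' @export
network_blobs <- function(N) {
  if (nrow(N$edges) == 0L) return(list())
  g <- as_igraph(N, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  ret <- reticulation_nodes(N)
  out <- list()
  for (comp in bc$components) {
    ids <- as.integer(names(comp))
    if (length(ids) < 3L) next
    out[[length(out) + 1L]] <- list(
      nodes = sort(ids),
      reticulation_count = sum(ids %in% ret)
    )
  }
  out
}

#' @rdname network_blobs
#' @export
network_level <- function(N) {
  blobs <- network_blobs(N)
  if (length(blobs) == 0L) return(0L)
  max(vapply(blobs, function(b) b$reticulation_count, integer(1)))
}

#' Tree-width upper bounds from level and reticulation number
#'
#' For a level-`k` network with `r` reticulations the tree-width of the
#' underlying graph satisfies `tw(N) <= k + 1 <= r + 1`; both bounds are
#' returned.
#'
#' @param level_k Network level (non-negative integer).
#' @param reticulations_r Number of reticulations; must be at least `level_k`.
#' @return Named integer vector `c(from_level = k + 1, from_reticulations = r + 1)`.
#' @export
treewidth_bounds <- function(level_k, reticulations_r) {
  if (length(level_k) != 1L || length(reticulations_r) != 1L ||
      level_k < 0 || reticulations_r < 0 || level_k > reticulations_r) {
    stop_input("treewidth_bounds: need 0 <= level_k <= reticulations_r")
  }
  c(from_level = as.integer(level_k) + 1L,
    from_reticulations = as.integer(reticulations_r) + 1L)
}

#' Label-preserving isomorphism of two networks
#'
#' Tests whether two networks are isomorphic as directed graphs under a
#' bijection that maps each labelled leaf of one to the leaf with the same
#' taxon label in the other (used by the read/write round-trip tests, where
#' node identifiers may be renumbered but labels must be preserved).
#'
#' @param N1,N2 [phylo_network()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
networks_isomorphic <- function(N1, N2) {
  if (length(N1$nodes) != length(N2$nodes) || nrow(N1$edges) != nrow(N2$edges)) {
    return(FALSE)
  }
  l1 <- sort(unname(N1$leaf_labels))
  l2 <- sort(unname(N2$leaf_labels))
  if (!identical(l1, l2)) return(FALSE)
  if (length(N1$nodes) == 1L) return(TRUE)
  all_labels <- unique(c(N1$leaf_labels, N2$leaf_labels))
  colour <- function(N) {
    cl <- integer(length(N$nodes))
    names(cl) <- as.character(N$nodes)
    cl[names(N$leaf_labels)] <- match(N$leaf_labels, all_labels)
    unname(cl)
  }
  igraph::isomorphic(as_igraph(N1), as_igraph(N2), method = "vf2",
                     vertex.color1 = colour(N1), vertex.color2 = colour(N2))
}
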