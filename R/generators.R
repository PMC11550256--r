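# Synthetic network generators and level / tree-width bound machinery.
#
# Random networks are grown from a single node by inverting the two cherry
# reductions: splitting a leaf into a cherry, or turning a pair of leaves
# (u, h) into a reticulated cherry (u becomes the internal tree parent of a
# fresh leaf and of h; h acquires a second parent and a fresh leaf child).
# Growth is the reverse of a reduction sequence, so every generated network
# is orchard by construction; tree-child networks are obtained by rejecting
# reticulation placements whose new reticulation would leave its other
# parent without a tree child.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

grow_network <- function(num_leaves, num_reticulations, tree_child, max_rejections) {
  # mutable flat representation; node ids never reused
  edges <- matrix(integer(0), ncol = 2L)
  next_id <- 2L
  leaves <- 1L          # current leaf ids
  new_node <- function() { id <- next_id; next_id <<- next_id + 1L; id }

  parent_of <- function(v) edges[edges[, 2L] == v, 1L]
  children_of <- function(v) edges[edges[, 1L] == v, 2L]
  is_reticulation <- function(v) sum(edges[, 2L] == v) >= 2L

  split_leaf <- function() {
    u <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    a <- new_node(); b <- new_node()
    edges <<- rbind(edges, c(u, a), c(u, b))
    leaves <<- c(setdiff(leaves, u), a, b)
  }

  valid_ret_pairs <- function() {
    # (u, h): distinct leaves; for tree-child growth, h's sibling must not be
    # a reticulation (h's parent would otherwise lose its only tree child)
    hs <- leaves
    if (tree_child) {
      ok <- vapply(hs, function(h) {
        p <- parent_of(h)
        if (length(p) != 1L) return(FALSE)
        sib <- setdiff(children_of(p), h)
        length(sib) == 1L && !is_reticulation(sib)
      }, logical(1))
      hs <- hs[ok]
    }
    if (length(hs) == 0L) return(NULL)
    d <- expand.grid(u = leaves, h = hs)
    d[d$u != d$h, , drop = FALSE]
  }

  add_reticulated_cherry <- function() {
    pairs <- valid_ret_pairs()
    if (is.null(pairs) || nrow(pairs) == 0L) return(FALSE)
    pick <- pairs[sample.int(nrow(pairs), 1L), ]
    u <- pick$u; h <- pick$h
    l1 <- new_node(); l3 <- new_node()
    edges <<- rbind(edges, c(u, l1), c(u, h), c(h, l3))
    leaves <<- c(setdiff(leaves, c(u, h)), l1, l3)
    TRUE
  }

  # a leaf split adds one leaf; a reticulated-cherry addition keeps the leaf
  # count (two leaves are consumed, two fresh ones created) and adds one
  # reticulation -- so the two quotas are independent
  splits_left <- num_leaves - 1L
  rets_left <- num_reticulations
  while (splits_left + rets_left > 0L) {
    want_ret <- rets_left > 0L && length(leaves) >= 2L &&
      (splits_left == 0L ||
         stats::runif(1) < rets_left / (rets_left + splits_left))
    if (want_ret && add_reticulated_cherry()) {
      rets_left <- rets_left - 1L
    } else if (splits_left > 0L) {
      split_leaf()
      splits_left <- splits_left - 1L
    } else {
      return(NULL)  # stuck: all remaining quota is reticulations, none fits
    }
  }
  list(edges = edges, leaves = leaves)
}

grow_with_retries <- function(num_leaves, num_reticulations, tree_child,
                              max_rejections) {
  for (attempt in seq_len(max(1L, max_rejections))) {
    raw <- grow_network(num_leaves, num_reticulations, tree_child, max_rejections)
    if (!is.null(raw)) return(raw)
  }
  stop_domain(paste0("generate: rejection budget exhausted; try fewer ",
                     "reticulations relative to leaves"))
}

finish_network <- function(raw) {
  nodes <- sort(unique(c(as.integer(raw$edges), 1L)))
  names_vec <- paste0("n", nodes)
  N <- phylo_network(
    edges = if (nrow(raw$edges) == 0L) NULL else
      matrix(paste0("n", raw$edges), ncol = 2L),
    nodes = names_vec, leaf_labels = character(0)
  )
  leaves <- network_leaves(N)
  lab <- paste0("t", seq_along(leaves))
  names(lab) <- as.character(leaves)
  N$leaf_labels <- lab
  N
}

#' Generate a random tree-child network
#'
#' Grows a pristine binary tree-child network with the requested numbers of
#' leaves and reticulations by reverse cherry reductions (see the package
#' vignette).  The output is orchard by construction and reproducible: the
#' same arguments always yield the identical network.
#'
#' @param num_leaves Number of leaves (at least 1).
#' @param num_reticulations Number of reticulations (at most
#'   `num_leaves - 2` when positive).
#' @param seed Integer seed; all randomness is local to the call.
#' @param max_rejections Budget for rejected reticulation placements.
#' @return A pristine [phylo_network()], leaves labelled `t1, t2, ...`.
#' @examples
#' N <- generate_tree_child(6, 2, seed = 7)
#' length(internal_tree_nodes(N))  # 6 + 2 - 1 = 7
#' @export
generate_tree_child <- function(num_leaves, num_reticulations = 0L, seed = 1L,
                                max_rejections = 100L) {
  check_generator_args(num_leaves, num_reticulations, tree_child = TRUE)
  with_local_seed(seed, {
    finish_network(grow_with_retries(num_leaves, num_reticulations,
                                     tree_child = TRUE,
                                     max_rejections = max_rejections))
  })
}

#' Generate a random orchard network (tree-child not enforced)
#'
#' Same growth process as [generate_tree_child()] but without the tree-child
#' rejection rule, so the new reticulation may be placed next to an existing
#' one.  The result is always a pristine binary orchard network (growth
#' inverts a reduction sequence) but need not be tree-child — the regime in
#' which the sequence/extension correspondence is injective only.
#'
#' @inheritParams generate_tree_child
#' @return A pristine [phylo_network()].
#' @export
generate_orchard <- function(num_leaves, num_reticulations = 0L, seed = 1L,
                             max_rejections = 100L) {
  check_generator_args(num_leaves, num_reticulations, tree_child = FALSE)
  with_local_seed(seed, {
    finish_network(grow_with_retries(num_leaves, num_reticulations,
                                     tree_child = FALSE,
                                     max_rejections = max_rejections))
  })
}

check_generator_args <- function(num_leaves, num_reticulations, tree_child) {
  if (num_leaves < 1L) stop_input("generate: num_leaves must be at least 1")
  if (num_reticulations < 0L) stop_input("generate: num_reticulations must be >= 0")
  if (num_reticulations > 0L && num_leaves < 2L) {
    stop_input("generate: reticulations require at least 2 leaves")
  }
  if (tree_child && num_reticulations > num_leaves - 1L) {
    # a tree-child network on L leaves has at most L - 1 reticulations
    stop_input(paste0("generate: a tree-child network with ", num_leaves,
                      " leaves has at most ", num_leaves - 1L, " reticulations"))
  }
}

# ---- minors ---------------------------------------------------------------

#' Minor specification
#'
#' A minor of (the underlying undirected graph of) a network is described by
#' a partition of a node subset into named classes, each inducing a
#' connected subgraph, together with the class pairs declared adjacent.
#'
#' @param classes Named list: class name -> vector of node names/identifiers.
#' @param declared_edges Two-column matrix of class-name pairs (undirected).
#' @return An object of class `minor_spec`.
#' @export
minor_spec <- function(classes, declared_edges) {
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    stop_input("minor_spec: classes must be named")
  }
  if (is.data.frame(declared_edges)) declared_edges <- as.matrix(declared_edges)
  structure(list(classes = classes, declared_edges = declared_edges),
            class = "minor_spec")
}

#' Verify a declared minor
#'
#' Checks that the classes are pairwise disjoint subsets of the network's
#' nodes, that each class induces a connected subgraph of the underlying
#' undirected graph, that every declared class edge is witnessed by a
#' network edge between the two classes, and that the quotient's edge set
#' equals the target graph's edge set (as unordered class pairs).
#'
#' @param N A [phylo_network()].
#' @param spec A [minor_spec()].
#' @param target Two-column matrix of class-name pairs: the abstract graph
#'   the quotient must equal (e.g. `complete_graph_edges()` for a clique).
#' @return A list with `ok` (logical) and `failures` (character vector).
#' @export
verify_minor <- function(N, spec, target) {
  failures <- character(0)
  class_ids <- lapply(spec$classes, function(v) resolve_node(N, v, several.ok = TRUE))
  allv <- unlist(class_ids)
  if (anyDuplicated(allv)) failures <- c(failures, "classes are not pairwise disjoint")

  g <- as_igraph(N, directed = FALSE)
  for (cn in names(class_ids)) {
    sub <- igraph::induced_subgraph(g, as.character(class_ids[[cn]]))
    if (!igraph::is_connected(sub)) {
      failures <- c(failures, sprintf("class %s does not induce a connected subgraph", cn))
    }
  }

  whom <- rep(NA_character_, length(N$nodes))
  names(whom) <- as.character(N$nodes)
  for (cn in names(class_ids)) whom[as.character(class_ids[[cn]])] <- cn

  ep <- whom[as.character(N$edges[, "parent"])]
  ec <- whom[as.character(N$edges[, "child"])]
  between <- !is.na(ep) & !is.na(ec) & ep != ec
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  quotient_edges <- unique(canon(ep[between], ec[between]))

  declared <- unique(canon(as.character(spec$declared_edges[, 1L]),
                           as.character(spec$declared_edges[, 2L])))
  missing_witness <- setdiff(declared, quotient_edges)
  if (length(missing_witness) > 0L) {
    failures <- c(failures, sprintf("declared edge %s has no witnessing network edge",
                                    missing_witness))
  }

  if (is.data.frame(target)) target <- as.matrix(target)
  target_edges <- unique(canon(as.character(target[, 1L]), as.character(target[, 2L])))
  extra <- setdiff(quotient_edges, target_edges)
  absent <- setdiff(target_edges, quotient_edges)
  if (length(extra) > 0L) {
    failures <- c(failures, sprintf("quotient has edge %s not in the target", extra))
  }
  if (length(absent) > 0L) {
    failures <- c(failures, sprintf("target edge %s is missing from the quotient", absent))
  }
  list(ok = length(failures) == 0L, failures = failures)
}

#' Edge list of a complete graph on the given class names
#'
#' @param names Character vector of class names.
#' @return Two-column matrix with one row per unordered pair.
#' @export
complete_graph_edges <- function(names) {
  t(utils::combn(names, 2L))
}

#' Clique-minor tree-child network family
#'
#' Explicitly constructs, for each `n >= 3`, a pristine binary tree-child
#' network consisting of a single blob with `(n-1)(n-2)/2` reticulations
#' (hence level `(n-1)(n-2)/2`) whose underlying graph has a minor
#' isomorphic to the clique `K_n` — witnessing that tree-child networks
#' have unbounded tree-width (a `K_n` minor forces tree-width at least
#' `n - 1`), with level quadratic in the clique size.  The minor contracts
#' `n` pairwise disjoint directed paths, returned as the classes
#' `z_1, ..., z_n` of the accompanying [minor_spec()]; the pendant leaves
#' `x_ij` are left out of all classes.
#'
#' @param n Clique size, at least 3.
#' @return List with `network` (a [phylo_network()]) and `spec` (a
#'   [minor_spec()] whose quotient is `K_n`).
#' @export
build_clique_minor_network <- function(n) {
  if (n < 3L) stop_input("build_clique_minor_network: n must be at least 3")
  u <- function(i, j) sprintf("u_%d_%d", i, j)
  h <- function(i, j) sprintf("h_%d_%d", i, j)
  v <- function(i, j) sprintf("v_%d_%d", i, j)
  x <- function(i, j) sprintf("x_%d_%d", i, j)
  z <- function(j) sprintf("z_%d", j)

  E <- list()
  add <- function(a, b) E[[length(E) + 1L]] <<- c(a, b)

  for (j in 1:2) {
    for (l in seq_len(n)) if (l > j && l < n) add(u(j, l), u(j, l + 1L))
    add(u(j, n), z(j))
  }
  # the root's edge to the second path (used by the quotient but absent from
  # the per-path edge sets as printed; without it u_12 would have out-degree 1)
  add(u(1L, 2L), u(2L, 3L))
  if (n >= 4L) {
    for (j in 3:(n - 1L)) {
      if (j >= 4L) for (i in 2:(j - 2L)) {
        add(h(i, j), v(i, j)); add(v(i, j), x(i, j)); add(v(i, j), h(i + 1L, j))
      }
      add(h(j - 1L, j), u(j, j + 1L))
      for (l in seq_len(n)) if (l > j && l < n) add(u(j, l), u(j, l + 1L))
      add(u(j, n), z(j))
    }
  }
  if (n >= 4L) for (i in 2:(n - 2L)) {
    add(h(i, n), v(i, n)); add(v(i, n), x(i, n)); add(v(i, n), h(i + 1L, n))
  }
  add(h(n - 1L, n), z(n))
  for (j in 3:n) {
    add(u(1L, j), h(2L, j))
    for (i in 2:(j - 1L)) add(u(i, j), h(i, j))
  }

  N <- phylo_network(do.call(rbind, E))

  classes <- list()
  classes[[z(1L)]] <- c(vapply(2:n, function(j) u(1L, j), character(1)), z(1L))
  classes[[z(2L)]] <- c(if (n >= 3L) vapply(3:n, function(l) u(2L, l), character(1)),
                        z(2L))
  if (n >= 4L) {
    for (j in 3:(n - 1L)) {
      path <- character(0)
      for (i in 2:(j - 1L)) {
        path <- c(path, h(i, j))
        if (i <= j - 2L) path <- c(path, v(i, j))
      }
      path <- c(path, vapply((j + 1L):n, function(l) u(j, l), character(1)), z(j))
      classes[[z(j)]] <- path
    }
  }
  last <- character(0)
  for (i in 2:(n - 1L)) {
    last <- c(last, h(i, n))
    if (i <= n - 2L) last <- c(last, v(i, n))
  }
  classes[[z(n)]] <- c(last, z(n))

  spec <- minor_spec(classes, complete_graph_edges(names(classes)))
  list(network = N, spec = spec)
}

# ---- level lower bounds ---------------------------------------------------

#' Level lower bound from a biconnected minor
#'
#' If the underlying graph of a network has a biconnected minor with `v`
#' nodes and `e` edges, the network's level is at least `e - v + 1`
#' (clamped at 0).
#'
#' @param num_nodes,num_edges Node and edge counts of the minor.
#' @return Non-negative integer.
#' @export
level_lower_bound_from_minor <- function(num_nodes, num_edges) {
  if (num_nodes < 0 || num_edges < 0) {
    stop_input("level_lower_bound_from_minor: counts must be non-negative")
  }
  max(0L, as.integer(num_edges) - as.integer(num_nodes) + 1L)
}

#' Level lower bounds from clique and grid/biclique minors
#'
#' A `K_n` minor forces level at least `(n-1)(n-2)/2` (and tree-width at
#' least `n - 1`); an `n x m` grid or complete bipartite minor forces level
#' at least `(n-1)(m-1)`.
#'
#' @param n,m Minor dimensions (at least 1).
#' @return Non-negative integer.
#' @export
clique_level_bound <- function(n) {
  if (n < 1L) stop_input("clique_level_bound: n must be at least 1")
  as.integer((n - 1L) * (n - 2L) / 2L)
}

#' @rdname clique_level_bound
#' @export
grid_level_bound <- function(n, m) {
  if (n < 1L || m < 1L) stop_input("grid_level_bound: n and m must be at least 1")
  as.integer((n - 1L) * (m - 1L))
}

# ---- per-class reticulation check ----------------------------------------

#' Orientation of a minor induced by the network
#'
#' For each declared class edge, picks a direction witnessed by a directed
#' network edge between the two classes (the first witness in edge order).
#'
#' @param N A [phylo_network()].
#' @param spec A [minor_spec()].
#' @return Two-column matrix of class names `(from, to)`.
#' @export
induce_orientation <- function(N, spec) {
  whom <- rep(NA_character_, length(N$nodes))
  names(whom) <- as.character(N$nodes)
  for (cn in names(spec$classes)) {
    whom[as.character(resolve_node(N, spec$classes[[cn]], several.ok = TRUE))] <- cn
  }
  ep <- whom[as.character(N$edges[, "parent"])]
  ec <- whom[as.character(N$edges[, "child"])]
  out <- NULL
  for (k in seq_len(nrow(spec$declared_edges))) {
    a <- spec$declared_edges[k, 1L]; b <- spec$declared_edges[k, 2L]
    fwd <- which(ep == a & ec == b)
    bwd <- which(ep == b & ec == a)
    if (length(fwd) == 0L && length(bwd) == 0L) {
      stop_domain(sprintf("induce_orientation: class edge %s~%s has no witness", a, b))
    }
    out <- rbind(out, if (length(fwd) > 0L) c(a, b) else c(b, a))
  }
  colnames(out) <- c("from", "to")
  out
}

#' Per-class reticulation count check
#'
#' For a minor with an orientation induced by the network, every class with
#' oriented in-degree `d >= 1` must contain at least `d - 1` reticulations
#' of the network.  This always holds for valid inputs; the per-class report
#' is the structural self-check behind the level lower bound.
#'
#' @param N A [phylo_network()].
#' @param spec A [minor_spec()].
#' @param orientation Two-column matrix of class names `(from, to)`; each
#'   directed class edge must be witnessed by a correspondingly directed
#'   network edge.
#' @return Data frame with columns `class`, `indegree`, `reticulations`,
#'   `satisfied`.
#' @export
check_reticulations_per_class <- function(N, spec, orientation) {
  whom <- rep(NA_character_, length(N$nodes))
  names(whom) <- as.character(N$nodes)
  for (cn in names(spec$classes)) {
    whom[as.character(resolve_node(N, spec$classes[[cn]], several.ok = TRUE))] <- cn
  }
  ep <- whom[as.character(N$edges[, "parent"])]
  ec <- whom[as.character(N$edges[, "child"])]
  for (k in seq_len(nrow(orientation))) {
    a <- orientation[k, 1L]; b <- orientation[k, 2L]
    if (!any(ep == a & ec == b, na.rm = TRUE)) {
      stop_domain(sprintf(
        "check_reticulations_per_class: directed class edge %s->%s is not witnessed by any network edge",
        a, b))
    }
  }
  rets <- reticulation_nodes(N)
  cls <- names(spec$classes)
  indeg <- vapply(cls, function(cn) sum(orientation[, 2L] == cn), integer(1))
  nret <- vapply(cls, function(cn) {
    sum(resolve_node(N, spec$classes[[cn]], several.ok = TRUE) %in% rets)
  }, integer(1))
  data.frame(class = cls, indegree = indeg, reticulations = nret,
             satisfied = nret >= pmax(indeg - 1L, 0L), row.names = NULL)
}
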