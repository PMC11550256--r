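# Cherry reductions.  A terminal node is an internal tree node rooting a
# cherry (both children leaves) or a reticulated cherry (one child a leaf,
# the other a reticulation whose single child is a leaf).  Reducing a
# terminal node u deletes every edge below u and every strict descendant of
# u that is currently a tree node; reticulation descendants are kept and
# become leaves, and u itself becomes a leaf.  All roles are re-evaluated on
# current degrees at every step.

network_digest <- function(N) {
  paste(c(nrow(N$edges), length(N$nodes), N$root,
          paste(N$edges[, 1L], N$edges[, 2L], sep = ">"),
          paste(names(N$leaf_labels), N$leaf_labels, sep = "=")),
        collapse = "|")
}

new_cr_sequence <- function(N, nodes) {
  structure(list(reduced_nodes = as.integer(nodes),
                 network_ref = network_digest(N)),
            class = "cr_sequence")
}

#' @export
print.cr_sequence <- function(x, ...) {
  cat("cherry reduction sequence:",
      paste(x$reduced_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Terminal nodes of a network
#'
#' Returns every internal tree node that roots a cherry or a reticulated
#' cherry, with its kind.  For a tree-child network this set coincides with
#' the maximal elements of the reachability poset on the internal tree nodes
#' (a property tested extensively in this package); for general orchard
#' networks a maximal internal tree node need not be terminal.
#'
#' @param N A [phylo_network()] (pristine or reduced).
#' @return Named character vector: names are node identifiers (ascending),
#'   values `"cherry"` or `"reticulated_cherry"`.
#' @export
terminal_nodes <- function(N) {
  indeg <- in_degrees(N)
  outdeg <- out_degrees(N)
  out <- character(0)
  for (u in internal_tree_nodes(N)) {
    ch <- node_children(N, u)
    if (length(ch) != 2L) next
    leafish <- outdeg[as.character(ch)] == 0L
    if (all(leafish)) {
      out[as.character(u)] <- "cherry"
    } else if (sum(leafish) == 1L) {
      h <- ch[!leafish]
      if (indeg[as.character(h)] >= 2L && outdeg[as.character(h)] == 1L) {
        hc <- node_children(N, h)
        if (outdeg[as.character(hc)] == 0L) {
          out[as.character(u)] <- "reticulated_cherry"
        }
      }
    }
  }
  out[order(as.integer(names(out)))]
}

#' Cherry reduction
#'
#' Reduces the terminal node `u`: removes every edge on a path below `u`
#' (i.e. every edge whose tail descends from `u`) and every strict
#' descendant of `u` that is currently a tree node.  Reticulation
#' descendants are kept; having lost their outgoing edge (and any incoming
#' edge from below `u`) they become new, unlabelled leaves, as does `u`
#' itself.  Node identifiers are unchanged: the result is a literal
#' subnetwork, valid in `"reduced"` mode, and tree-child whenever the input
#' was.
#'
#' @param N A [phylo_network()].
#' @param u A terminal node of `N` (identifier or name).
#' @return A [phylo_network()].
#' @export
cherry_reduce <- function(N, u) {
  u <- resolve_node(N, u)
  term <- terminal_nodes(N)
  if (!(as.character(u) %in% names(term))) {
    stop_domain(sprintf(paste0(
      "cherry_reduce: node %s is not terminal (it roots neither a cherry ",
      "- both children leaves - nor a reticulated cherry - one child a leaf, ",
      "the other a reticulation whose single child is a leaf)"),
      N$node_names[as.character(u)]))
  }
  desc <- reachable_from(N, u)
  strict_desc <- setdiff(desc, u)
  indeg <- in_degrees(N)
  drop_nodes <- strict_desc[indeg[as.character(strict_desc)] <= 1L]

  N2 <- N
  keep_edge <- !(N$edges[, "parent"] %in% desc)
  N2$edges <- N$edges[keep_edge, , drop = FALSE]
  keep_nodes <- setdiff(N$nodes, drop_nodes)
  N2 <- subnetwork(N2, keep_nodes)
  N2
}

#' Orchard recognition
#'
#' A network is orchard when iterated cherry reductions take it down to a
#' single node.  Because any two complete reduction sequences of an orchard
#' network have the same length, a greedy strategy (reduce any terminal
#' node, here always the one of smallest identifier) suffices: getting stuck
#' with more than one node proves no sequence exists.
#'
#' @param N A pristine [phylo_network()].
#' @return `TRUE` or `FALSE`.
#' @export
is_orchard <- function(N) {
  repeat {
    if (length(N$nodes) == 1L) return(TRUE)
    term <- terminal_nodes(N)
    if (length(term) == 0L) return(FALSE)
    N <- cherry_reduce(N, as.integer(names(term)[1L]))
  }
}

#' Enumerate all cherry reduction sequences
#'
#' Depth-first enumeration over every terminal choice at every step
#' (children tried in ascending identifier order, so the result is
#' reproducible).  Every complete sequence has length `|T(N-ring)|`; the
#' list is empty iff the network is not orchard (and has more than one
#' node).  This is the brute-force oracle against which the
#' linear-extension counting route is verified.
#'
#' @param N A [phylo_network()].
#' @param guard Maximum allowed `|T(N-ring)|` (default 10); beyond it the
#'   number of sequences can reach `guard!` and [count_cherry_sequences()]
#'   should be used instead.
#' @return List of `cr_sequence` objects.
#' @export
enumerate_cr_sequences <- function(N, guard = 10L) {
  p <- length(internal_tree_nodes(N))
  if (p > guard) {
    stop_guard(sprintf(paste0(
      "enumerate_cr_sequences: %d internal tree nodes exceeds the guard (%d); ",
      "use count_cherry_sequences() to count without enumerating"), p, guard))
  }
  recurse <- function(net, acc) {
    if (length(net$nodes) == 1L) return(list(acc))
    term <- as.integer(names(terminal_nodes(net)))
    if (length(term) == 0L) return(list())
    out <- list()
    for (u in term) {
      out <- c(out, recurse(cherry_reduce(net, u), c(acc, u)))
    }
    out
  }
  lapply(recurse(N, integer(0)), function(s) new_cr_sequence(N, s))
}

replay_sequence <- function(N, nodes) {
  # applies the reductions in order, erroring at the first failing step
  for (i in seq_along(nodes)) {
    ok <- tryCatch({N <- cherry_reduce(N, nodes[i]); TRUE},
                   cherrycount_error = function(e) e)
    if (!isTRUE(ok)) {
      stop_domain(sprintf("replay error at step %d (node %s): %s",
                          i, nodes[i], conditionMessage(ok)))
    }
  }
  N
}

#' From a reduction sequence to a linear extension
#'
#' The order in which internal tree nodes are reduced is a linear extension
#' of the *dual* of the reachability poset on `T(N-ring)` (terminal nodes
#' are maximal, but they are reduced first); reversing it therefore yields a
#' linear extension of the poset itself.  The sequence is validated by
#' replay before reversal.
#'
#' @param N The starting [phylo_network()].
#' @param S A `cr_sequence` (or a plain vector of node identifiers).
#' @return Integer vector: the reversed reduction order, a linear extension
#'   of the reachability poset on the internal tree nodes.
#' @export
crseq_to_linext <- function(N, S) {
  nodes <- if (inherits(S, "cr_sequence")) S$reduced_nodes else as.integer(S)
  final <- replay_sequence(N, nodes)
  if (length(final$nodes) != 1L) {
    stop_domain("crseq_to_linext: sequence is not complete (network not fully reduced)")
  }
  rev(nodes)
}

#' From a dual linear extension to a reduction sequence
#'
#' Given a tree-child network and a linear extension `pi` of the order-dual
#' of the reachability poset on `T(N-ring)` (i.e. a candidate reduction
#' order: no listed node may reach a node listed after it), replays the
#' reductions in order `pi` and returns the resulting complete sequence.
#' That the replay always succeeds for tree-child networks is exactly the
#' surjectivity half of the sequence/extension bijection; for non-tree-child
#' orchard networks a maximal internal tree node may start no sequence, and
#' the function refuses such inputs.
#'
#' @param N A pristine tree-child [phylo_network()].
#' @param pi Permutation of the internal tree nodes (identifiers or names).
#' @return A `cr_sequence` with `reduced_nodes` equal to `pi`.
#' @export
linext_to_crseq <- function(N, pi) {
  if (!is_tree_child(N)) {
    stop_domain(paste0("linext_to_crseq: network is not tree-child; for general ",
                       "orchard networks a maximal internal tree node need not ",
                       "begin any reduction sequence"))
  }
  ids <- resolve_node(N, pi, several.ok = TRUE)
  tn <- internal_tree_nodes(N)
  if (length(ids) != length(tn) || !setequal(ids, tn)) {
    stop_input("linext_to_crseq: pi must be a permutation of the internal tree nodes")
  }
  P <- reachability_poset(N, tn)
  s <- strict_matrix(P)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && s[as.character(ids[i]), as.character(ids[j])]) {
        stop_order(sprintf(paste0(
          "linext_to_crseq: pi is not a linear extension of the dual order: ",
          "%s precedes %s in pi but is an ancestor of it"),
          N$node_names[as.character(ids[i])], N$node_names[as.character(ids[j])]))
      }
    }
  }
  replay_sequence(N, ids)
  new_cr_sequence(N, ids)
}
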