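# Shared fixtures and small generators, all built in code.

# minimal reticulated network: rho -> {u1, u2}; u1 -> {l1, h}; u2 -> {l2, h};
# h -> l3 (one reticulation, level 1)
minimal_reticulated <- function() {
  phylo_network(rbind(
    c("rho", "u1"), c("rho", "u2"),
    c("u1", "l1"), c("u1", "h"),
    c("u2", "l2"), c("u2", "h"),
    c("h", "l3")
  ))
}

balanced_tree4 <- function() read_network("((a,b)u,(c,d)v)r;")

cherry_network <- function() phylo_network(rbind(c("r", "a"), c("r", "b")))

single_node_network <- function() phylo_network(nodes = "star")

# smallest stuck network: both children of each internal tree node are
# reticulations, so no cherry and no reticulated cherry ever exists
non_orchard_network <- function() {
  phylo_network(rbind(
    c("rho", "u1"), c("rho", "u2"),
    c("u1", "h1"), c("u1", "h2"),
    c("u2", "h1"), c("u2", "h2"),
    c("h1", "x"), c("h2", "y")
  ))
}

node_by_name <- function(N, nm) unname(N$nodes[match(nm, N$node_names)])

names_of <- function(N, ids) unname(N$node_names[as.character(ids)])

# random poset on n elements via a random DAG, closed transitively
random_poset <- function(n, seed, p = 0.3) {
  withr::with_seed(seed, {
    elems <- seq_len(n)
    rel <- NULL
    if (n >= 2) {
      ord <- sample(elems)
      for (i in seq_len(n - 1)) {
        for (j in seq((i + 1), n)) {
          if (runif(1) < p) rel <- rbind(rel, c(ord[i], ord[j]))
        }
      }
    }
    poset(elems, rel)
  })
}

# random forest poset: each element after the first attaches below an earlier
# one with probability `attach`, otherwise starts a new tree
random_forest_poset <- function(n, seed, attach = 0.85) {
  withr::with_seed(seed, {
    rel <- NULL
    for (i in seq_len(n)[-1]) {
      if (runif(1) < attach) rel <- rbind(rel, c(sample(i - 1, 1), i))
    }
    poset(seq_len(n), rel)
  })
}

# terminal nodes must equal the maximal elements of the reachability poset at
# every step of a complete reduction sequence (tree-child networks)
expect_terminals_maximal_along <- function(N, S) {
  nodes <- if (inherits(S, "cr_sequence")) S$reduced_nodes else S
  for (u in nodes) {
    tn <- internal_tree_nodes(N)
    P <- reachability_poset(N, tn)
    expect_identical(sort(as.integer(names(terminal_nodes(N)))),
                     sort(as.integer(maximal_elements(P))))
    N <- cherry_reduce(N, u)
  }
  invisible(N)
}
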