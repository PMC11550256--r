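# Posets, duals, reachability, and the two cover-graph constructions.

test_that("poset closure, antisymmetry and extremal elements", {
  P <- poset(letters[1:4], rbind(c("a", "b"), c("b", "c")))
  expect_true(P$leq["a", "c"])  # transitivity
  expect_true(all(diag(P$leq)))  # reflexivity
  expect_setequal(maximal_elements(P), c("c", "d"))
  expect_setequal(minimal_elements(P), c("a", "d"))
  expect_error(poset(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
               class = "cherrycount_input_error")
})

test_that("dualize flips the order and is an involution", {
  expect_identical(dualize(poset(1:3))$leq, poset(1:3)$leq)  # antichain
  ch <- poset(1:3, rbind(c(1, 2), c(2, 3)))
  expect_setequal(maximal_elements(dualize(ch)), 1)
  for (s in 1:20) {
    P <- random_poset(5, seed = s)
    expect_identical(dualize(dualize(P))$leq, P$leq)
  }
})

test_that("reachability poset on standard subsets", {
  tr <- balanced_tree4()
  leaves <- network_leaves(tr)
  expect_length(maximal_elements(reachability_poset(tr, leaves)), length(leaves))

  fx <- minimal_reticulated()
  P <- reachability_poset(fx)
  rho <- node_by_name(fx, "rho"); u1 <- node_by_name(fx, "u1"); u2 <- node_by_name(fx, "u2")
  expect_setequal(P$elements, c(rho, u1, u2))
  expect_true(P$leq[as.character(rho), as.character(u1)])
  expect_true(P$leq[as.character(rho), as.character(u2)])
  expect_false(P$leq[as.character(u1), as.character(u2)])
  expect_false(P$leq[as.character(u2), as.character(u1)])

  # a directed path restricted to all nodes is a total order
  path <- phylo_network(rbind(c("a", "b"), c("b", "c")))
  expect_identical(sum(reachability_poset(path, path$nodes)$leq), 6L)
})

test_that("cover graph by transitive reduction (oracle)", {
  tot <- poset(1:4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_identical(nrow(cover_graph(tot)$edges), 3L)
  expect_identical(nrow(cover_graph(poset(1:4))$edges), 0L)
  diamond <- poset(letters[1:4], rbind(c("a", "b"), c("a", "c"), c("b", "d"),
                                       c("c", "d"), c("a", "d")))
  cg <- cover_graph(diamond)
  expect_identical(nrow(cg$edges), 4L)  # the implied a->d edge is gone
  expect_false(any(cg$edges[, 1] == "a" & cg$edges[, 2] == "d"))
})

test_that("internal tree nodes on the standard fixtures", {
  expect_identical(internal_tree_nodes(cherry_network()),
                   node_by_name(cherry_network(), "r"))
  fx <- minimal_reticulated()
  expect_setequal(names_of(fx, internal_tree_nodes(fx)), c("rho", "u1", "u2"))
  tr <- balanced_tree4()
  expect_setequal(names_of(tr, internal_tree_nodes(tr)), c("r", "u", "v"))
})

test_that("contraction construction on hand-checked fixtures", {
  # a tree: cover graph is its internal-node tree, no contractions
  tr <- balanced_tree4()
  ccg <- contracted_cover_graph(tr)
  expect_identical(nrow(ccg$cover$edges), 2L)
  expect_true(all(ccg$quot[as.character(network_leaves(tr))] == -1L))

  # minimal fixture: h's child is a leaf, so h is discarded
  fx <- minimal_reticulated()
  ccg <- contracted_cover_graph(fx)
  expect_setequal(names_of(fx, ccg$cover$nodes), c("rho", "u1", "u2"))
  expect_identical(ccg$quot[[as.character(node_by_name(fx, "h"))]], -1L)
  got <- cbind(names_of(fx, ccg$cover$edges[, 1]), names_of(fx, ccg$cover$edges[, 2]))
  expect_setequal(paste(got[, 1], got[, 2]), c("rho u1", "rho u2"))

  # a reticulation with an internal child is contracted into it
  N <- phylo_network(rbind(
    c("rho", "u1"), c("rho", "u2"), c("u1", "a"), c("u1", "h"),
    c("u2", "h"), c("u2", "b"), c("h", "w"), c("w", "c"), c("w", "d")
  ))
  expect_length(validate_network(N, "pristine"), 0)
  ccg <- contracted_cover_graph(N)
  h <- reticulation_nodes(N)
  expect_identical(unname(ccg$quot[as.character(h)]),
                   unname(ccg$quot[as.character(node_by_name(N, "w"))]))
  oracle <- cover_graph(reachability_poset(N))
  expect_identical(ccg$cover$edges, oracle$edges)

  expect_error(contracted_cover_graph(non_orchard_network()),
               class = "cherrycount_domain_error")
})

test_that("contraction equals the transitive-reduction oracle on random networks", {
  for (s in 1:40) {
    L <- 4 + s %% 4
    r <- min(s %% 4, L - 1)
    N <- generate_tree_child(L, r, seed = 400 + s)
    ccg <- contracted_cover_graph(N)
    oracle <- cover_graph(reachability_poset(N))
    expect_identical(ccg$cover$nodes, oracle$nodes)
    expect_identical(ccg$cover$edges, oracle$edges)

    # quotient classes have size 1 or 2; 2-classes pair a reticulation with
    # its internal tree child, joined by a network edge (minor property)
    q <- ccg$quot[ccg$quot > 0]
    sizes <- table(q)
    expect_true(all(sizes <= 2))
    rets <- reticulation_nodes(N)
    for (idx in names(sizes[sizes == 2])) {
      members <- as.integer(names(q)[q == as.integer(idx)])
      hmem <- members[members %in% rets]
      expect_length(hmem, 1)
      tmem <- setdiff(members, hmem)
      expect_true(any(N$edges[, 1] == hmem & N$edges[, 2] == tmem))
    }
  }
})

test_that("node_children of reticulations are unique in tree-child networks", {
  # (sanity for the contraction: every reticulation has out-degree 1)
  N <- generate_tree_child(6, 3, seed = 11)
  for (h in reticulation_nodes(N)) {
    expect_length(cherrycount:::node_children(N, h), 1)
  }
})
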