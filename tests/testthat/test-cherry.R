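# Terminal nodes, cherry reductions, orchard recognition, enumeration, and
# the sequence <-> linear-extension correspondence maps.

test_that("terminal node detection distinguishes the two kinds", {
  ch <- cherry_network()
  expect_identical(unname(terminal_nodes(ch)), "cherry")

  fx <- minimal_reticulated()
  tn <- terminal_nodes(fx)
  expect_setequal(names_of(fx, as.integer(names(tn))), c("u1", "u2"))
  expect_identical(unname(tn), rep("reticulated_cherry", 2))

  tr <- balanced_tree4()
  tn <- terminal_nodes(tr)
  expect_setequal(names_of(tr, as.integer(names(tn))), c("u", "v"))
  expect_identical(unname(tn), rep("cherry", 2))

  expect_length(terminal_nodes(non_orchard_network()), 0)
})

test_that("cherry reduction of a plain cherry removes the two leaves", {
  N <- read_network("((a,b)u,c)r;")
  red <- cherry_reduce(N, node_by_name(N, "u"))
  expect_length(red$nodes, 3)
  expect_setequal(names_of(red, network_leaves(red)), c("u", "c"))
  expect_length(validate_network(red, "reduced"), 0)
})

test_that("reticulated-cherry reduction turns the reticulation into a leaf", {
  fx <- minimal_reticulated()
  red <- cherry_reduce(fx, "u1")
  # l1 and l3 removed; u1 and h are now leaves; u2 untouched
  expect_setequal(names_of(red, red$nodes), c("rho", "u1", "u2", "h", "l2"))
  expect_setequal(names_of(red, network_leaves(red)), c("u1", "h", "l2"))
  expect_identical(classify_node(red, "h"), "leaf")
  # node identifiers are preserved (literal subnetwork)
  expect_true(all(red$nodes %in% fx$nodes))
  expect_true(all(paste(red$edges[, 1], red$edges[, 2]) %in%
                    paste(fx$edges[, 1], fx$edges[, 2])))
})

test_that("reducing a non-terminal node errors", {
  fx <- minimal_reticulated()
  expect_error(cherry_reduce(fx, "rho"), class = "cherrycount_domain_error")
  expect_error(cherry_reduce(fx, "h"), class = "cherrycount_domain_error")
})

test_that("orchard recognition", {
  expect_true(is_orchard(balanced_tree4()))
  expect_true(is_orchard(minimal_reticulated()))
  expect_false(is_orchard(non_orchard_network()))
  for (s in 1:10) expect_true(is_orchard(generate_tree_child(5, 2, seed = s)))
})

test_that("enumeration returns every complete sequence exactly once", {
  expect_length(enumerate_cr_sequences(single_node_network()), 1)
  expect_length(enumerate_cr_sequences(single_node_network())[[1]]$reduced_nodes, 0)

  tr <- balanced_tree4()
  seqs <- enumerate_cr_sequences(tr)
  expect_length(seqs, 2)
  got <- lapply(seqs, function(s) names_of(tr, s$reduced_nodes))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  c("u,v,r", "v,u,r"))

  fx <- minimal_reticulated()
  seqs <- enumerate_cr_sequences(fx)
  expect_setequal(
    vapply(seqs, function(s) paste(names_of(fx, s$reduced_nodes), collapse = ","), ""),
    c("u1,u2,rho", "u2,u1,rho"))

  expect_length(enumerate_cr_sequences(non_orchard_network()), 0)
  expect_error(enumerate_cr_sequences(generate_tree_child(13, 0, seed = 1)),
               class = "cherrycount_guard_error")
})

test_that("after each reduction the internal tree nodes shrink by exactly {u}", {
  for (s in 1:15) {
    N <- generate_tree_child(4 + s %% 4, min(2, s %% 3), seed = 100 + s)
    for (S in enumerate_cr_sequences(N)[1]) {
      net <- N
      for (u in S$reduced_nodes) {
        before <- internal_tree_nodes(net)
        net <- cherry_reduce(net, u)
        expect_setequal(internal_tree_nodes(net), setdiff(before, u))
        expect_true(u %in% network_leaves(net))
        expect_length(validate_network(net, "reduced"), 0)
      }
    }
  }
})

test_that("all complete sequences of an orchard network have length |T(N-ring)|", {
  for (s in 1:10) {
    N <- generate_orchard(5, 2, seed = 200 + s)
    p <- length(internal_tree_nodes(N))
    for (S in enumerate_cr_sequences(N)) {
      expect_length(S$reduced_nodes, p)
    }
  }
})

test_that("tree-child property is preserved along every reduction step", {
  for (s in 1:10) {
    N <- generate_tree_child(5, 2, seed = 300 + s)
    S <- enumerate_cr_sequences(N)[[1]]
    net <- N
    for (u in S$reduced_nodes) {
      net <- cherry_reduce(net, u)
      expect_true(is_tree_child(net))
    }
  }
})

test_that("crseq_to_linext reverses a validated sequence", {
  fx <- minimal_reticulated()
  S <- enumerate_cr_sequences(fx)[[1]]
  ext <- crseq_to_linext(fx, S)
  expect_identical(ext, rev(S$reduced_nodes))
  # the result is a linear extension of the reachability poset
  P <- reachability_poset(fx)
  s <- cherrycount:::strict_matrix(P)
  for (i in seq_along(ext)) for (j in seq_along(ext)) {
    if (i > j) expect_false(s[as.character(ext[i]), as.character(ext[j])])
  }
  expect_error(crseq_to_linext(fx, c(node_by_name(fx, "rho"))),
               class = "cherrycount_domain_error")
})

test_that("linext_to_crseq replays a dual extension and round-trips", {
  fx <- minimal_reticulated()
  for (S in enumerate_cr_sequences(fx)) {
    back <- linext_to_crseq(fx, rev(crseq_to_linext(fx, S)))
    expect_identical(back$reduced_nodes, S$reduced_nodes)
  }
  # the root is an ancestor of everything, so it cannot come first
  ids <- c(node_by_name(fx, "rho"), node_by_name(fx, "u1"), node_by_name(fx, "u2"))
  expect_error(linext_to_crseq(fx, ids), class = "cherrycount_order_error")
  # non-tree-child networks are refused
  expect_error(linext_to_crseq(non_orchard_network(),
                               internal_tree_nodes(non_orchard_network())),
               class = "cherrycount_domain_error")
})
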