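# Exact linear-extension counting: oracle equivalences, closed forms, laws.

test_that("brute-force oracle on pencil-and-paper cases", {
  expect_identical(as.character(count_linext_bruteforce(poset(integer(0)))), "1")
  expect_identical(as.double(count_linext_bruteforce(poset(1:3))), 6)  # 3!
  P <- poset(letters[1:4], rbind(c("a", "c"), c("b", "c"), c("b", "d")))
  expect_identical(as.double(count_linext_bruteforce(P)), 5)
  expect_error(count_linext_bruteforce(random_poset(9, 1)),
               class = "cherrycount_guard_error")
})

test_that("downset DP on degenerate shapes and the shared example", {
  chain5 <- poset(1:5, cbind(1:4, 2:5))
  expect_identical(as.double(count_linext_downset_dp(chain5)), 1)
  expect_identical(as.double(count_linext_downset_dp(poset(1:4))), 24)
  P <- poset(letters[1:4], rbind(c("a", "c"), c("b", "c"), c("b", "d")))
  expect_identical(as.double(count_linext_downset_dp(P)), 5)
  expect_error(count_linext_downset_dp(poset(1:5), cap = 4L),
               class = "cherrycount_guard_error")
})

test_that("DP agrees with brute force on random posets", {
  for (s in 1:120) {
    P <- random_poset(3 + s %% 5, seed = s, p = 0.15 + (s %% 7) / 10)
    expect_true(count_linext_downset_dp(P) == count_linext_bruteforce(P))
  }
})

test_that("component decomposition obeys the multinomial law", {
  two_chains <- poset(1:4, rbind(c(1, 2), c(3, 4)))
  expect_identical(as.double(count_linext(two_chains)), 6)  # C(4,2)
  expect_identical(as.double(count_linext(poset(1:3))), 6)
  # connected posets: decomposition equals the direct DP
  for (s in 1:25) {
    P <- random_poset(6, seed = 500 + s, p = 0.4)
    expect_true(count_linext(P) == count_linext_downset_dp(P))
  }
})

test_that("duality preserves the number of linear extensions", {
  for (s in 1:40) {
    P <- random_poset(6, seed = 600 + s)
    expect_true(count_linext(P) == count_linext(dualize(P)))
  }
})

test_that("count bounds and extremal characterisations", {
  for (s in 1:30) {
    n <- 3 + s %% 4
    P <- random_poset(n, seed = 700 + s)
    cnt <- count_linext(P)
    expect_true(cnt >= 1)
    expect_true(cnt <= big_factorial(n))
    s_mat <- cherrycount:::strict_matrix(P)
    if (cnt == 1) expect_identical(sum(s_mat), as.integer(n * (n - 1) / 2))  # total order
    if (cnt == big_factorial(n)) expect_identical(sum(s_mat), 0L)  # antichain
  }
})

test_that("removing a relation never decreases the count", {
  for (s in 1:15) {
    P <- random_poset(5, seed = 800 + s, p = 0.5)
    cg <- cover_graph(P)
    if (nrow(cg$edges) == 0) next
    # drop one cover edge and re-close: a weaker poset
    drop <- cg$edges[1, , drop = FALSE]
    keep <- cg$edges[-1, , drop = FALSE]
    Q <- poset(P$elements, keep)
    expect_true(count_linext(Q) >= count_linext(P))
  }
})

test_that("forest closed form equals the DP on chains, stars and random forests", {
  chain <- poset(1:6, cbind(1:5, 2:6))
  expect_identical(as.double(count_linext_forest_closedform(chain)), 1)
  star <- poset(1:4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_identical(as.double(count_linext_forest_closedform(star)), 6)  # 4!/4
  expect_identical(as.double(count_linext_bruteforce(star)), 6)
  for (s in 1:30) {
    P <- random_forest_poset(4 + s %% 9, seed = s)
    expect_true(count_linext_forest_closedform(P) == count_linext(P))
  }
  not_forest <- poset(1:3, rbind(c(1, 3), c(2, 3)))
  expect_error(count_linext_forest_closedform(not_forest),
               class = "cherrycount_domain_error")
})

test_that("count_cherry_sequences on the worked fixtures", {
  expect_identical(as.double(count_cherry_sequences(balanced_tree4())), 2)
  expect_identical(as.double(count_cherry_sequences(minimal_reticulated())), 2)
  expect_identical(as.double(count_cherry_sequences(single_node_network())), 1)
  # internal poset of the balanced 4-leaf tree is a root with two children
  ccg <- contracted_cover_graph(balanced_tree4())
  expect_identical(as.double(count_linext_forest_closedform(poset_from_cover(ccg$cover))), 2)
})

test_that("count_cherry_sequences guards its domain", {
  no <- non_orchard_network()
  expect_error(count_cherry_sequences(no, "lecount"),
               class = "cherrycount_domain_error")
  expect_warning(cnt <- count_cherry_sequences(no, "bruteforce"))
  expect_true(cnt == 0)
  red <- cherry_reduce(minimal_reticulated(), "u1")
  expect_error(count_cherry_sequences(red), class = "cherrycount_input_error")
})

test_that("auto method equals brute force on guard-sized networks", {
  for (s in 1:20) {
    L <- 3 + s %% 4
    r <- min(s %% 3, L - 1)
    N <- generate_tree_child(L, r, seed = 900 + s)
    expect_true(count_cherry_sequences(N, "auto") ==
                  count_cherry_sequences(N, "bruteforce"))
  }
})
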