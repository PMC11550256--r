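# Exact counting of linear extensions, and the headline operation: counting
# cherry reduction sequences of a tree-child network by counting linear
# extensions of the reachability poset on its internal tree nodes.
#
# Four counters: a permutation-filter brute force (the oracle), a dynamic
# program over downsets (e(D) = sum over maximal m of D of e(D \ {m}),
# states keyed by bitmask, only reachable downsets materialised), a
# component decomposition (multinomial shuffle of independent components),
# and a hook-length closed form when the cover graph is a forest.  All
# results are exact big integers; no floating point anywhere.

the <- new.env(parent = emptyenv())

perms_all <- function(n) {
  key <- as.character(n)
  if (!is.null(the$perms[[key]])) return(the$perms[[key]])
  if (is.null(the$perms)) the$perms <- list()
  gen <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = max(1L, length(v) > 0L)))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], gen(v[-i]))
    }))
  }
  the$perms[[key]] <- gen(seq_len(n))
  the$perms[[key]]
}

#' Count linear extensions by brute force
#'
#' Enumerates all `|P|!` permutations of the ground set and keeps those
#' compatible with the order.  Deliberately naive: this is the independent
#' oracle for the other counters.
#'
#' @param P A [poset()] with at most 8 elements.
#' @return A [bignat()].
#' @export
count_linext_bruteforce <- function(P) {
  n <- poset_size(P)
  if (n > 8L) stop_guard("count_linext_bruteforce: oracle limited to 8 elements")
  if (n == 0L) return(bignat(1))
  s <- strict_matrix(P)
  perms <- perms_all(n)
  bad <- rep(FALSE, nrow(perms))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # position i before position j: invalid if perms[,j] precedes perms[,i]
      bad <- bad | s[cbind(perms[, j], perms[, i])]
    }
  }
  bignat(sum(!bad))
}

#' Count linear extensions by dynamic programming over downsets
#'
#' Computes `e(D)` for downsets `D` of the poset by removing maximal
#' elements: `e(empty) = 1`, `e(D) = sum over maximal m of D of
#' e(D \ {m})`; the answer is `e(P)`.  States are bitmasks over the
#' elements in ascending order; memoization is lazy, so only reachable
#' downsets are stored.
#'
#' @param P A [poset()].
#' @param cap Maximum number of elements (default 28, keeping the
#'   worst-case antichain state space at 2^28).
#' @return A [bignat()].
#' @export
count_linext_downset_dp <- function(P, cap = 28L) {
  n <- poset_size(P)
  if (n > cap) {
    stop_guard(sprintf(paste0(
      "count_linext_downset_dp: %d elements exceeds the cap (%d); ",
      "decompose the poset (count_linext) or raise cap"), n, cap))
  }
  if (n == 0L) return(bignat(1))
  s <- strict_matrix(P)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  # up[i]: bitmask of elements strictly above element i
  up <- vapply(seq_len(n), function(i) {
    ab <- which(s[i, ])
    if (length(ab) == 0L) 0L else Reduce(bitwOr, bit[ab])
  }, integer(1))
  memo <- new.env(parent = emptyenv())
  count_mask <- function(mask) {
    if (mask == 0L) return(bignat(1))
    key <- as.character(mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- bignat(0)
    for (i in seq_len(n)) {
      if (bitwAnd(mask, bit[i]) != 0L && bitwAnd(mask, up[i]) == 0L) {
        # i is maximal within the downset: removing it keeps a downset
        total <- big_add(total, count_mask(bitwAnd(mask, bitwNot(bit[i]))))
      }
    }
    memo[[key]] <- total
    total
  }
  full <- if (n == 31L) -1L else bitwShiftL(1L, n) - 1L
  count_mask(full)
}

comparability_components <- function(P) {
  n <- poset_size(P)
  s <- strict_matrix(P)
  adj <- s | t(s)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(P$elements, comp)
}

#' Count linear extensions (component decomposition)
#'
#' Splits the poset into comparability-connected components of sizes
#' `n_1, ..., n_k`; any linear extension interleaves the components freely,
#' so the count is the multinomial coefficient times the product of the
#' per-component downset-DP counts.  Equals the direct DP when the poset is
#' connected.
#'
#' @param P A [poset()].
#' @param cap Per-component DP cap, see [count_linext_downset_dp()].
#' @return A [bignat()].
#' @export
count_linext <- function(P, cap = 28L) {
  if (poset_size(P) == 0L) return(bignat(1))
  comps <- comparability_components(P)
  sizes <- lengths(comps)
  out <- big_multinomial(sizes)
  for (elems in comps) {
    out <- big_mul(out, count_linext_downset_dp(subposet(P, elems), cap = cap))
  }
  out
}

#' Count linear extensions of a forest poset (hook-length closed form)
#'
#' When the cover graph of the poset is a forest with edges pointing away
#' from the roots, the number of linear extensions has the classical closed
#' form `n! / prod_v s_v`, where `s_v` is the number of elements greater
#' than or equal to `v` (the size of `v`'s subtree).  Used as a second
#' independent oracle for tree-shaped posets.
#'
#' @param P A [poset()] whose cover graph is a forest (each element covers
#'   at most one other; otherwise an error is raised).
#' @return A [bignat()].
#' @export
count_linext_forest_closedform <- function(P) {
  n <- poset_size(P)
  if (n == 0L) return(bignat(1))
  cg <- cover_graph(P)
  indeg <- table(factor(as.character(cg$edges[, 2L]),
                        levels = as.character(P$elements)))
  if (any(indeg > 1L)) {
    stop_domain("count_linext_forest_closedform: cover graph is not a forest")
  }
  s <- strict_matrix(P)
  subtree_sizes <- rowSums(s) + 1L
  out <- big_factorial(n)
  for (sz in subtree_sizes) out <- big_div_small(out, sz)
  out
}

#' Count cherry reduction sequences
#'
#' The headline operation.  For a tree-child network, the number of complete
#' cherry reduction sequences equals the number of linear extensions of the
#' reachability poset on the internal tree nodes (equivalently of its dual:
#' reversal is a bijection), so the count is obtained without enumeration by
#' building the poset's cover graph via [contracted_cover_graph()] and
#' applying [count_linext()].  The brute-force method enumerates sequences
#' with [enumerate_cr_sequences()] (guarded) and also works for non-tree-child
#' orchard networks, where the linear-extension count is only an upper bound.
#'
#' @param N A pristine [phylo_network()].
#' @param method `"auto"` (lecount for tree-child networks, otherwise brute
#'   force), `"lecount"` or `"bruteforce"`.
#' @param guard Enumeration guard for the brute-force path.
#' @return A [bignat()]: the exact number of complete cherry reduction
#'   sequences.  A non-orchard network yields 0 (with a warning) under
#'   `"bruteforce"`.
#' @examples
#' N <- read_network("((a,b)u,(c,d)v)r;")
#' count_cherry_sequences(N)  # 2
#' @export
count_cherry_sequences <- function(N, method = c("auto", "lecount", "bruteforce"),
                                   guard = 10L) {
  method <- match.arg(method)
  bad <- validate_network(N, "pristine")
  if (length(bad) > 0L) {
    stop_input(paste0("count_cherry_sequences: network is not a valid pristine ",
                      "binary network: ", paste(bad, collapse = "; ")))
  }
  if (length(N$nodes) == 1L) return(bignat(1))
  if (method == "auto") {
    method <- if (is_tree_child(N)) "lecount" else "bruteforce"
  }
  if (method == "lecount") {
    if (!is_tree_child(N)) {
      stop_domain(paste0(
        "count_cherry_sequences: the linear-extension route requires a ",
        "tree-child network; for general orchard networks the sequence/",
        "extension correspondence is only injective, not bijective"))
    }
    ccg <- contracted_cover_graph(N)
    return(count_linext(poset_from_cover(ccg$cover)))
  }
  seqs <- enumerate_cr_sequences(N, guard = guard)
  if (length(seqs) == 0L) {
    warning("count_cherry_sequences: network is not orchard; no sequence exists")
  }
  bignat(length(seqs))
}
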