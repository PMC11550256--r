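---
title: "Counting cherry reduction sequences via linear extensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cherry reduction sequences via linear extensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherrycount)
```

## The objects

A *phylogenetic network* here is a rooted directed acyclic graph whose
leaves (out-degree-0 nodes) are bijectively labelled by taxa, in which
every node of in-degree at least 2 — a *reticulation*, modelling
hybridization or lateral transfer — has out-degree exactly 1.  We work
with *binary* networks: every non-root internal node has degrees (1,2) or
(2,1), the root has (0,2) unless the network is a single node.  A network
is *tree-child* if every internal node has at least one child of tree type
(in-degree at most 1).

A *cherry* is a pair of leaves with a common parent; a *reticulated
cherry* is a leaf whose sibling is a reticulation whose single child is a
leaf.  An internal tree node rooting either configuration is *terminal*.
Reducing a terminal node `u` deletes every edge below `u` and every strict
descendant of `u` that is currently a tree node; a descendant reticulation
survives and, having lost its outgoing edge, becomes a new leaf, as does
`u` itself.  Networks reducible to a single node by iterating this
operation are *orchard*; all tree-child networks are orchard.  Throughout
the package, node roles are re-evaluated against **current** degrees after
every reduction: an ex-reticulation with one remaining parent is a tree
node from then on.  Node identifiers are opaque integers fixed at
construction and never renumbered, so a reduced network is a literal
subnetwork of its parent and the same identifier denotes the same node
across a whole sequence.

## The counting identity

Write `N̊` for the network with all leaves removed and `T(N̊)` for its
internal tree nodes (`p = |T(N̊)|`).  Reachability in the network induces a
partial order on `T(N̊)`.  Two facts drive the package:

* in a tree-child network, the terminal nodes are exactly the **maximal**
  elements of that poset, at every stage of a reduction;
* recording the order in which internal tree nodes are reduced maps each
  complete sequence to a linear extension of the **dual** poset, and this
  map is a bijection for tree-child networks.  Reversal turns dual
  extensions into extensions of the poset itself, so
  `|CR-Seq(N)| = |LinExt(T(N̊))|`.

For orchard networks that are not tree-child the map is injective only: a
maximal internal tree node need not be terminal, so some dual extensions
start no sequence and `|CR-Seq(N)| ≤ |LinExt(T(N̊)^op)|`, possibly
strictly.  `count_cherry_sequences()` therefore refuses the
linear-extension route for non-tree-child inputs and falls back to guarded
enumeration.

For binary networks a degree-sum argument gives `p = |Σ| + r − 1` (leaves
plus reticulations minus one); the package always computes `p` from the
graph rather than from a formula, and its complexity diagnostics are
stated in terms of `p`.

## Building the Hasse diagram on the network

`contracted_cover_graph()` constructs the cover graph of the poset
directly from the network: discard leaves; discard reticulations whose
child is a leaf (they have out-degree 0 in `N̊`); contract every remaining
reticulation into its unique child, which is a tree node by the tree-child
property.  The quotient map assigns the sentinel −1 to discarded nodes and
ascending indices to internal tree nodes, so classes have size 1 or 2, a
2-class being a reticulation together with its internal tree child.  The
output is a *minor* of the network, which is what bounds the tree-width of
the cover graph by that of the network and, through the level, yields the
`O(p^{tw+4})` complexity regime for tree-decomposition-based extension
counters.

One correction discovered while verifying this construction against an
independent oracle: the raw quotient is **not** always the Hasse diagram.
If a reticulation `h` (contracted into its child `v`) has parents `u` and
`y` with `u` also an ancestor of `y` through other tree nodes, the network
edge `u→h` contributes a quotient edge `u→[v]` even though `u ≺ … ≺ v`
holds through intermediates, i.e. the edge is transitively implied rather
than a cover relation.  A minimal pristine tree-child example is
`u→{c,h}, c→{y,l1}, y→{h,l2}, h→v, v→{l3,l4}`.  The transitive closure —
and hence any count derived from the quotient — is unaffected, but
`contracted_cover_graph()` finishes with a transitive-reduction pass
computed from the contracted DAG alone so that its output is exactly the
cover graph.  The package's tests compare this route, network in hand,
against a definitional oracle (`cover_graph()` of `reachability_poset()`,
cubic-time transitive reduction of the igraph-computed reachability
relation); the two routes share no code path.

## Counting linear extensions

Four counters, in increasing sophistication, cross-validated against each
other:

* `count_linext_bruteforce()` filters all `p!` permutations (guard:
  `p ≤ 8`).  Deliberately naive; it is the ground truth.
* `count_linext_downset_dp()` runs the exact dynamic program over
  downsets, `e(D) = Σ_m e(D∖{m})` over maximal `m` of `D`.  States are
  bitmasks in ascending-identifier order; memoization is lazy, so memory
  scales with the number of *reachable* downsets, not `2^p`.  The default
  cap of 28 elements keeps the worst case (an antichain) at `2^28` states;
  it is an argument, not a constant.  Removing maximal elements rather
  than minimal ones mirrors the reduction process itself (terminal nodes
  are maximal); by duality the two directions count the same thing.
* `count_linext()` splits the poset into comparability-connected
  components and multiplies the per-component DP counts by the multinomial
  coefficient of the component sizes.
* `count_linext_forest_closedform()` evaluates `n!/∏_v s_v` (subtree
  sizes) when the cover graph is a forest — a closed form used as a second
  independent oracle on tree-shaped posets.

Counts are exact big naturals end to end (base-10^6 limb arithmetic with
addition, multiplication, exact small division and binomials); linear
extension counts pass 2^53 already around `p = 19` on an antichain, so
double-precision floats are not an option anywhere on the counting path.
The CLI prints decimal strings, never scientific notation.

## Synthetic networks

`generate_tree_child()` grows a network from a single node by inverting
the two reductions: splitting a leaf into a cherry (adds one leaf), or
picking two distinct leaves `(u, h)` and adding a reticulated cherry —
`u` becomes internal with a fresh leaf and an edge to `h`; `h` becomes a
reticulation with a fresh leaf child (leaf count unchanged, one more
reticulation).  Interleaving is random with probability proportional to
the remaining quota of each operation.  Because growth inverts a reduction
sequence, every generated network is orchard by construction; tree-child
placements whose new reticulation would rob its other parent of its last
tree child are rejected and resampled, with a whole-run retry budget
(`max_rejections`, default 100).  `generate_orchard()` is the same process
without the rejection rule and is the source of orchard non-tree-child
study networks (filtered on `is_tree_child()`); with 5–7 leaves and 2–3
reticulations roughly half of its draws are non-tree-child.

The generator is reproducible — identical arguments give a byte-identical
serialization, and the RNG state is restored afterwards — but it is *not*
a uniform sampler over tree-child networks of given size: its law is
whatever reverse-reduction growth induces.  Passing tests on these
networks therefore demonstrates correctness of the algebra on a broad,
reproducible family of topologies, not calibration against any biological
generative process; real reticulate histories also carry branch lengths,
non-binary polytomies and incomplete taxon sampling, none of which are
modelled (branch lengths are parsed and discarded at input).

Default study conditions used by the test-suite and the acceptance script:
200 tree-child networks with 4–7 leaves and 0–3 reticulations (sizes where
full enumeration stays comfortably inside the brute-force guard while
still producing hundreds of sequences per network), 50 searched orchard
non-tree-child networks, 500 random posets of 3–7 elements for the DP
cross-check and 100 random tree posets of 4–12 elements for the
hook-length check.

## The clique-minor family and level bounds

`build_clique_minor_network(n)` constructs, for `n ≥ 3`, a pristine binary
tree-child network with `(n−1)(n−2)/2` reticulations in a single
nontrivial blob whose underlying graph has a `K_n` minor, obtained by
contracting `n` pairwise disjoint paths (the classes `z_1 … z_n` of the
returned `minor_spec`; the pendant leaves `x_ij` stay outside all
classes).  One printed-edge-list nuance: the per-path edge sets omit the
root's edge `u_12→u_23`, yet the quotient argument uses it and the root
would otherwise have out-degree 1, so the constructor includes it.  A
`K_n` minor certifies tree-width at least `n − 1`; the family therefore
shows that tree-child networks have unbounded tree-width with level
growing only quadratically in the clique size.  The package reports
`n − 1` (the clique tree-width bound), not `n`.

In the opposite direction, `level_lower_bound_from_minor()` implements
`level(N) ≥ |E(H)| − |V(H)| + 1` for a biconnected minor `H`, with
`clique_level_bound(n) = (n−1)(n−2)/2` and
`grid_level_bound(n, m) = (n−1)(m−1)` as specialisations; on the clique
family the bound is tight, which the tests verify.
`check_reticulations_per_class()` exposes the underlying structural fact:
under any orientation induced by the network, a minor class of oriented
in-degree `d` contains at least `d − 1` reticulations.

## Conventions and degenerate cases

* *Blobs*: only biconnected components with ≥ 3 nodes count; bridges are
  trivial and carry no reticulation.  The level of a tree (no blobs) is 0.
* *Validation modes*: `"pristine"` enforces the full definition;
  `"reduced"` accepts the unlabelled ex-reticulation/ex-terminal leaves
  that reductions create and skips the elementary-node rule.  One type
  with a mode flag, not two types.
* *Single-node network*: valid ("the root is a leaf"); its leafless graph
  is empty, it admits exactly one (empty) reduction sequence, and all
  counters return 1 on the empty poset.
* *Determinism*: enumeration tries terminal nodes in ascending identifier
  order; quotient indices are assigned in ascending identifier order; ties
  never depend on hash order.
* *Dual-order convention*: `linext_to_crseq()` takes the reduction order
  itself (an extension of the dual poset) and validates it by replay;
  `crseq_to_linext()` returns the reversal.  Round trip:
  `linext_to_crseq(N, rev(crseq_to_linext(N, S)))` reproduces `S`.
* *Orchard test*: greedy reduction is sufficient because all complete
  sequences of an orchard network have equal length; getting stuck at more
  than one node is a proof of non-orchardness, not an unlucky choice.

## Limitations

* Non-binary and unrooted networks are out of scope; so is exact
  tree-width computation (only the bounds above are reported) and the
  tree-decomposition-parameterised extension counter — the downset DP with
  component decomposition is the only counting engine, so extremely wide
  posets (`p` beyond ~28 per component) are out of reach by design.
* Randomised approximation of extension counts is not implemented.
* Reconstruction of networks *from* sequences (cherry-picking insertion)
  is not exposed; growth is used internally by the generator only.
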