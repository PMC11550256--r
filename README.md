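# cherrycount

Exact counting of cherry reduction sequences in rooted binary tree-child
phylogenetic networks, by reduction to counting linear extensions of a
poset.

## The problem

Orchard networks — and in particular tree-child networks, one of the most
widely used classes of phylogenetic networks — share a key property with
phylogenetic trees: they can be completely dismantled by iteratively
reducing *cherries* (two leaves with a common parent) and *reticulated
cherries* (a leaf whose sibling is a reticulation whose only child is a
leaf).  The number of distinct orders in which this dismantling can be done
is a topological invariant of the network.  Enumerating the orders directly
explodes combinatorially; this package instead counts them exactly, for
networks far beyond enumeration range, using the identity

```
|CR-Seq(N)|  =  |LinExt( T(N̊) )|
```

for tree-child `N`: the number of complete cherry reduction sequences
equals the number of linear extensions of the reachability poset on the
internal tree nodes of the leafless network `N̊`.  The Hasse diagram of
that poset is read directly off the network — delete the leaves, drop
reticulations whose child is a leaf, contract every remaining reticulation
into its unique tree child, and prune transitively implied edges — and the
extensions are counted by an exact dynamic program over downsets
(`O(2^p · p)` with `p = |T(N̊)| = |Σ| + r − 1`), with a
connected-component multinomial decomposition and a hook-length closed
form for forest-shaped posets.  All counts are arbitrary-precision
integers.

For general orchard networks the correspondence is only injective:
`|CR-Seq(N)| ≤ |LinExt(T(N̊)^op)|`, with strict inequality possible — the
package's generators and tests exercise that regime too.

The package also ships the supporting constructions: an explicit family of
tree-child networks of level `(n−1)(n−2)/2` whose underlying graph has a
`K_n` minor (so tree-child networks have unbounded tree-width), graph-minor
verification, and the level lower bound `level(N) ≥ |E(H)| − |V(H)| + 1`
for any biconnected minor `H`, with its clique and grid/biclique
specialisations.

## Worked example

```r
library(cherrycount)

N <- read_network("((a,(h)#H1)u1,(#H1,b)u2)r;")   # extended Newick, #Hk hybrids
N
#> phylo_network: 7 nodes, 7 edges, 3 leaves, 1 reticulations
#> root: r
is_tree_child(N)        #> TRUE
network_level(N)        #> 1
terminal_nodes(N)       #> nodes u1, u2: both "reticulated_cherry"
count_cherry_sequences(N)
#> 2
for (S in enumerate_cr_sequences(N))
  cat(paste(N$node_names[as.character(S$reduced_nodes)], collapse = " -> "), "\n")
#> u1 -> u2 -> r
#> u2 -> u1 -> r
```

The two printed sequences are the two orders in which the network's
terminal nodes can be reduced; the count returned by
`count_cherry_sequences()` is obtained *without* enumeration, via the
poset route, and agrees with the brute-force enumeration:

```r
G <- generate_tree_child(7, 3, seed = 2026)   # random tree-child network
length(internal_tree_nodes(G))                #> 9   (= 7 leaves + 3 reticulations - 1)
count_cherry_sequences(G, "lecount")          #> 6
count_cherry_sequences(G, "bruteforce")       #> 6

b <- build_clique_minor_network(6)            # K_6-minor family member
network_level(b$network)                      #> 10  (= (6-1)(6-2)/2)
clique_level_bound(6)                         #> 10
```

## Command line

A thin wrapper is installed at `inst/cli/cherrycount`:

```sh
Rscript inst/cli/cherrycount count --input net.nwk --method auto --json
Rscript inst/cli/cherrycount validate --input net.nwk
Rscript inst/cli/cherrycount enumerate --input net.nwk
Rscript inst/cli/cherrycount cover-graph --input net.nwk --output cover.tsv
Rscript inst/cli/cherrycount generate --type random-tree-child \
    --leaves 8 --reticulations 3 --seed 11 --output net.nwk
```

Counts go to stdout as exact decimals; diagnostics (`p`, reticulation
count, level, tree-width bounds, method) to stderr.  Exit codes: 0 ok,
1 input error, 2 domain error, 3 resource guard.

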