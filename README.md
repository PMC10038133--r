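# streamnet

Memory-efficient streaming simulation of contact networks for epidemic
modelling.

## The problem

Epidemic simulation pipelines (FAVITES-style) start from a random *contact
network*: an undirected graph whose nodes are individuals and whose edges are
contacts capable of transmitting a pathogen. General-purpose graph libraries
build the whole network in memory before writing it out, which is fine at
city scale and hopeless at global scale. streamnet instead treats a network
as a **lazy edge stream**: generators emit edges in bounded chunks, writers
consume them chunk by chunk, and — for every model except Barabási–Albert
(O(nm) working set) and the shortcut set of Newman–Watts–Strogatz (O(S)) —
the retained state is constant in the network size.

## Models

| model | parameters | edges |
|---|---|---|
| complete | n | n(n−1)/2 |
| path | n | n−1 |
| cycle | n ≥ 3 | n |
| barbell | n1 ≥ 2, n2 ≥ 0 | n1(n1−1) + n2 + 1 |
| ring lattice | n, even k | nk/2 |
| empty | n | 0 |
| Erdős–Rényi G(n,p) | n, p | Binomial(C(n,2), p) |
| Barabási–Albert | n, m | exactly m(n−m) |
| Newman–Watts–Strogatz | n, even k, p | nk/2 + S, S ~ Binomial(nk/2, p) |

Two algorithmic points carry the memory efficiency:

* **Sparse G(n,p) by geometric skipping.** Rather than flipping C(n,2)
  coins, `gen_er_fast()` jumps straight between included pairs: with
  r ~ Uniform(0,1) the gap to the next included pair is
  1 + ⌊log(1−r)/log(1−p)⌋, and the landed-on position is decoded to a node
  pair by exact integer arithmetic — O(n + |E|) expected time, O(1) state.

* **Small-world shortcuts without enumerating pairs.** The NWS model adds a
  shortcut with probability p per ring-lattice edge. streamnet draws the
  shortcut count in one go, S ~ Binomial(nk/2, p), then samples S distinct
  integers uniformly from 0 … n(n−k−1)/2 − 1 and maps each through an exact
  bijection onto the admissible (non-lattice) node pairs
  (`nws_index_to_edge()`): full rows of the admissible-cell matrix invert by
  integer division, the triangular tail by integer square root with a
  post-check. Only the S shortcut edges are ever held in memory, and every
  sampled graph is connected because the lattice is never rewired.

Output formats: a tab-delimited edge list (plain `u<TAB>v` lines, or the
FAVITES NODE/EDGE dialect), and a compact binary format of exactly
`2·b·|E| + 1` bytes for b-byte node identifiers (b ∈ {1, 2, 4, 8}; one
header byte holding b, then little-endian fixed-width endpoints). Both
stream, both gzip transparently on a `.gz` suffix.

## Worked example

```r
library(streamnet)

rng <- random_source(42)
st  <- gen_nws(10000, 4, 0.05, rng)     # lazy: nothing generated yet
write_edge_list(st, "contacts.tsv")     # streams to disk
#> [1] 20972                            # 20000 lattice + 972 shortcut edges

degree_histogram(gen_nws(10000, 4, 0.05, random_source(42)))
#>    4    5    6    7
#> 8231 1604  155   10                  # lattice degree 4 plus shortcuts

is_connected(gen_nws(10000, 4, 0.05, random_source(42)))
#> [1] TRUE                             # guaranteed by the model

write_binary(gen_nws(10000, 4, 0.05, random_source(42)), "contacts.bin",
             width = 2)
#> [1] 83889                            # exactly 2*2*20972 + 1 bytes
```

The same run from a shell, for pipelines:

```sh
$ Rscript inst/cli/streamnet.R er -n 1000 -p 0.01 --seed 7 -o er.tsv
streamnet: model=er n=1000 |E|=4995 seed=7 format=tsv
$ head -3 er.tsv
0	448
0	499
0	512
```

Identical seeds give byte-identical output, and the logged seed makes any
unseeded run reproducible after the fact.

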