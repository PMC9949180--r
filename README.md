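# eulertigs

Minimum plain-text representation of a k-mer set, without repetitions.

Sequence indexes, sketches and pangenome tools routinely reduce their input
to a *canonical k-spectrum* CS_k(I): the set of length-k substrings of a
string set I, with each k-mer identified with its reverse complement. A
*spectrum-preserving string set* (SPSS) is any string set I′ with
CS_k(I′) = CS_k(I); it is the natural plain-text (FASTA) carrier for a k-mer
set, and the shorter it is, the cheaper every downstream index becomes. This
package computes an SPSS of **minimum cumulative length** (total character
count, CL) under the constraint that every canonical k-mer occupies exactly
one window of the output — no repetitions — together with a certificate
that the minimum is attained. Greedy heuristics of the kind used by
simplitig/unitig-stitching tools are included for comparison, as are a
brute-force oracle and seeded data generators used by the test-suite.

## The method

Work in the arc-centric bidirected de Bruijn graph: nodes are canonical
(k−1)-mers, arcs are canonical k-mers with signed incidences
(⊕ outgoing, ⊖ incoming, ⊙ at self-complemental nodes); a walk may traverse
an arc forwards (spelling its label η) or backwards (spelling rc(η)), and
consecutive arcs must meet at a node with negated signs. An SPSS without
repetitions is exactly a walk cover using every arc once, and its cumulative
length is

    ‖I′‖ = Σ_{W ∈ 𝒲} (k − 1 + |W|),

so minimising CL means minimising the number of walks. Each node's
imbalance (δ⁺ − δ⁻ for normal nodes; degree parity for self-complemental
ones) forces walk ends, giving the per-component lower bound
max(1, imbalance(G)/2) on the number of walks. The algorithm attains it:

1. **Eulerise** — pair up unbalanced incidences with label-less *breaking
   arcs* so every node has imbalance 0;
2. **Eulerian cycle** — Hierholzer's algorithm adapted to signed
   incidences;
3. **Break** — delete the breaking-arc steps; the runs between them are the
   output walks;
4. **Spell** — concatenate oriented labels with (k−1)-overlap.

Everything runs in linear time in the number of k-mers. Unitig compaction
is applied first by default (identical results, smaller graph).

## Worked example

```r
library(eulertigs)
res <- compute_eulertigs(c("GAATG", "ATCTGCT"), k = 3)
res
#> SPSS (eulertigs), k = 3
#>   strings (SC):      2
#>   cumulative length: 12
#>   k-mers:            8 in 1 component(s)
#>   imbalance:         4 (2 breaking arcs)
res$strings
#> [1] "AGATGCTG" "ATTC"
```

The two input strings contain 8 canonical 3-mers; the graph has imbalance 4,
so at least 4/2 = 2 strings are needed, and CL = 8 + (3−1)·2 = 12 is the
minimum. Minimum SPSSs are not unique — `{ATC, AGAATGCTG}` is another valid
witness — but CL and SC are, and the output above passes verification:

```r
verify_spss(c("GAATG", "ATCTGCT"), res$strings, 3)
#> SPSS verification (k = 3)
#>   spectra equal:       TRUE
#>   repeated k-mer windows: 0
spss_lower_bound(c("GAATG", "ATCTGCT"), 3)
#> SPSS lower bound, k = 3: min SC = 2, min CL = 12 over 1 component(s), 8 k-mers
```

Greedy extension can miss the minimum. On `{AGGTGGGAT, GTGCCGTG}` with
k = 4 the optimum is a single string of 14 characters, but forward-only
extension that first follows the `GGGAT` branch is left with two strings
totalling 17:

```r
compute_eulertigs(c("AGGTGGGAT", "GTGCCGTG"), 4)$strings
#> [1] "AGGTGCCGTGGGAT"
g <- build_dbg(canonical_spectrum(c("AGGTGGGAT", "GTGCCGTG"), 4))
ust_tigs(g, seed_order("kmers",
  kmers = c("AGGT", "GGTG", "GTGG", "TGGG", "GGGA", "GGAT")))$strings
#> [1] "ACGGCACG"  "AGGTGGGAT"
```

## Command line

A thin launcher is installed at `exec/eulertigs` inside the package:

```sh
eulertigs compute -k 31 -o tigs.fa --stats stats.json reads.fastq
eulertigs verify -k 31 -c tigs.fa reads.fastq
eulertigs stats -k 31 assembly.fasta
eulertigs simulate -l 10000 --seed 1 -o genome.fa
```

`compute` supports `--algorithm eulertigs|ust|prophasm|unitigs`,
`--min-abundance`, `--no-compact`, `--order-file` (one k-mer per line,
forcing the heuristic extension order) and `--seed`. Identical
configuration gives byte-identical output.

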