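---
title: "Minimum spectrum-preserving string sets without repetitions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum spectrum-preserving string sets without repetitions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eulertigs)
```

## The problem

Many k-mer-based tools (indexes, sketches, abundance filters) operate on the
*canonical k-spectrum* of a sequence set: the set of all length-k substrings,
with each k-mer identified with its reverse complement and represented by the
lexicographically smaller of the two. Storing the spectrum as plain strings is
attractive because any sequence toolchain can consume it, but a naive dump of
one string per k-mer wastes k-1 characters of overlap between adjacent
k-mers. A *spectrum-preserving string set* (SPSS) is any string set with the
same canonical k-spectrum as the input; the goal of this package is the SPSS
of minimum total character count (*cumulative length*, CL) under the
constraint that no canonical k-mer occupies more than one window
("without repetitions"), so the representation stays a set, not a multiset.

This package computes that minimum exactly, in time linear in the input for a
fixed alphabet. It also implements the greedy heuristics the minimum is
usually compared against, an imbalance-based lower bound that certifies
optimality, a brute-force oracle for independent verification on tiny
instances, and seeded synthetic-data generators so that every claim in the
test-suite is checked without external data.

## The graph model

Strands are handled with a *bidirected* graph rather than by doubling the
graph. Nodes are canonical (k-1)-mers; each canonical k-mer is an arc from
the canonical form of its (k-1)-prefix to the canonical form of its
(k-1)-suffix. Every incidence of an arc carries a sign: `+` (outgoing), `-`
(incoming), or `.` at *self-complemental* nodes — (k-1)-mers equal to their
own reverse complement, which exist exactly when k-1 is even. A walk may use
an arc forwards (spelling its label) or backwards (spelling the reverse
complement), and consecutive arcs must meet at a shared node with *negated*
signs; sign negation swaps `+` and `-` and fixes `.`. This continuity rule is
exactly equivalent to (k-1)-character overlap of the spelled k-mers, which is
the content of the label-soundness property that
`check_label_soundness()` verifies exhaustively (all four incidence/overlap
biconditionals over all arc pairs) on every fixture graph.

The sign convention in `build_dbg()` — tail `+` iff the prefix is canonical,
head `-` iff the suffix is canonical, `.` at self-complemental ends — is the
unique convention up to a global flip that satisfies those biconditionals.
Corner cases are carried, not excluded: a palindromic k-mer (even k, e.g.
`ACGT`) becomes a self-loop with *both* incidences signed `+` at one node and
counts two incidences toward that node's degree; self-complemental nodes
(odd k, e.g. `AT` at k = 3) carry only dot incidences.

## Lower bound, Eulerisation and the Eulerian cycle

For a normal node the *imbalance* is outdegree minus indegree; for a
self-complemental node it is the parity of its degree. Summed in absolute
value over a connected component, the imbalance counts forced walk ends: a
walk passing through a node consumes one incidence of each sign (or two dot
incidences), so each unit of imbalance forces a walk to start or end there.
A repetition-free walk cover of a connected graph therefore needs at least
`max(1, imbalance/2)` walks, and since every walk costs exactly k-1
characters over its k-mer count, the minimum cumulative length is
`n_kmers + (k-1) * min_walks`. `spss_lower_bound()` reports this per
component.

The bound is attained constructively. `eulerise()` collects the unbalanced
incidences in ascending node-id order — one dot entry per odd-degree
self-complemental node, |imbalance| entries of the *opposite* sign per
unbalanced normal node — and pairs consecutive entries into label-less
*breaking arcs*. The list always has even length because the total imbalance
is even (adding any single arc changes it by -2, 0 or +2). The balanced
graph then admits a bidirected Eulerian cycle, found by `eulerian_cycle()`
with a Hierholzer-style search: a stack of pending states, where a state is
the node plus the sign the next departure must carry. We use the stack
formulation with one cursor per (node, sign) adjacency list instead of the
equivalent linked-list formulation that keeps a "first unfinished" pointer
into the cycle; the cursors guarantee each departure candidate is inspected
once, so the search is linear in the number of arcs either way, and the
stack variant maps naturally onto R vectors.

`break_cycle()` removes the breaking-arc steps; the maximal runs of real
steps between them (wrapping around the cycle) are the output walks —
exactly `max(1, imbalance/2)` of them, matching the bound. Two adjacent
breaking arcs would yield an empty run, but the sign bookkeeping makes that
impossible (all breaking incidences at a node carry the sign opposite to its
excess, so no breaking arc can depart where another just arrived); the
implementation still guards for it and fails loudly, since an empty run
could only come from a construction bug. `spell_walk()` concatenates the
oriented labels with k-1 overlap, validating the overlap as it goes.
`compute_eulertigs()` runs this per connected component and asserts, on
every run, the two identities `SC = sum(max(1, imbalance_c/2))` and
`CL = n_kmers + (k-1) * SC`.

### Determinism

Minimum SPSSs are not unique, so every arbitrary choice is pinned down to
make outputs byte-reproducible: node ids follow first encounter over sorted
k-mers; arc uids are sorted label order; the cycle search starts at the
smallest uid in forward orientation and always takes the smallest-uid unused
continuation (forward preferred); a balanced component's cycle is opened
before its smallest-uid step; spelled strings are emitted in canonical
orientation (string <= its reverse complement) and sorted. Only CL and SC
are intrinsic; the specific strings are one valid witness.

## Compaction

`compact_dbg()` contracts the standard unitig-internal nodes: normal nodes
with exactly one incoming and one outgoing arc (neither a self-loop), and
self-complemental nodes with exactly two single-incidence arcs. Nodes
touching any self-loop are left alone — contracting an arc with itself is
ill-defined, and the self-complemental clause ("exactly one incidence each")
already excludes it, an exclusion we extend to normal nodes. A cycle whose
nodes are all contractible is anchored at the arc with the smallest uid and
collapses to one self-loop. Merged labels are normalised to canonical
orientation. Contracted nodes are balanced by construction, so degrees at
surviving nodes, component structure, imbalance, and hence CL and SC are
unchanged; the tests confirm the compacted and uncompacted pipelines agree
exactly. Compaction is on by default purely as a graph-size reduction.

## The greedy heuristics

For comparison, `ust_tigs()` re-implements forward-only greedy extension
with a joining pass, and `prophasm_tigs()` bidirectional greedy extension,
as sketched in the literature they come from. Both are described there only
at the level of "choose an arbitrary arc, extend to arbitrary unused arcs",
so the arbitrary choices are externalised into a `seed_order()`: ascending
uid (default), a supplied k-mer list (to force a particular extension path),
or a seeded random permutation of the oriented arcs. Choices this package
had to make and documents as its own: a walk extends forward fully before
backward extension begins (bidirectional variant); the joining pass scans
candidate walk starts in ascending uid and matches them against the finished
walk's end state in the orientation the walks were built. With an
orientation-inclusive random order, the forward-only heuristic can seed a
terminal arc in its dead-end orientation and keep an extra string even on a
simple path; only the dominance guarantee (heuristic CL and SC never below
the optimum) holds for every order, and that is what the tests assert
globally. The two-string example shipped in
`inst/extdata/branching_pair.fasta` shows the gap: the optimum is one string
of 14 characters, while the forced adversarial order yields two strings
totalling 17.

## The brute-force oracle

`brute_force_min_spss()` certifies minimality independently: it enumerates
partitions of the arcs into sign-consistent walks by backtracking,
anchoring each new walk at the smallest-uid uncovered arc in forward
orientation (sound because walks extend at both ends and whole-walk reversal
gives the same cover) and growing head-first then tail-first so each walk is
generated once. It deliberately never consults the imbalance formula —
that would be circular — and is capped at 10 k-mers by default. The
acceptance suite checks the pipeline's CL against the oracle on 200 seeded
random canonical k-mer sets with k in {3, 4, 5} and up to 8 k-mers.

## Synthetic data

`generate_genome()` draws uniform i.i.d. bases; `generate_reads()` samples
uniform substrings at a target coverage with optional per-base `N`
injection; `random_kmer_set()` draws, canonicalises and deduplicates random
k-mers. These emulate the two input shapes that matter to the algorithm —
long assembled strings and many short reads — and the parser behaviours
(ambiguity splitting, segment dropping). They do not emulate repeats, GC
bias, or realistic error models, so passing tests demonstrate correctness of
the combinatorics on arbitrary spectra, not performance characteristics on
real genomes; correctness is input-agnostic because every property checked
(spectrum equality, zero repetitions, bound tightness) is verified directly
on each output.

The suite exercises genomes of 1-10 kb and read sets of a few hundred reads,
with k in {5, 21, 31, 32}: k = 5 on 10 kb saturates the 5-mer space and
produces a dense, highly unbalanced graph; k = 21 and 31 give sparse
path-like graphs; k = 32 (even) exercises palindromic k-mers, and odd k
exercises self-complemental nodes. These sizes keep the full suite under
half a minute while covering both graph regimes.

## Tunable parameters

* `k` (mandatory, >= 2): the k-mer length. Both parities are supported; k = 1
  is rejected because nodes would be empty strings. Nodes are (k-1)-mers, so
  self-complemental *nodes* appear at odd k and palindromic *arcs* at even k.
* `min_abundance` (default 1): canonical k-mer count threshold applied over
  all windows of all input strings; above 1 it is an error filter for read
  sets.
* `compact` (default TRUE): whether the Eulerian phase runs on the compacted
  graph; results are identical either way.
* Ambiguity handling (fixed policy): input is uppercased, characters outside
  the alphabet split strings into segments, segments shorter than k are
  dropped with a message carrying the count.
* The alphabet itself is parametrizable (`alphabet()`): any ordered symbol
  set with a self-inverse complement works; DNA is the default.

## Degenerate inputs and guards

Empty spectra return an empty result with a warning. Disconnected graphs are
handled per component (`eulerise()` itself refuses disconnected input, as
its contract is per-component). `eulerian_cycle()` refuses unbalanced graphs
naming the offending node, and detects disconnection by an incomplete cycle.
Mixed-length or non-canonical k-mer vectors are rejected at construction.
The quadratic label-soundness checker refuses graphs above 1000 arcs.

## Known limitations

* The construction is hash-based and in-memory; it targets desk-scale inputs
  (up to a few hundred thousand k-mers), not whole-genome scale, and there
  is no external-memory or parallel mode.
* Repetition-allowing minimum SPSS variants (which can be shorter than the
  repetition-free minimum) are out of scope.
* The heuristics are faithful to their published sketches, not
  bit-compatible with the original UST/ProphAsm binaries, whose internal
  orders are unspecified; comparisons should be made through CL/SC, which is
  what they were built for.

## A worked example

```{r}
res <- compute_eulertigs(c("GAATG", "ATCTGCT"), k = 3)
res
res$strings
spss_lower_bound(c("GAATG", "ATCTGCT"), 3)
verify_spss(c("GAATG", "ATCTGCT"), res$strings, 3)
```
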