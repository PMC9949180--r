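# Graph construction, signs, degrees, components and compaction.

test_that("construction produces the expected nodes, arcs and signs", {
  g <- worked_graph()
  expect_identical(n_nodes(g), 6L)
  expect_identical(n_arcs(g), 8L)
  expect_identical(sort(g$node_mer), sort(c("GA", "AA", "AT", "CA", "AG", "GC")))
  expect_identical(g$node_mer[g$node_selfc], c("AT", "GC"))
  # self-complemental nodes carry only dot incidences, normal nodes never do
  arcs <- as.data.frame(g)
  expect_true(all(arcs$tail_sign[g$node_selfc[arcs$tail]] == "."))
  expect_true(all(arcs$head_sign[g$node_selfc[arcs$head]] == "."))
  expect_true(all(arcs$tail_sign[!g$node_selfc[arcs$tail]] != "."))
  expect_true(all(arcs$head_sign[!g$node_selfc[arcs$head]] != "."))
})

test_that("single-arc sign rules match the canonical-prefix convention", {
  # both (k-1)-mers canonical: tail outgoing, head incoming
  g <- build_dbg(kmer_set("GAA", 3))
  a <- as.data.frame(g)
  expect_identical(a$tail_mer, "GA")
  expect_identical(a$tail_sign, "+")
  expect_identical(a$head_mer, "AA")
  expect_identical(a$head_sign, "-")
  # palindromic k-mer: self-loop with both incidences (ACG, +)
  g2 <- build_dbg(kmer_set("ACGT", 4))
  a2 <- as.data.frame(g2)
  expect_identical(a2$tail, a2$head)
  expect_identical(a2$tail_mer, "ACG")
  expect_identical(a2$tail_sign, "+")
  expect_identical(a2$head_sign, "+")
})

test_that("mixed k-mer lengths and non-canonical input are rejected", {
  expect_error(build_dbg(c("GAA", "AATC")), "mixed")
  expect_error(build_dbg(c("TCT")), "canonical")
})

test_that("degrees and imbalance match hand counts", {
  dr <- degrees_and_imbalance(worked_graph())
  expect_identical(dr$imbalance, 4L)
  imb1 <- dr$nodes$mer[dr$nodes$imbalance == 1L]
  expect_identical(sort(imb1), sort(c("GA", "AT", "CA", "AG")))
  # balanced graph with self-complemental nodes of even degree
  dr2 <- degrees_and_imbalance(build_dbg(canonical_spectrum("AATAA", 3)))
  expect_identical(dr2$imbalance, 0L)
  # empty graph
  dr3 <- degrees_and_imbalance(build_dbg(kmer_set(character(0), 3)))
  expect_identical(dr3$imbalance, 0L)
  # palindromic self-loop counts two incidences toward the degree
  dr4 <- degrees_and_imbalance(build_dbg(kmer_set("ACGT", 4)))
  expect_identical(dr4$nodes$outdegree, 2L)
  expect_identical(dr4$nodes$indegree, 0L)
  expect_identical(dr4$imbalance, 2L)
})

test_that("graph imbalance is even on constructed and Eulerised graphs", {
  for (seed in 1:25) {
    ks <- random_kmer_set(sample(2:20, 1), sample(3:5, 1), seed = seed)
    g <- build_dbg(ks)
    expect_identical(degrees_and_imbalance(g)$imbalance %% 2L, 0L)
    cc <- connected_components(g)
    for (ci in seq_len(cc$n_components)) {
      sub <- eulertigs:::.subgraph(g, which(cc$arc_component == ci))
      ge <- eulerise(sub)
      expect_identical(degrees_and_imbalance(ge)$imbalance, 0L)
    }
  }
})

test_that("connected components partition nodes and arcs", {
  cc <- connected_components(worked_graph())
  expect_identical(cc$n_components, 1L)
  two <- build_dbg(kmer_set(
    sort(unique(c(canonical_spectrum("GAATG", 3)$kmers,
                  canonical_spectrum("CCCCC", 3)$kmers))), 3))
  cc2 <- connected_components(two)
  expect_identical(cc2$n_components, 2L)
  expect_identical(length(cc2$arc_component), n_arcs(two))
  expect_true(all(table(cc2$arc_component) >= 1L))
  empty <- connected_components(build_dbg(kmer_set(character(0), 3)))
  expect_identical(empty$n_components, 0L)
})

test_that("label soundness holds exhaustively on all fixture graphs", {
  for (g in fixture_graphs()) {
    expect_true(check_label_soundness(g))
  }
  for (seed in 1:10) {
    ks <- random_kmer_set(sample(5:40, 1), sample(3:6, 1), seed = seed + 50)
    expect_true(check_label_soundness(build_dbg(ks)))
  }
  gen <- generate_genome(150, seed = 9)
  expect_true(check_label_soundness(build_dbg(canonical_spectrum(gen, 5))))
  expect_true(check_label_soundness(
    compact_dbg(build_dbg(canonical_spectrum(gen, 5)))))
})

test_that("compaction contracts 1-in-1-out and 2-incidence palindromic nodes", {
  g <- worked_graph()
  gc <- compact_dbg(g)
  # AA (one in GAA, one out AAT) contracts into GAAT, stored canonically
  expect_true("ATTC" %in% gc$label)  # rc(GAAT)
  # GC (self-complemental, single incidences from GCA and AGC) contracts
  expect_true("AGCA" %in% gc$label)
  expect_false("AA" %in% gc$node_mer)
  expect_false("GC" %in% gc$node_mer)
  # branching nodes survive
  expect_true(all(c("AT", "GA", "AG", "CA") %in% gc$node_mer))
})

test_that("compaction preserves the label spectrum and degrees", {
  for (seed in 1:10) {
    gen <- generate_genome(300, seed = seed)
    ks <- canonical_spectrum(gen, 5)
    g <- build_dbg(ks)
    gc <- compact_dbg(g)
    expect_identical(eulertigs:::.label_spectrum(gc), ks$kmers)
    expect_identical(eulertigs:::.n_label_kmers(gc), length(ks))
    # degrees at surviving nodes unchanged
    d0 <- degrees_and_imbalance(g)$nodes
    d1 <- degrees_and_imbalance(gc)$nodes
    shared <- match(d1$mer, d0$mer)
    expect_identical(d1$degree, d0$degree[shared])
    expect_identical(d1$imbalance, d0$imbalance[shared])
    # idempotent
    gcc <- compact_dbg(gc)
    expect_identical(gcc$label, gc$label)
  }
})

test_that("a fully contractible cycle collapses to one self-loop", {
  g <- build_dbg(kmer_set(c("AAC", "ACA", "CAA"), 3))
  gc <- compact_dbg(g)
  expect_identical(n_arcs(gc), 1L)
  expect_identical(gc$tail, gc$head)
  expect_identical(eulertigs:::.label_spectrum(gc), sort(c("AAC", "ACA", "CAA")))
})

test_that("nodes touching self-loops or branching are never contracted", {
  # ACG has a palindromic self-loop plus a through-path: must survive
  ks <- kmer_set(sort(c("ACGT", "AACG", "ACGA")), 4)
  g <- build_dbg(ks)
  gc <- compact_dbg(g)
  expect_true("ACG" %in% gc$node_mer)
  expect_identical(eulertigs:::.label_spectrum(gc), ks$kmers)
  # a node with two outgoing and one incoming arc is untouched
  ks2 <- kmer_set(sort(c("GAA", "AAT", "AAC")), 3)
  gc2 <- compact_dbg(build_dbg(ks2))
  expect_true("AA" %in% gc2$node_mer)
  expect_identical(eulertigs:::.label_spectrum(gc2), ks2$kmers)
})

test_that("GFA dump and load round-trips the graph", {
  td <- withr::local_tempdir()
  ge <- eulerise(worked_graph())
  path <- file.path(td, "graph.gfa")
  write_gfa(ge, path)
  g2 <- read_gfa(path)
  expect_identical(as.data.frame(ge), as.data.frame(g2))
  expect_identical(g2$k, 3L)
  expect_identical(g2$node_selfc, ge$node_selfc)
})
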