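# Eulerisation, Eulerian cycles, cycle breaking, spelling and the full
# minimum-SPSS pipeline.

test_that("eulerise adds imbalance/2 breaking arcs and balances every node", {
  ge <- eulerise(worked_graph())
  expect_identical(sum(ge$breaking), 2L)
  expect_identical(degrees_and_imbalance(ge)$imbalance, 0L)
  # already balanced graph is untouched
  gb <- build_dbg(canonical_spectrum("AATAA", 3))
  expect_identical(sum(eulerise(gb)$breaking), 0L)
  # palindromic self-loop: breaking self-loop with both incidences (ACG, -)
  gp <- eulerise(build_dbg(kmer_set("ACGT", 4)))
  br <- which(gp$breaking)
  expect_identical(length(br), 1L)
  expect_identical(gp$tail[br], gp$head[br])
  expect_identical(gp$tsign[br], -1L)
  expect_identical(gp$hsign[br], -1L)
  expect_identical(degrees_and_imbalance(gp)$imbalance, 0L)
})

test_that("eulerise refuses disconnected graphs", {
  two <- build_dbg(kmer_set(
    sort(unique(c(canonical_spectrum("GAATG", 3)$kmers,
                  canonical_spectrum("CCCCC", 3)$kmers))), 3))
  expect_error(eulerise(two), "connected")
})

test_that("the Eulerian cycle uses every arc exactly once", {
  cases <- list(
    list(g = eulerise(worked_graph()), len = 10L),
    list(g = eulerise(build_dbg(kmer_set("ACGT", 4))), len = 2L),
    list(g = build_dbg(canonical_spectrum("AATAA", 3)), len = 3L)
  )
  for (cs in cases) {
    cyc <- eulerian_cycle(cs$g)
    expect_identical(length(cyc), cs$len)
    expect_true(cyc$is_cycle)
    expect_identical(sort(cyc$uid), seq_len(n_arcs(cs$g)))
  }
})

test_that("eulerian_cycle names the offending unbalanced node", {
  expect_error(eulerian_cycle(worked_graph()), "not Eulerian.*imbalance")
  expect_error(eulerian_cycle(build_dbg(kmer_set(character(0), 3))),
               "at least one arc")
})

test_that("break_cycle splits at breaking arcs, wrapping around the cycle", {
  ge <- eulerise(worked_graph())
  walks <- break_cycle(eulerian_cycle(ge), ge)
  expect_identical(length(walks), 2L)
  expect_identical(sort(unlist(lapply(walks, `[[`, "uid"))), 1:8)
  expect_false(any(ge$breaking[unlist(lapply(walks, `[[`, "uid"))]))
  # zero breaking arcs: one walk, opened before the smallest-uid step
  gb <- build_dbg(canonical_spectrum("AATAA", 3))
  wb <- break_cycle(eulerian_cycle(gb), gb)
  expect_identical(length(wb), 1L)
  expect_identical(length(wb[[1]]), 3L)
  expect_identical(wb[[1]]$uid[1L], 1L)
  # one breaking arc: one walk
  gp <- eulerise(build_dbg(kmer_set("ACGT", 4)))
  wp <- break_cycle(eulerian_cycle(gp), gp)
  expect_identical(length(wp), 1L)
  expect_identical(length(wp[[1]]), 1L)
})

test_that("spelling overlaps k-mers by k-1 and respects orientation", {
  g <- worked_graph()
  uid_of <- function(lab) which(g$label == lab)
  w <- eulertigs:::.new_walk(c(uid_of("GAA"), uid_of("AAT")), c(TRUE, TRUE))
  expect_identical(spell_walk(w, g), "GAAT")
  w2 <- eulertigs:::.new_walk(uid_of("AGA"), FALSE)
  expect_identical(spell_walk(w2, g), "TCT")
  expect_identical(spell_walk(eulertigs:::.new_walk(integer(0), logical(0)), g),
                   "")
  # discontinuous steps are reported with their index
  bad <- eulertigs:::.new_walk(c(uid_of("GAA"), uid_of("CAG")), c(TRUE, TRUE))
  expect_error(spell_walk(bad, g), "step 2")
  # breaking arcs cannot be spelled
  ge <- eulerise(g)
  br <- which(ge$breaking)[1L]
  expect_error(spell_walk(eulertigs:::.new_walk(br, TRUE), ge), "breaking")
})

test_that("the pipeline reproduces the worked example: SC 2, CL 12", {
  res <- compute_eulertigs(worked_example, 3)
  expect_identical(res$SC, 2L)
  expect_identical(res$CL, 12L)
  expect_identical(res$imbalance, 4L)
  expect_identical(res$breaking_arcs, 2L)
  expect_valid_spss(res, worked_example, 3)
  # the published witness {ATC, AGAATGCTG} spans the same spectrum
  rep <- verify_spss(worked_example, c("ATC", "AGAATGCTG"), 3)
  expect_true(rep$spectra_equal)
  expect_identical(rep$repeated_kmer_positions, 0L)
})

test_that("the branching pair collapses to one string of length 14", {
  res <- compute_eulertigs(branching_pair, 4)
  expect_identical(res$SC, 1L)
  expect_identical(res$CL, 14L)
  expect_valid_spss(res, branching_pair, 4)
})

test_that("a balanced component yields a single circularly-opened string", {
  res <- compute_eulertigs("AATAA", 3)
  expect_identical(res$SC, 1L)
  expect_identical(res$CL, 5L)
  expect_valid_spss(res, "AATAA", 3)
})

test_that("disconnected inputs are handled per component", {
  strings <- c("GAATG", "CCCCCC")
  res <- compute_eulertigs(strings, 3)
  expect_identical(res$n_components, 2L)
  expect_valid_spss(res, strings, 3)
  lb <- spss_lower_bound(strings, 3)
  expect_identical(res$CL, lb$min_CL)
  expect_identical(res$SC, lb$min_SC)
})

test_that("empty spectra produce an empty result with a warning", {
  expect_warning(
    expect_warning(res <- compute_eulertigs("AC", 3), "empty"),
    "empty"
  )
  expect_identical(res$SC, 0L)
  expect_identical(res$CL, 0L)
})

test_that("lower bound: per-component imbalance and cumulative length", {
  lb <- spss_lower_bound(worked_example, 3)
  expect_identical(lb$min_SC, 2L)
  expect_identical(lb$min_CL, 12L)
  lb2 <- spss_lower_bound(branching_pair, 4)
  expect_identical(lb2$min_SC, 1L)
  expect_identical(lb2$min_CL, 14L)
  lb3 <- spss_lower_bound(kmers = kmer_set("GAA", 3))
  expect_identical(lb3$min_SC, 1L)
  expect_identical(lb3$min_CL, 3L)
})

test_that("computed CL always attains the lower bound (tightness)", {
  for (seed in 1:15) {
    gen <- generate_genome(sample(100:800, 1), seed = seed + 200)
    k <- sample(c(4L, 5L, 7L, 11L), 1)
    res <- compute_eulertigs(gen, k)
    lb <- spss_lower_bound(gen, k)
    expect_identical(res$CL, lb$min_CL)
    expect_identical(res$SC, lb$min_SC)
    expect_identical(res$CL, res$n_kmers + (k - 1L) * res$SC)
  }
})

test_that("spectrum preservation at scale for odd and even k", {
  genome_sizes <- c(1000L, 10000L)
  for (i in seq_along(genome_sizes)) {
    gen <- generate_genome(genome_sizes[i], seed = 7000L + i)
    for (k in c(5L, 21L, 31L, 32L)) {
      a <- compute_eulertigs(gen, k, compact = TRUE)
      b <- compute_eulertigs(gen, k, compact = FALSE)
      expect_identical(a$CL, b$CL)
      expect_identical(a$SC, b$SC)
      expect_valid_spss(a, gen, k)
      rep_b <- verify_spss(gen, b$strings, k)
      expect_true(rep_b$spectra_equal)
      expect_identical(rep_b$repeated_kmer_positions, 0L)
    }
  }
  # read sets with ambiguous bases
  gen <- generate_genome(3000, seed = 77)
  reads <- generate_reads(gen, 100, 6, seed = 78, n_rate = 0.005)
  for (k in c(21L, 32L)) {
    res <- suppressMessages(compute_eulertigs(reads, k))
    rep <- verify_spss(reads, res$strings, k)
    expect_true(rep$spectra_equal)
    expect_identical(rep$repeated_kmer_positions, 0L)
  }
})

test_that("identical inputs give byte-identical results", {
  a <- compute_eulertigs(worked_example, 3)
  b <- compute_eulertigs(worked_example, 3)
  expect_identical(a$strings, b$strings)
  gen <- generate_genome(500, seed = 42)
  expect_identical(compute_eulertigs(gen, 7)$strings,
                   compute_eulertigs(gen, 7)$strings)
})
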