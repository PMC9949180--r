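# Worked examples and small helpers used across the suite.

# two strings whose order-3 graph has imbalance 4 (two walks needed)
worked_example <- c("GAATG", "ATCTGCT")
worked_spectrum <- sort(c("AAT", "AGA", "AGC", "ATC", "ATG", "CAG",
                          "GAA", "GCA"))

# two strings whose order-4 graph admits a single walk (CL 14) that greedy
# forward extension can miss (CL 17)
branching_pair <- c("AGGTGGGAT", "GTGCCGTG")
adversarial_kmers <- c("AGGT", "GGTG", "GTGG", "TGGG", "GGGA", "GGAT")

fixture_path <- function(name) {
  system.file("extdata", name, package = "eulertigs", mustWork = TRUE)
}

worked_graph <- function() build_dbg(canonical_spectrum(worked_example, 3))
branching_graph <- function() build_dbg(canonical_spectrum(branching_pair, 4))

# all fixture graphs the exhaustive soundness checks run over
fixture_graphs <- function() {
  list(
    worked = worked_graph(),
    worked_compacted = compact_dbg(worked_graph()),
    branching = branching_graph(),
    branching_compacted = compact_dbg(branching_graph()),
    palindrome_loop = build_dbg(canonical_spectrum("ACGT", 4)),
    balanced_odd = build_dbg(canonical_spectrum("AATAA", 3)),
    even_k_mixed = build_dbg(canonical_spectrum("ACGTACGT", 4))
  )
}

expect_valid_spss <- function(result, input, k) {
  rep <- verify_spss(input, result$strings, k)
  expect_true(rep$spectra_equal)
  expect_identical(rep$repeated_kmer_positions, 0L)
  expect_identical(result$CL, sum(nchar(result$strings)))
  expect_identical(result$SC, length(result$strings))
}
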