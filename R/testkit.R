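# Brute-force minimum-SPSS oracle and synthetic data generators. The oracle
# searches walk partitions directly and never consults the imbalance formula,
# so it is an independent check of the Eulertig pipeline's minimality.

#' Brute-force minimum SPSS without repetitions
#'
#' Exhaustive backtracking over all ways to partition the arcs of the
#' de Bruijn graph into sign-consistent walks, minimising the number of walks
#' (equivalently the cumulative length, since every walk costs a fixed k-1
#' characters on top of one character per k-mer). Each new walk is anchored at
#' the smallest-uid uncovered arc in forward orientation (any walk through
#' that arc can be built by extending both ends, and reversing a whole walk
#' yields the same cover), and walks are grown head-first then tail-first so
#' each walk is enumerated once. Exponential; guarded to tiny instances.
#'
#' @param kmers A \code{\link{kmer_set}} or character vector of canonical
#'   k-mers.
#' @param max_kmers Refuse instances with more k-mers than this.
#' @param ab Alphabet (ignored when \code{kmers} is a \code{kmer_set}).
#' @return A list: \code{min_SC}, \code{min_CL} and \code{strings} (one
#'   witness string set, canonical orientation, sorted).
#' @examples
#' brute_force_min_spss(canonical_spectrum(c("GAATG", "ATCTGCT"), 3))
#' @export
brute_force_min_spss <- function(kmers, max_kmers = 10L, ab = dna_alphabet()) {
  g <- build_dbg(kmers, ab)
  m <- n_arcs(g)
  k <- g$k
  if (m > max_kmers) {
    stop("instance has ", m, " k-mers; the brute-force oracle is limited to ",
         max_kmers)
  }
  if (m == 0L) {
    return(list(min_SC = 0L, min_CL = 0L, strings = character(0)))
  }
  tr <- .traversals(g)
  adj <- .state_adjacency(g, tr)
  partner <- function(t) t + ifelse(t %% 2L == 1L, 1L, -1L)
  unused_from <- function(state_key) {
    cand <- adj[[state_key]]
    cand[!used[tr$arc[cand]]]
  }

  used <- logical(m)
  best_count <- Inf
  best_walks <- NULL

  # open: traversal steps of the current walk; tail_only: once the walk has
  # been extended at its tail, head extensions stop (canonical build order)
  dfs <- function(open, closed, tail_only) {
    if (length(closed) + 1L >= best_count) return(invisible(NULL))
    if (all(used)) {
      best_count <<- length(closed) + 1L
      best_walks <<- c(closed, list(open))
      return(invisible(NULL))
    }
    if (!tail_only) {
      last <- open[length(open)]
      for (t in unused_from(.state_key(tr$to_node[last], -tr$to_sign[last]))) {
        used[tr$arc[t]] <<- TRUE
        dfs(c(open, t), closed, FALSE)
        used[tr$arc[t]] <<- FALSE
      }
    }
    first <- open[1L]
    for (u in unused_from(.state_key(tr$from_node[first],
                                     -tr$from_sign[first]))) {
      used[tr$arc[u]] <<- TRUE
      dfs(c(partner(u), open), closed, TRUE)
      used[tr$arc[u]] <<- FALSE
    }
    # close the current walk and anchor a new one
    a0 <- which(!used)[1L]
    used[a0] <<- TRUE
    dfs(2L * a0 - 1L, c(closed, list(open)), FALSE)
    used[a0] <<- FALSE
    invisible(NULL)
  }

  used[1L] <- TRUE
  dfs(1L, list(), FALSE)

  strings <- vapply(best_walks, function(s) {
    spell_walk(.new_walk(tr$arc[s], tr$forward[s]), g)
  }, character(1))
  list(
    min_SC = as.integer(best_count),
    min_CL = m + (k - 1L) * as.integer(best_count),
    strings = sort(.canonical(strings, g$alphabet))
  )
}

#' Synthetic genomes, read sets and k-mer sets
#'
#' Seeded generators used throughout the test-suite so that every run is
#' reproducible without external downloads. \code{generate_genome} draws a
#' uniform random string; \code{generate_reads} samples substrings at the
#' requested coverage, optionally overwriting bases with \code{N} to emulate
#' ambiguous calls; \code{random_kmer_set} draws, canonicalises and
#' deduplicates random k-mers.
#'
#' @param length Genome length in characters.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output. \code{NULL} leaves the RNG state alone.
#' @param ab Alphabet.
#' @return \code{generate_genome}: a single string.
#' @export
generate_genome <- function(length, seed = NULL, ab = dna_alphabet()) {
  length <- as.integer(length)
  if (length < 1L) stop("genome length must be positive")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(ab$symbols, length, replace = TRUE), collapse = "")
}

#' @rdname generate_genome
#' @param genome A genome string.
#' @param read_length Read length; must not exceed the genome length.
#' @param coverage Mean per-base coverage; the number of reads is
#'   \code{ceiling(nchar(genome) * coverage / read_length)}.
#' @param n_rate Per-base probability of replacing a call with \code{N}.
#' @return \code{generate_reads}: a character vector of reads.
#' @export
generate_reads <- function(genome, read_length, coverage, seed = NULL,
                           n_rate = 0) {
  L <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length < 1L || read_length > L) {
    stop("read length must be between 1 and the genome length")
  }
  if (coverage <= 0) stop("coverage must be positive")
  if (n_rate < 0 || n_rate > 1) stop("n_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_reads <- as.integer(ceiling(L * coverage / read_length))
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1L)
  if (n_rate > 0) {
    reads <- vapply(reads, function(r) {
      hit <- which(stats::runif(read_length) < n_rate)
      if (length(hit) > 0L) {
        ch <- strsplit(r, "", fixed = TRUE)[[1L]]
        ch[hit] <- "N"
        r <- paste(ch, collapse = "")
      }
      r
    }, character(1), USE.NAMES = FALSE)
  }
  reads
}

#' @rdname generate_genome
#' @param size Number of distinct canonical k-mers to return.
#' @param k k-mer length.
#' @return \code{random_kmer_set}: a \code{\link{kmer_set}} of \code{size}
#'   distinct canonical k-mers.
#' @export
random_kmer_set <- function(size, k, seed = NULL, ab = dna_alphabet()) {
  size <- as.integer(size)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  n_canonical <- ceiling(length(ab$symbols)^k / 2)
  if (size > n_canonical) {
    stop("only ", n_canonical, " canonical ", k, "-mers exist")
  }
  if (!is.null(seed)) set.seed(seed)
  found <- character(0)
  while (length(found) < size) {
    draw <- vapply(seq_len(2L * size), function(i) {
      paste(sample(ab$symbols, k, replace = TRUE), collapse = "")
    }, character(1))
    found <- unique(c(found, .canonical(draw, ab)))
  }
  kmer_set(sort(found[seq_len(size)]), k, ab)
}
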