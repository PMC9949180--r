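# Canonical k-mer spectra and SPSS verification.

#' Construct a canonical k-mer set
#'
#' Container for a deduplicated set of canonical k-mers of a common length k
#' (the canonical k-spectrum of some input). Members are validated to be
#' canonical, distinct and of length k, and are stored sorted.
#'
#' @param kmers Character vector of canonical k-mers.
#' @param k k-mer length; inferred from \code{kmers} when missing.
#' @param ab Alphabet.
#' @return An object of class \code{kmer_set} with fields \code{k},
#'   \code{kmers} (sorted) and \code{alphabet}.
#' @export
kmer_set <- function(kmers, k = NULL, ab = dna_alphabet()) {
  kmers <- as.character(kmers)
  if (is.null(k)) {
    if (length(kmers) == 0L) stop("cannot infer k from an empty k-mer set")
    k <- nchar(kmers[1L])
  }
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (length(kmers) > 0L) {
    if (!all(nchar(kmers) == k)) stop("all k-mers must have length k = ", k)
    .assert_alphabet(kmers, ab)
    if (anyDuplicated(kmers)) stop("k-mers must be distinct")
    if (!all(kmers == .canonical(kmers, ab))) {
      stop("all k-mers must be canonical (<= their reverse complement)")
    }
  }
  structure(list(k = k, kmers = sort(kmers), alphabet = ab),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("Canonical k-mer set: ", length(x$kmers), " k-mers, k = ", x$k, "\n",
      sep = "")
  if (length(x$kmers) > 0L) {
    shown <- utils::head(x$kmers, 10L)
    cat("  ", paste(shown, collapse = " "),
        if (length(x$kmers) > 10L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$kmers)

# Split input strings into clean segments: uppercase, break at any character
# outside the alphabet, drop segments shorter than k. Returns the segments and
# the number of dropped short segments.
.split_segments <- function(strings, k, ab) {
  strings <- toupper(as.character(strings))
  parts <- unlist(strsplit(strings, .non_alphabet_class(ab)), use.names = FALSE)
  parts <- parts[nchar(parts) > 0L]
  keep <- nchar(parts) >= k
  list(segments = parts[keep], dropped = sum(!keep))
}

# All length-k windows of a single segment.
.windows <- function(s, k) {
  n <- nchar(s)
  substring(s, seq_len(n - k + 1L), k:n)
}

# All length-k windows across a character vector of segments.
.all_windows <- function(segments, k) {
  if (length(segments) == 0L) return(character(0))
  unlist(lapply(segments, .windows, k = k), use.names = FALSE)
}

#' Canonical k-spectrum of a string set
#'
#' Computes the set of canonical forms of every length-k substring of the
#' input strings (identifying each k-mer with its reverse complement).
#' Multiplicities and strands are discarded: each canonical k-mer appears
#' once. Input is uppercased; characters outside the alphabet split a string
#' into segments, and segments shorter than k are dropped with a message
#' stating the count.
#'
#' @param strings Character vector of input strings (e.g. reads or contigs).
#' @param k k-mer length, at least 2.
#' @param ab Alphabet.
#' @return A \code{\link{kmer_set}}.
#' @examples
#' canonical_spectrum(c("GAATG", "ATCTGCT"), 3)
#' @export
canonical_spectrum <- function(strings, k, ab = dna_alphabet()) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  sp <- .split_segments(strings, k, ab)
  if (sp$dropped > 0L) {
    message(sp$dropped, " segment(s) shorter than k = ", k, " dropped")
  }
  if (length(sp$segments) == 0L) {
    warning("no segment of length >= k; the spectrum is empty")
    return(kmer_set(character(0), k, ab))
  }
  w <- .all_windows(sp$segments, k)
  kmer_set(sort(unique(.canonical(w, ab))), k, ab)
}

#' Canonical k-mers above an abundance threshold
#'
#' Counts the occurrences of each canonical k-mer over all windows of all
#' input strings (both strands identified) and keeps those occurring at least
#' \code{threshold} times. With \code{threshold = 1} this equals
#' \code{\link{canonical_spectrum}}. Used to discard likely sequencing errors
#' when the input is a read set.
#'
#' @inheritParams canonical_spectrum
#' @param threshold Minimum abundance, at least 1.
#' @return A \code{\link{kmer_set}}.
#' @export
min_abundance_filter <- function(strings, k, threshold = 1L, ab = dna_alphabet()) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) stop("threshold must be at least 1")
  sp <- .split_segments(strings, k, ab)
  if (sp$dropped > 0L) {
    message(sp$dropped, " segment(s) shorter than k = ", k, " dropped")
  }
  if (length(sp$segments) == 0L) {
    warning("no segment of length >= k; the spectrum is empty")
    return(kmer_set(character(0), k, ab))
  }
  counts <- table(.canonical(.all_windows(sp$segments, k), ab))
  kmer_set(sort(names(counts)[counts >= threshold]), k, ab)
}

#' Verify a spectrum-preserving string set
#'
#' Checks whether a candidate string set has the same canonical k-spectrum as
#' the input, and counts repeated k-mer windows in the candidate: the total
#' number of length-k windows across the candidate strings minus the number of
#' distinct canonical k-mers they contain. A value of 0 means every canonical
#' k-mer occupies exactly one window, i.e. the representation has no
#' repetitions.
#'
#' @param input_strings,candidate_strings Character vectors of strings.
#' @param k k-mer length.
#' @param ab Alphabet.
#' @return A list of class \code{spss_report} with fields
#'   \code{spectra_equal}, \code{repeated_kmer_positions},
#'   \code{missing_kmers} (in input but not candidate) and \code{extra_kmers}
#'   (in candidate but not input).
#' @examples
#' verify_spss(c("GAATG", "ATCTGCT"), c("ATC", "AGAATGCTG"), 3)
#' @export
verify_spss <- function(input_strings, candidate_strings, k, ab = dna_alphabet()) {
  k <- as.integer(k)
  in_sp <- suppressMessages(canonical_spectrum(input_strings, k, ab))
  cand_segments <- .split_segments(candidate_strings, k, ab)$segments
  if (length(cand_segments) == 0L) {
    cand_kmers <- character(0)
    n_windows <- 0L
  } else {
    w <- .canonical(.all_windows(cand_segments, k), ab)
    cand_kmers <- unique(w)
    n_windows <- length(w)
  }
  structure(
    list(
      spectra_equal = setequal(in_sp$kmers, cand_kmers),
      repeated_kmer_positions = n_windows - length(cand_kmers),
      missing_kmers = length(setdiff(in_sp$kmers, cand_kmers)),
      extra_kmers = length(setdiff(cand_kmers, in_sp$kmers)),
      k = k
    ),
    class = "spss_report"
  )
}

#' @export
print.spss_report <- function(x, ...) {
  cat("SPSS verification (k = ", x$k, ")\n", sep = "")
  cat("  spectra equal:       ", x$spectra_equal, "\n", sep = "")
  cat("  repeated k-mer windows: ", x$repeated_kmer_positions, "\n", sep = "")
  if (!x$spectra_equal) {
    cat("  missing k-mers: ", x$missing_kmers,
        ", extra k-mers: ", x$extra_kmers, "\n", sep = "")
  }
  invisible(x)
}
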