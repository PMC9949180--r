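# Alphabets with a self-inverse complement function.

#' Define an alphabet with a complement function
#'
#' An alphabet is an ordered set of single-character symbols together with a
#' self-inverse complement mapping (applying it twice returns the original
#' symbol). The default DNA alphabet pairs A with T and C with G.
#'
#' @param symbols Character vector of distinct single-character symbols; their
#'   order defines the lexicographic order used for canonical k-mers (via the
#'   native string collation, so symbols should be ASCII and given in sorted
#'   order for the usual conventions to apply).
#' @param complement Named character vector mapping every symbol to its
#'   complement; must be self-inverse.
#' @return An object of class \code{kmer_alphabet}.
#' @examples
#' dna_alphabet()
#' alphabet(c("0", "1"), c("0" = "1", "1" = "0"))
#' @export
alphabet <- function(symbols, complement) {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be distinct")
  if (is.null(names(complement)) || !setequal(names(complement), symbols)) {
    stop("'complement' must be a named vector covering every symbol")
  }
  complement <- complement[symbols]
  if (!all(unname(complement[complement]) == symbols)) {
    stop("complement function must be self-inverse")
  }
  structure(
    list(
      symbols = symbols,
      complement = complement,
      chartr_from = paste(symbols, collapse = ""),
      chartr_to = paste(unname(complement), collapse = "")
    ),
    class = "kmer_alphabet"
  )
}

#' @rdname alphabet
#' @export
dna_alphabet <- function() {
  alphabet(c("A", "C", "G", "T"), c(A = "T", C = "G", G = "C", T = "A"))
}

#' @export
print.kmer_alphabet <- function(x, ...) {
  cat("Alphabet {", paste(x$symbols, collapse = ", "), "} with complement ",
      paste(sprintf("%s<->%s", x$symbols, x$complement), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Regex character class matching anything NOT in the alphabet.
.non_alphabet_class <- function(ab) {
  esc <- gsub("([][^\\\\-])", "\\\\\\1", ab$symbols)
  paste0("[^", paste(esc, collapse = ""), "]+")
}

.assert_alphabet <- function(x, ab) {
  bad <- grepl(.non_alphabet_class(ab), x)
  if (any(bad)) {
    chars <- regmatches(x[bad][1], regexpr(.non_alphabet_class(ab), x[bad][1]))
    stop("string contains symbols outside the alphabet (e.g. '", chars, "')")
  }
  invisible(TRUE)
}

# Reverse every string in a character vector. Fixed-width vectors are reversed
# column-wise which is much faster than per-string splitting.
.reverse_strings <- function(x) {
  if (length(x) == 0L) return(character(0))
  w <- nchar(x)
  if (all(w == w[1L]) && w[1L] > 0L) {
    cols <- lapply(seq_len(w[1L]), function(i) substr(x, i, i))
    do.call(paste0, rev(cols))
  } else {
    vapply(x, function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Reverse complement of strings
#'
#' Reverses each string and complements every symbol. The operation is a
#' self-inverse: \code{reverse_complement(reverse_complement(w))} equals
#' \code{w}.
#'
#' @param x Character vector of alphabet strings.
#' @param ab Alphabet, by default DNA.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("GAATG")  # "CATTC"
#' @export
reverse_complement <- function(x, ab = dna_alphabet()) {
  .assert_alphabet(x, ab)
  .rc(x, ab)
}

# internal fast path: no validation
.rc <- function(x, ab) {
  .reverse_strings(chartr(ab$chartr_from, ab$chartr_to, x))
}

#' Canonical form of k-mers
#'
#' A k-mer is canonical when it is lexicographically smaller than or equal to
#' its reverse complement. This returns the canonical form of each input
#' together with its status: \code{"canonical"} (input already canonical),
#' \code{"not-canonical"} (the reverse complement was returned) or
#' \code{"self-complemental"} (the input equals its own reverse complement,
#' which is possible only at even length).
#'
#' @param x Character vector of alphabet strings.
#' @param ab Alphabet.
#' @return A data.frame with columns \code{input}, \code{canonical} and
#'   \code{status}.
#' @examples
#' canonicalize(c("TCT", "GAA", "ACGT"))
#' @export
canonicalize <- function(x, ab = dna_alphabet()) {
  if (any(nchar(x) == 0L)) stop("k-mers must be non-empty")
  .assert_alphabet(x, ab)
  r <- .rc(x, ab)
  canon <- ifelse(x <= r, x, r)
  status <- ifelse(x == r, "self-complemental",
                   ifelse(x <= r, "canonical", "not-canonical"))
  data.frame(input = x, canonical = canon, status = status,
             stringsAsFactors = FALSE)
}

# internal: canonical strings only
.canonical <- function(x, ab) {
  r <- .rc(x, ab)
  ifelse(x <= r, x, r)
}
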