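# Sequence and graph I/O.

#' Read sequences from FASTA or FASTQ
#'
#' Wrapped multi-record FASTA and FASTQ are both supported (qualities are
#' ignored). The format is taken from the file extension
#' (\code{.fq}/\code{.fastq} mean FASTQ) unless given explicitly.
#'
#' @param path Path to the file.
#' @param format \code{"auto"}, \code{"fasta"} or \code{"fastq"}.
#' @return Named character vector of sequences (uppercased).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readBStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param strings Character vector of sequences.
#' @param path Output path.
#' @param headers Record headers; defaults to \code{seq_1}, \code{seq_2}, ...
#' @return The path, invisibly.
#' @export
write_fasta <- function(strings, path, headers = NULL) {
  x <- Biostrings::BStringSet(strings)
  names(x) <- if (is.null(headers)) {
    paste0("seq_", seq_along(strings))
  } else {
    headers
  }
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# Write an spss result as FASTA with informative headers plus a JSON stats
# sidecar carrying the run configuration.
.write_spss <- function(res, fasta_path, stats_path = NULL, config = list()) {
  k <- res$k
  headers <- sprintf("tig_%d length=%d kmers=%d", seq_along(res$strings),
                     nchar(res$strings), nchar(res$strings) - k + 1L)
  write_fasta(res$strings, fasta_path, headers)
  if (!is.null(stats_path)) {
    stats <- list(
      algorithm = res$algorithm,
      k = k,
      n_kmers = res$n_kmers,
      n_components = res$n_components,
      imbalance = res$imbalance,
      breaking_arcs = res$breaking_arcs,
      CL = res$CL,
      SC = res$SC,
      config = config
    )
    jsonlite::write_json(stats, stats_path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  }
  invisible(fasta_path)
}

#' Dump or load a bidirected graph in a GFA1-style text form
#'
#' Debugging format: an \code{H} header line carrying k, one \code{S} line
#' per node (\code{S <id> <mer>} with an \code{SC:i:1} tag on
#' self-complemental nodes), and one \code{L} line per arc:
#' \code{L <tail> <sign> <head> <sign> <label>} where signs are \code{+},
#' \code{-} or \code{.} and breaking arcs carry \code{*} as label. This
#' deviates from strict GFA1 in carrying the dot sign and arc labels, which
#' plain GFA cannot express.
#'
#' @param g A \code{bigraph}.
#' @param path Output (input) path.
#' @return \code{write_gfa}: the path invisibly; \code{read_gfa}: a
#'   \code{bigraph}.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tKK:i:%d", g$k), con)
  sc_tag <- ifelse(g$node_selfc, "\tSC:i:1", "")
  writeLines(sprintf("S\t%d\t%s%s", seq_len(n_nodes(g)), g$node_mer, sc_tag),
             con)
  if (n_arcs(g) > 0L) {
    writeLines(sprintf(
      "L\t%d\t%s\t%d\t%s\t%s",
      g$tail, unname(SIGN_CHAR[as.character(g$tsign)]),
      g$head, unname(SIGN_CHAR[as.character(g$hsign)]),
      ifelse(g$breaking, "*", g$label)
    ), con)
  }
  invisible(path)
}

#' @rdname write_gfa
#' @param ab Alphabet for the loaded graph.
#' @export
read_gfa <- function(path, ab = dna_alphabet()) {
  lines <- readLines(path)
  type <- substr(lines, 1L, 1L)
  h <- strsplit(lines[type == "H"][1L], "\t", fixed = TRUE)[[1L]]
  kk <- h[grepl("^KK:i:", h)]
  if (length(kk) != 1L) stop("missing KK:i tag in GFA header")
  k <- as.integer(sub("^KK:i:", "", kk))
  s <- strsplit(lines[type == "S"], "\t", fixed = TRUE)
  node_id <- vapply(s, function(f) as.integer(f[2L]), integer(1))
  node_mer <- vapply(s, `[`, character(1), 3L)
  ord <- order(node_id)
  node_mer <- node_mer[ord]
  sign_of <- function(ch) c(`+` = 1L, `-` = -1L, `.` = 0L)[ch]
  l <- strsplit(lines[type == "L"], "\t", fixed = TRUE)
  lab <- vapply(l, `[`, character(1), 6L)
  .new_bigraph(
    k, node_mer, node_mer == .rc(node_mer, ab),
    vapply(l, function(f) as.integer(f[2L]), integer(1)),
    unname(sign_of(vapply(l, `[`, character(1), 3L))),
    vapply(l, function(f) as.integer(f[4L]), integer(1)),
    unname(sign_of(vapply(l, `[`, character(1), 5L))),
    ifelse(lab == "*", NA_character_, lab),
    lab == "*", ab
  )
}
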