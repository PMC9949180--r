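# Eulerisation, bidirected Eulerian cycles, cycle breaking and walk spelling:
# the minimum-SPSS pipeline.

.new_walk <- function(uid, forward, is_cycle = FALSE) {
  structure(list(uid = as.integer(uid), forward = as.logical(forward),
                 is_cycle = is_cycle),
            class = "bigraph_walk")
}

#' @export
print.bigraph_walk <- function(x, ...) {
  cat(if (x$is_cycle) "Cycle" else "Walk", "of", length(x$uid), "steps\n")
  invisible(x)
}

#' @export
length.bigraph_walk <- function(x) length(x$uid)

# States visited by a walk: from/to (node, sign) per step, in traversal
# orientation.
.walk_states <- function(w, g) {
  fwd <- w$forward
  list(
    from_node = ifelse(fwd, g$tail[w$uid], g$head[w$uid]),
    from_sign = ifelse(fwd, g$tsign[w$uid], g$hsign[w$uid]),
    to_node = ifelse(fwd, g$head[w$uid], g$tail[w$uid]),
    to_sign = ifelse(fwd, g$hsign[w$uid], g$tsign[w$uid])
  )
}

# Continuity: consecutive steps share a node with negated signs; cycles wrap.
.validate_walk <- function(w, g) {
  s <- .walk_states(w, g)
  l <- length(w$uid)
  if (l <= 1L && !w$is_cycle) return(invisible(TRUE))
  i <- seq_len(l - 1L)
  ok <- s$to_node[i] == s$from_node[i + 1L] &
    s$to_sign[i] == -s$from_sign[i + 1L]
  if (!all(ok)) {
    stop("walk continuity violated at step ", which(!ok)[1L])
  }
  if (w$is_cycle && l > 0L) {
    if (!(s$to_node[l] == s$from_node[1L] &&
          s$to_sign[l] == -s$from_sign[1L])) {
      stop("cycle does not close: end state does not match start state")
    }
  }
  invisible(TRUE)
}

#' Eulerise a connected bidirected graph by adding breaking arcs
#'
#' Builds a list of unbalanced incidences in ascending node-id order: one dot
#' incidence for each self-complemental node of odd degree, and, for each
#' normal node with imbalance i, |i| copies of an incoming incidence when
#' i > 0 (an excess of outgoing arcs is cancelled by extra incoming ones) or
#' of an outgoing incidence when i < 0. Consecutive entries of the list are
#' paired into label-less breaking arcs. The list always has even length
#' because the graph imbalance is even, and the returned graph has imbalance
#' zero at every node, with imbalance(g)/2 breaking arcs added.
#'
#' @param g A connected \code{bigraph}.
#' @return The graph augmented with breaking arcs (flagged, \code{NA} label).
#' @export
eulerise <- function(g) {
  if (n_arcs(g) > 0L && connected_components(g)$n_components != 1L) {
    stop("eulerise requires a connected graph; split into components first")
  }
  dr <- degrees_and_imbalance(g)
  imb <- dr$nodes$imbalance
  node <- integer(0)
  sign <- integer(0)
  for (v in seq_len(n_nodes(g))) {
    if (imb[v] == 0L) next
    if (g$node_selfc[v]) {
      node <- c(node, v); sign <- c(sign, 0L)
    } else {
      node <- c(node, rep(v, abs(imb[v])))
      sign <- c(sign, rep(if (imb[v] > 0L) -1L else 1L, abs(imb[v])))
    }
  }
  stopifnot(length(node) %% 2L == 0L)
  if (length(node) == 0L) return(g)
  odd <- seq(1L, length(node), by = 2L)
  g$tail <- c(g$tail, node[odd]); g$tsign <- c(g$tsign, sign[odd])
  g$head <- c(g$head, node[odd + 1L]); g$hsign <- c(g$hsign, sign[odd + 1L])
  g$label <- c(g$label, rep(NA_character_, length(odd)))
  g$breaking <- c(g$breaking, rep(TRUE, length(odd)))
  g
}

#' Eulerian cycle of a balanced connected bidirected graph
#'
#' Hierholzer-style search adapted to signed incidences: a walk arriving at a
#' node with sign d must depart through an incidence with sign -d. Each arc is
#' used exactly once, either forwards or reversed. Per-state cursors into the
#' adjacency lists ensure no departure candidate is scanned twice, keeping the
#' total work linear in the number of arcs. The search starts at the
#' smallest-uid arc in forward orientation and always takes the
#' smallest-uid unused continuation (forward orientation preferred), so the
#' output is deterministic.
#'
#' @param g A connected \code{bigraph} with every node balanced (imbalance
#'   zero) and at least one arc; typically the output of
#'   \code{\link{eulerise}}.
#' @return A \code{bigraph_walk} with \code{is_cycle = TRUE} covering every
#'   arc exactly once.
#' @export
eulerian_cycle <- function(g) {
  m <- n_arcs(g)
  if (m == 0L) stop("eulerian_cycle requires at least one arc")
  dr <- degrees_and_imbalance(g)
  bad <- which(dr$nodes$imbalance != 0L)
  if (length(bad) > 0L) {
    stop("graph is not Eulerian: node '", g$node_mer[bad[1L]],
         "' has imbalance ", dr$nodes$imbalance[bad[1L]])
  }
  tr <- .traversals(g)
  adj <- .state_adjacency(g, tr)
  cur <- rep(1L, length(adj))
  used <- logical(m)

  st_state <- integer(m + 1L)
  st_step <- integer(m + 1L)
  top <- 1L
  st_state[1L] <- .state_key(tr$from_node[1L], tr$from_sign[1L])
  st_step[1L] <- 0L
  out <- integer(m)
  nout <- 0L
  while (top > 0L) {
    s <- st_state[top]
    cand <- adj[[s]]
    i <- cur[s]
    while (i <= length(cand) && used[tr$arc[cand[i]]]) i <- i + 1L
    cur[s] <- i
    if (i <= length(cand)) {
      t <- cand[i]
      used[tr$arc[t]] <- TRUE
      top <- top + 1L
      st_state[top] <- .state_key(tr$to_node[t], -tr$to_sign[t])
      st_step[top] <- t
    } else {
      if (st_step[top] > 0L) {
        nout <- nout + 1L
        out[nout] <- st_step[top]
      }
      top <- top - 1L
    }
  }
  if (nout < m) {
    stop("graph is not connected: Eulerian cycle covers only ", nout,
         " of ", m, " arcs")
  }
  steps <- rev(out[seq_len(nout)])
  w <- .new_walk(tr$arc[steps], tr$forward[steps], is_cycle = TRUE)
  .validate_walk(w, g)
  w
}

#' Break an Eulerian cycle at the breaking arcs
#'
#' Removes every breaking-arc step from the cycle; the maximal runs of
#' real-arc steps between breaking arcs become open walks (the cycle wraps, so
#' the run after the last breaking arc joins the run before the first). With
#' zero breaking arcs the cycle is opened into a single walk before its
#' smallest-uid step; with one breaking arc a single walk results. Two
#' adjacent breaking arcs would produce an empty segment, which the sign
#' bookkeeping of Eulerisation makes impossible; encountering one raises an
#' error since it would signal a construction bug.
#'
#' @param cycle A \code{bigraph_walk} cycle from \code{\link{eulerian_cycle}}.
#' @param g The Eulerised \code{bigraph} the cycle lives in.
#' @return A list of open \code{bigraph_walk}s covering all real arcs.
#' @export
break_cycle <- function(cycle, g) {
  l <- length(cycle$uid)
  if (l == 0L) return(list())
  br <- g$breaking[cycle$uid]
  if (!any(br)) {
    p <- which.min(cycle$uid)
    ord <- c(seq.int(p, l), if (p > 1L) seq_len(p - 1L))
    return(list(.new_walk(cycle$uid[ord], cycle$forward[ord])))
  }
  # rotate so that the first breaking step ends up in the last position
  first_break <- which(br)[1L]
  ord <- if (first_break == l) seq_len(l) else
    c(seq.int(first_break + 1L, l), seq_len(first_break))
  uid <- cycle$uid[ord]
  fwd <- cycle$forward[ord]
  cuts <- which(g$breaking[uid])
  walks <- list()
  prev <- 0L
  for (cut in cuts) {
    if (cut == prev + 1L) {
      stop("adjacent breaking arcs produced an empty segment; ",
           "this indicates a construction bug")
    }
    idx <- seq.int(prev + 1L, cut - 1L)
    walks[[length(walks) + 1L]] <- .new_walk(uid[idx], fwd[idx])
    prev <- cut
  }
  walks
}

#' Spell the string of a walk
#'
#' The k-mer sequence of a walk takes each arc label as-is for a forward step
#' and reverse-complemented for a reversed step; consecutive k-mers (or merged
#' labels, on a compacted graph) overlap by k-1 characters, so the spelled
#' string is the first label followed by the non-overlapping tail of each
#' subsequent label. The overlap is checked and a continuity violation is
#' reported with the offending step index.
#'
#' @param w A \code{bigraph_walk} whose steps are all real arcs.
#' @param g The \code{bigraph} the walk lives in.
#' @return The spelled string (empty string for an empty walk).
#' @examples
#' g <- build_dbg(canonical_spectrum("GAAT", 3))
#' spell_walk(eulertigs:::.new_walk(c(1, 2), c(TRUE, TRUE)), g)  # "GAAT"
#' @export
spell_walk <- function(w, g) {
  if (length(w$uid) == 0L) return("")
  if (any(g$breaking[w$uid])) {
    stop("walk contains breaking arcs; break the cycle first")
  }
  k <- g$k
  lab <- g$label[w$uid]
  km <- ifelse(w$forward, lab, .rc(lab, g$alphabet))
  if (length(km) > 1L) {
    suf <- substring(km[-length(km)], nchar(km[-length(km)]) - k + 2L)
    pre <- substr(km[-1L], 1L, k - 1L)
    bad <- which(suf != pre)
    if (length(bad) > 0L) {
      stop("walk continuity violated at step ", bad[1L] + 1L,
           ": labels do not overlap by k-1")
    }
  }
  paste0(km[1L], paste(substring(km[-1L], k), collapse = ""))
}

# Run eulerise -> eulerian_cycle -> break_cycle -> spell on one connected
# component. Returns spelled strings, walks and the breaking-arc count.
.component_eulertigs <- function(sub) {
  if (n_arcs(sub) == 0L) {
    return(list(strings = character(0), walks = list(), breaking = 0L))
  }
  ge <- eulerise(sub)
  cyc <- eulerian_cycle(ge)
  walks <- break_cycle(cyc, ge)
  list(
    strings = vapply(walks, spell_walk, character(1), g = ge),
    walks = walks,
    breaking = sum(ge$breaking)
  )
}

.new_spss <- function(strings, k, algorithm, n_kmers, n_components,
                      imbalance = NA_integer_, breaking_arcs = NA_integer_,
                      walks = NULL) {
  structure(
    list(
      strings = strings,
      CL = sum(nchar(strings)),
      SC = length(strings),
      k = k,
      algorithm = algorithm,
      n_kmers = n_kmers,
      n_components = n_components,
      imbalance = imbalance,
      breaking_arcs = breaking_arcs,
      walks = walks
    ),
    class = "spss"
  )
}

#' @export
print.spss <- function(x, ...) {
  cat("SPSS (", x$algorithm, "), k = ", x$k, "\n", sep = "")
  cat("  strings (SC):      ", x$SC, "\n", sep = "")
  cat("  cumulative length: ", x$CL, "\n", sep = "")
  cat("  k-mers:            ", x$n_kmers, " in ", x$n_components,
      " component(s)\n", sep = "")
  if (!is.na(x$imbalance)) {
    cat("  imbalance:         ", x$imbalance, " (", x$breaking_arcs,
        " breaking arcs)\n", sep = "")
  }
  invisible(x)
}

#' Compute Eulertigs: a minimum SPSS without repetitions
#'
#' The full pipeline: canonical k-spectrum, de Bruijn graph construction
#' (optionally compacted), and then per connected component Eulerisation,
#' bidirected Eulerian cycle, cycle breaking and walk spelling. The output
#' string set has the same canonical k-spectrum as the input, uses every
#' canonical k-mer at exactly one window, and attains the imbalance lower
#' bound: its string count is the sum over components of max(1,
#' imbalance/2) and its cumulative length is
#' n_kmers + (k-1) * string_count, the minimum possible. Both identities are
#' asserted on every run. Each output string is emitted in canonical
#' orientation and the set is sorted, making results byte-reproducible
#' (minimum SPSSs are not unique; only CL and SC are).
#'
#' @param strings Character vector of input strings; ignored when
#'   \code{kmers} is given.
#' @param k k-mer length, at least 2.
#' @param ab Alphabet.
#' @param compact Compact the graph before the Eulerian phase (identical CL
#'   and SC either way; compaction shrinks the graph).
#' @param min_abundance Keep only canonical k-mers occurring at least this
#'   many times in the input.
#' @param kmers Optional \code{\link{kmer_set}} to use directly instead of
#'   computing the spectrum of \code{strings}.
#' @return An object of class \code{spss}: \code{strings}, \code{CL}
#'   (cumulative length), \code{SC} (string count), \code{n_kmers},
#'   \code{n_components}, \code{imbalance}, \code{breaking_arcs} and the
#'   per-component \code{walks}.
#' @examples
#' compute_eulertigs(c("GAATG", "ATCTGCT"), 3)
#' @export
compute_eulertigs <- function(strings = NULL, k = NULL, ab = dna_alphabet(),
                              compact = TRUE, min_abundance = 1L,
                              kmers = NULL) {
  if (is.null(kmers)) {
    if (is.null(strings) || is.null(k)) {
      stop("provide input strings and k, or a kmer_set")
    }
    kmers <- if (min_abundance > 1L) {
      min_abundance_filter(strings, k, min_abundance, ab)
    } else {
      canonical_spectrum(strings, k, ab)
    }
  }
  k <- kmers$k
  if (length(kmers) == 0L) {
    warning("empty k-mer spectrum; returning an empty SPSS")
    return(.new_spss(character(0), k, "eulertigs", 0L, 0L, 0L, 0L, list()))
  }
  g <- build_dbg(kmers)
  if (compact) g <- compact_dbg(g)
  cc <- connected_components(g)
  comp_strings <- character(0)
  walks <- vector("list", cc$n_components)
  breaking <- 0L
  comp_imb <- integer(cc$n_components)
  for (ci in seq_len(cc$n_components)) {
    sub <- .subgraph(g, which(cc$arc_component == ci))
    comp_imb[ci] <- degrees_and_imbalance(sub)$imbalance
    res <- .component_eulertigs(sub)
    comp_strings <- c(comp_strings, res$strings)
    walks[[ci]] <- res$walks
    breaking <- breaking + res$breaking
  }
  out <- sort(.canonical(comp_strings, g$alphabet))
  n_kmers <- .n_label_kmers(g)
  result <- .new_spss(out, k, "eulertigs", n_kmers, cc$n_components,
                      sum(comp_imb), breaking, walks)
  # tightness and bookkeeping guarantees; these hold by construction
  stopifnot(
    sum(comp_imb) %% 2L == 0L,
    result$SC == sum(pmax(1L, comp_imb %/% 2L)),
    result$CL == n_kmers + (k - 1L) * result$SC
  )
  result
}

#' Imbalance lower bound on SPSS size
#'
#' For each connected component of the de Bruijn graph, a walk cover without
#' repetitions needs at least max(1, imbalance/2) walks, where the component
#' imbalance is the sum of absolute node imbalances (each unbalanced node
#' forces walk ends). Every walk spends k-1 characters on its overlapless
#' margin, so the minimum cumulative length is
#' n_kmers + (k-1) * minimum_string_count. The Eulertig pipeline attains this
#' bound.
#'
#' @inheritParams compute_eulertigs
#' @return A list of class \code{spss_bound}: \code{per_component}
#'   (data.frame with component, n_kmers, imbalance, min_SC), \code{min_SC},
#'   \code{min_CL}, \code{n_kmers} and \code{k}.
#' @examples
#' spss_lower_bound(c("GAATG", "ATCTGCT"), 3)
#' @export
spss_lower_bound <- function(strings = NULL, k = NULL, ab = dna_alphabet(),
                             kmers = NULL) {
  if (is.null(kmers)) {
    if (is.null(strings) || is.null(k)) {
      stop("provide input strings and k, or a kmer_set")
    }
    kmers <- canonical_spectrum(strings, k, ab)
  }
  k <- kmers$k
  g <- build_dbg(kmers)
  cc <- connected_components(g)
  per <- data.frame(component = seq_len(cc$n_components),
                    n_kmers = integer(cc$n_components),
                    imbalance = integer(cc$n_components),
                    min_SC = integer(cc$n_components))
  for (ci in seq_len(cc$n_components)) {
    arcs <- which(cc$arc_component == ci)
    sub <- .subgraph(g, arcs)
    per$n_kmers[ci] <- length(arcs)
    per$imbalance[ci] <- degrees_and_imbalance(sub)$imbalance
    per$min_SC[ci] <- max(1L, per$imbalance[ci] %/% 2L)
  }
  min_sc <- sum(per$min_SC)
  structure(
    list(per_component = per,
         min_SC = min_sc,
         min_CL = length(kmers) + (k - 1L) * min_sc,
         n_kmers = length(kmers),
         k = k),
    class = "spss_bound"
  )
}

#' @export
print.spss_bound <- function(x, ...) {
  cat("SPSS lower bound, k = ", x$k, ": min SC = ", x$min_SC,
      ", min CL = ", x$min_CL, " over ", nrow(x$per_component),
      " component(s), ", x$n_kmers, " k-mers\n", sep = "")
  invisible(x)
}
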