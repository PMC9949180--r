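# Greedy SPSS heuristics: forward-only extension with walk joining
# (UST-style) and bidirectional extension (ProphAsm-style). Both cover every
# arc exactly once and preserve the spectrum, but unlike the Eulertig
# pipeline they need not reach the minimum cumulative length.

#' Seed orders for the greedy heuristics
#'
#' The greedy heuristics pick an arbitrary arc to seed each walk and an
#' arbitrary admissible continuation at every extension step; a seed order
#' pins those choices down so the output is fully determined. Three policies:
#' \describe{
#'   \item{ascending-uid}{Arcs in ascending uid, forward orientation before
#'     reversed (the default).}
#'   \item{kmers}{A supplied list of k-mers (in either orientation) tried
#'     first, in the given order; remaining traversals follow in ascending
#'     uid. A non-canonical k-mer selects the reversed traversal of its
#'     canonical arc. This is how adversarial or favourable extension orders
#'     are forced.}
#'   \item{random}{A seeded random permutation of all traversals.}
#' }
#'
#' @param policy One of \code{"ascending-uid"}, \code{"kmers"},
#'   \code{"random"}.
#' @param kmers Character vector of k-mers for \code{policy = "kmers"}.
#' @param seed Integer seed for \code{policy = "random"}.
#' @return An object of class \code{seed_order}.
#' @export
seed_order <- function(policy = c("ascending-uid", "kmers", "random"),
                       kmers = NULL, seed = NULL) {
  policy <- match.arg(policy)
  if (policy == "kmers" && (is.null(kmers) || length(kmers) == 0L)) {
    stop("policy 'kmers' requires a non-empty k-mer list")
  }
  if (policy == "random" && is.null(seed)) {
    stop("policy 'random' requires a seed")
  }
  structure(list(policy = policy, kmers = kmers, seed = seed),
            class = "seed_order")
}

# Resolve a seed order into a priority rank per traversal (1 = first).
.resolve_order <- function(order, g, tr) {
  nt <- 2L * tr$m
  base <- seq_len(nt)
  pri <- switch(order$policy,
    "ascending-uid" = base,
    "random" = {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(order$seed)
      sample(nt)
    },
    "kmers" = {
      km <- toupper(order$kmers)
      if (any(nchar(km) != g$k)) {
        stop("seed-order k-mers must have length k = ", g$k)
      }
      canon <- .canonical(km, g$alphabet)
      a <- match(canon, g$label)
      if (anyNA(a)) {
        stop("seed-order k-mer(s) not present in the graph: ",
             paste(km[is.na(a)], collapse = ", "))
      }
      t_idx <- ifelse(km == canon, 2L * a - 1L, 2L * a)
      if (anyDuplicated(t_idx)) stop("duplicate seed-order k-mers")
      c(t_idx, setdiff(base, t_idx))
    }
  )
  # pri lists traversal indices in priority order; invert to ranks
  rank <- integer(nt)
  rank[pri] <- seq_len(nt)
  rank
}

# Shared greedy engine. Extension and seeding both take the lowest-rank
# admissible unused traversal. "Forwards" extends at the head of the current
# walk; backward extension (ProphAsm) prepends the partner of the
# lowest-rank unused traversal departing against the walk's start state.
.greedy_tigs <- function(g, order, bidirectional, join, algorithm) {
  if (any(g$breaking)) stop("heuristics run on the graph without breaking arcs")
  m <- n_arcs(g)
  k <- g$k
  if (m == 0L) {
    return(.new_spss(character(0), k, algorithm, 0L, 0L))
  }
  tr <- .traversals(g)
  rank <- .resolve_order(order, g, tr)
  adj <- .state_adjacency(g, tr, priority = rank)
  cur <- rep(1L, length(adj))
  used <- logical(m)
  partner <- function(t) t + ifelse(t %% 2L == 1L, 1L, -1L)

  next_from <- function(state_key) {
    cand <- adj[[state_key]]
    i <- cur[state_key]
    while (i <= length(cand) && used[tr$arc[cand[i]]]) i <- i + 1L
    cur[state_key] <<- i
    if (i <= length(cand)) cand[i] else NA_integer_
  }

  seed_seq <- order(rank)  # traversal indices in priority order
  seed_ptr <- 1L
  walks <- list()
  buf <- integer(m)
  repeat {
    while (seed_ptr <= length(seed_seq) &&
           used[tr$arc[seed_seq[seed_ptr]]]) {
      seed_ptr <- seed_ptr + 1L
    }
    if (seed_ptr > length(seed_seq)) break
    t0 <- seed_seq[seed_ptr]
    used[tr$arc[t0]] <- TRUE
    nbuf <- 1L
    buf[1L] <- t0
    # extend forwards
    repeat {
      last <- buf[nbuf]
      t <- next_from(.state_key(tr$to_node[last], -tr$to_sign[last]))
      if (is.na(t)) break
      used[tr$arc[t]] <- TRUE
      nbuf <- nbuf + 1L
      buf[nbuf] <- t
    }
    steps <- buf[seq_len(nbuf)]
    if (bidirectional) {
      back <- integer(0)
      first <- steps[1L]
      repeat {
        u <- next_from(.state_key(tr$from_node[first], -tr$from_sign[first]))
        if (is.na(u)) break
        used[tr$arc[u]] <- TRUE
        first <- partner(u)
        back <- c(back, first)
      }
      steps <- c(rev(back), steps)
    }
    walks[[length(walks) + 1L]] <- steps
  }

  if (join && length(walks) > 1L) {
    # map each walk's start state to its first traversal; join a finished
    # walk to a walk starting at an admissible successor of its last arc,
    # scanning candidates in ascending traversal index
    consumed <- logical(length(walks))
    start_state <- vapply(walks, function(s) {
      .state_key(tr$from_node[s[1L]], tr$from_sign[s[1L]])
    }, integer(1))
    first_step <- vapply(walks, `[[`, integer(1), 1L)
    for (i in seq_along(walks)) {
      if (consumed[i]) next
      repeat {
        last <- walks[[i]][length(walks[[i]])]
        s_end <- .state_key(tr$to_node[last], -tr$to_sign[last])
        cand <- which(!consumed & start_state == s_end)
        cand <- cand[cand != i]
        if (length(cand) == 0L) break
        j <- cand[which.min(first_step[cand])]
        walks[[i]] <- c(walks[[i]], walks[[j]])
        consumed[j] <- TRUE
      }
    }
    walks <- walks[!consumed]
  }

  strings <- vapply(walks, function(s) {
    spell_walk(.new_walk(tr$arc[s], tr$forward[s]), g)
  }, character(1))
  out <- sort(.canonical(strings, g$alphabet))
  cc <- connected_components(g)
  .new_spss(out, k, algorithm, .n_label_kmers(g), cc$n_components)
}

#' Forward-extension heuristic with walk joining (UST-style)
#'
#' Repeatedly seeds a walk at the first unused arc in the seed order and
#' extends it forwards (at its head) with the first admissible unused
#' continuation, as long as possible. Afterwards, a finished walk is joined
#' to another walk that starts at an admissible successor of its last arc;
#' each join consumes the joined walk, and joining continues from the merged
#' end until no candidate remains. Every arc is used exactly once, so the
#' spectrum is preserved with zero repetitions, but the cumulative length may
#' exceed the minimum.
#'
#' @param g An (uncompacted or compacted) \code{bigraph} without breaking
#'   arcs.
#' @param order A \code{\link{seed_order}}.
#' @return An object of class \code{spss}.
#' @export
ust_tigs <- function(g, order = seed_order()) {
  .greedy_tigs(g, order, bidirectional = FALSE, join = TRUE, "ust")
}

#' Bidirectional-extension heuristic (ProphAsm-style)
#'
#' Like \code{\link{ust_tigs}} but each walk is extended both forwards (at
#' its head, first) and backwards (at its tail) as long as possible, and no
#' joining step is performed.
#'
#' @inheritParams ust_tigs
#' @return An object of class \code{spss}.
#' @export
prophasm_tigs <- function(g, order = seed_order()) {
  .greedy_tigs(g, order, bidirectional = TRUE, join = FALSE, "prophasm")
}

#' Unitigs: the compacted graph's arc labels
#'
#' The maximal non-branching path labels of the compacted de Bruijn graph,
#' reported as an SPSS. This is the baseline representation that the greedy
#' heuristics and the Eulertig pipeline improve upon.
#'
#' @inheritParams compute_eulertigs
#' @return An object of class \code{spss}.
#' @export
unitigs <- function(strings = NULL, k = NULL, ab = dna_alphabet(),
                    min_abundance = 1L, kmers = NULL) {
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
    return(.new_spss(character(0), k, "unitigs", 0L, 0L))
  }
  g <- compact_dbg(build_dbg(kmers))
  cc <- connected_components(g)
  .new_spss(sort(g$label), k, "unitigs", .n_label_kmers(g), cc$n_components)
}
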