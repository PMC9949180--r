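# Arc-centric bidirected de Bruijn graphs.
#
# Signs are stored as integers: +1 for an outgoing incidence, -1 for an
# incoming incidence, and 0 for the dot sign carried by self-complemental
# nodes. Sign negation is arithmetic negation (0 is its own negation).

SIGN_CHAR <- c(`-1` = "-", `0` = ".", `1` = "+")

.new_bigraph <- function(k, node_mer, node_selfc,
                         tail, tsign, head, hsign,
                         label, breaking, ab, compacted = FALSE) {
  structure(
    list(
      k = as.integer(k),
      node_mer = as.character(node_mer),
      node_selfc = as.logical(node_selfc),
      tail = as.integer(tail), tsign = as.integer(tsign),
      head = as.integer(head), hsign = as.integer(hsign),
      label = as.character(label),
      breaking = as.logical(breaking),
      alphabet = ab,
      compacted = compacted
    ),
    class = "bigraph"
  )
}

#' Number of nodes and arcs of a bidirected graph
#' @param g A \code{bigraph}.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(g$node_mer)

#' @rdname n_nodes
#' @export
n_arcs <- function(g) length(g$tail)

#' @export
print.bigraph <- function(x, ...) {
  cat("Bidirected de Bruijn graph (k = ", x$k, ")",
      if (x$compacted) ", compacted" else "", "\n", sep = "")
  cat("  nodes: ", n_nodes(x), " (", sum(x$node_selfc),
      " self-complemental)\n", sep = "")
  cat("  arcs:  ", n_arcs(x), " (", sum(x$breaking), " breaking)\n", sep = "")
  invisible(x)
}

#' Arc table of a bidirected graph
#'
#' @param x A \code{bigraph}.
#' @param ... Unused.
#' @return A data.frame with one row per arc: uid, tail/head node ids and
#'   mers, signed incidences (\code{+}, \code{-}, \code{.}), label and
#'   breaking flag.
#' @export
as.data.frame.bigraph <- function(x, ...) {
  data.frame(
    uid = seq_len(n_arcs(x)),
    tail = x$tail, tail_mer = x$node_mer[x$tail],
    tail_sign = unname(SIGN_CHAR[as.character(x$tsign)]),
    head = x$head, head_mer = x$node_mer[x$head],
    head_sign = unname(SIGN_CHAR[as.character(x$hsign)]),
    label = x$label, breaking = x$breaking,
    stringsAsFactors = FALSE
  )
}

#' Build the arc-centric bidirected de Bruijn graph of a k-mer set
#'
#' Nodes are the distinct canonical (k-1)-mers occurring as a prefix or
#' suffix of the k-mers; each canonical k-mer becomes one arc from the
#' canonical form of its (k-1)-prefix to the canonical form of its
#' (k-1)-suffix. The incidence signs encode strand: the tail incidence is
#' \code{+} when the prefix itself is canonical and \code{-} otherwise, the
#' head incidence is \code{-} when the suffix is canonical and \code{+}
#' otherwise, and both are \code{.} at self-complemental nodes. This is the
#' unique sign convention (up to a global flip) under which walk continuity
#' coincides with (k-1)-character overlap of the spelled k-mers; see
#' \code{\link{check_label_soundness}}.
#'
#' Node ids are dense integers assigned in first-encounter order while
#' scanning the sorted k-mers, and arc uids are 1..m in sorted label order,
#' so construction is deterministic.
#'
#' @param kmers A \code{\link{kmer_set}}, or a character vector of canonical
#'   k-mers of a common length.
#' @param ab Alphabet (ignored when \code{kmers} is a \code{kmer_set}).
#' @return A \code{bigraph}.
#' @examples
#' build_dbg(canonical_spectrum(c("GAATG", "ATCTGCT"), 3))
#' @export
build_dbg <- function(kmers, ab = dna_alphabet()) {
  if (inherits(kmers, "kmer_set")) {
    ab <- kmers$alphabet
    k <- kmers$k
    kmers <- kmers$kmers
  } else {
    kmers <- as.character(kmers)
    if (length(kmers) == 0L) stop("cannot infer k from an empty k-mer vector")
    if (length(unique(nchar(kmers))) > 1L) {
      stop("mixed k-mer lengths in input")
    }
    k <- nchar(kmers[1L])
    kmers <- kmer_set(kmers, k, ab)$kmers
  }
  if (length(kmers) == 0L) {
    return(.new_bigraph(k, character(0), logical(0),
                        integer(0), integer(0), integer(0), integer(0),
                        character(0), logical(0), ab))
  }
  pre <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  pre_rc <- .rc(pre, ab)
  suf_rc <- .rc(suf, ab)
  pre_can <- ifelse(pre <= pre_rc, pre, pre_rc)
  suf_can <- ifelse(suf <= suf_rc, suf, suf_rc)
  tsign <- ifelse(pre == pre_rc, 0L, ifelse(pre <= pre_rc, 1L, -1L))
  hsign <- ifelse(suf == suf_rc, 0L, ifelse(suf <= suf_rc, -1L, 1L))
  node_mer <- unique(as.vector(rbind(pre_can, suf_can)))
  .new_bigraph(
    k,
    node_mer, node_mer == .rc(node_mer, ab),
    match(pre_can, node_mer), tsign,
    match(suf_can, node_mer), hsign,
    kmers, rep(FALSE, length(kmers)), ab
  )
}

#' Per-node degrees and graph imbalance
#'
#' For a normal node, the outdegree counts its \code{+} incidences and the
#' indegree its \code{-} incidences over all arcs (a self-loop contributes
#' two incidences); its imbalance is outdegree minus indegree. For a
#' self-complemental node, only the total degree over \code{.} incidences is
#' defined and the imbalance is 1 when that degree is odd, 0 otherwise. The
#' graph imbalance is the sum of absolute node imbalances; it is always even.
#'
#' @param g A \code{bigraph}.
#' @return A list of class \code{degree_report}: \code{nodes} (data.frame
#'   with id, mer, self_complemental, outdegree, indegree, degree, imbalance)
#'   and \code{imbalance} (graph total).
#' @export
degrees_and_imbalance <- function(g) {
  n <- n_nodes(g)
  endpoint <- c(g$tail, g$head)
  sign <- c(g$tsign, g$hsign)
  outd <- tabulate(endpoint[sign == 1L], n)
  ind <- tabulate(endpoint[sign == -1L], n)
  deg <- tabulate(endpoint[sign == 0L], n)
  imb <- ifelse(g$node_selfc, deg %% 2L, outd - ind)
  structure(
    list(
      nodes = data.frame(
        id = seq_len(n), mer = g$node_mer,
        self_complemental = g$node_selfc,
        outdegree = ifelse(g$node_selfc, NA_integer_, outd),
        indegree = ifelse(g$node_selfc, NA_integer_, ind),
        degree = ifelse(g$node_selfc, deg, outd + ind),
        imbalance = as.integer(imb),
        stringsAsFactors = FALSE
      ),
      imbalance = sum(abs(imb))
    ),
    class = "degree_report"
  )
}

#' @export
print.degree_report <- function(x, ...) {
  cat("Degree report: ", nrow(x$nodes), " nodes, graph imbalance ",
      x$imbalance, "\n", sep = "")
  print(utils::head(x$nodes, 12L))
  if (nrow(x$nodes) > 12L) cat("  ...\n")
  invisible(x)
}

#' Connected components of a bidirected graph
#'
#' Connectivity over the undirected incidence structure (two nodes are
#' connected when an arc joins them, ignoring signs). Components are numbered
#' 1..n_components in order of their smallest node id.
#'
#' @param g A \code{bigraph}.
#' @return A list: \code{n_components}, \code{node_component} (integer per
#'   node), \code{arc_component} (integer per arc).
#' @export
connected_components <- function(g) {
  n <- n_nodes(g)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (a in seq_len(n_arcs(g))) {
    ri <- find(g$tail[a]); rj <- find(g$head[a])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  list(
    n_components = length(unique(roots)),
    node_component = comp,
    arc_component = if (n_arcs(g) > 0L) comp[g$tail] else integer(0)
  )
}

# Traversal bookkeeping shared by the Eulerian-cycle search, the greedy
# heuristics, compaction and the brute-force oracle. Each arc a yields two
# traversals: 2a-1 (forward, from the tail incidence to the head incidence)
# and 2a (reversed). A traversal departs from state (from_node, from_sign)
# and, once taken, requires the next departure from state (to_node,
# -to_sign): walk continuity negates the sign across a shared node.
.traversals <- function(g) {
  m <- n_arcs(g)
  list(
    m = m,
    arc = rep(seq_len(m), each = 2L),
    forward = rep(c(TRUE, FALSE), m),
    from_node = as.vector(rbind(g$tail, g$head)),
    from_sign = as.vector(rbind(g$tsign, g$hsign)),
    to_node = as.vector(rbind(g$head, g$tail)),
    to_sign = as.vector(rbind(g$hsign, g$tsign))
  )
}

.state_key <- function(node, sign) (node - 1L) * 3L + sign + 2L

# Adjacency: for each state key, the traversal indices departing from it, in
# the order given by `priority` (defaults to traversal index, i.e. ascending
# uid with forward before reversed).
.state_adjacency <- function(g, tr = .traversals(g), priority = NULL) {
  keys <- .state_key(tr$from_node, tr$from_sign)
  idx <- seq_along(keys)
  if (!is.null(priority)) idx <- idx[order(priority[idx])]
  adj <- vector("list", 3L * n_nodes(g))
  sp <- split(idx, keys[idx])
  adj[as.integer(names(sp))] <- sp
  adj
}

#' Exhaustive label-soundness check
#'
#' Verifies, over every ordered pair of (real) arcs, the four biconditionals
#' tying incidence equality to (k-1)-character overlap of the labels: e.g. the
#' head incidence of one arc matches the tail incidence of another (same node,
#' negated signs) if and only if the (k-1)-suffix of the first label equals
#' the (k-1)-prefix of the second. This is the property that makes walk
#' continuity equivalent to overlap of the spelled k-mers, so it must hold for
#' every constructed graph. Quadratic in the number of arcs; guarded for use
#' on small graphs.
#'
#' @param g A \code{bigraph} (may be compacted; breaking arcs are skipped).
#' @param max_arcs Refuse larger graphs (quadratic cost).
#' @return \code{TRUE} invisibly if all checks pass, otherwise an error.
#' @export
check_label_soundness <- function(g, max_arcs = 1000L) {
  real <- which(!g$breaking)
  m <- length(real)
  if (m > max_arcs) stop("graph too large for the quadratic soundness check")
  if (m == 0L) return(invisible(TRUE))
  k <- g$k
  lab <- g$label[real]
  tail <- g$tail[real]; tsign <- g$tsign[real]
  head <- g$head[real]; hsign <- g$hsign[real]
  pre <- substr(lab, 1L, k - 1L)
  suf <- substring(lab, nchar(lab) - k + 2L)
  rc_pre <- .rc(pre, g$alphabet)  # = (k-1)-suffix of rc(label)
  rc_suf <- .rc(suf, g$alphabet)  # = (k-1)-prefix of rc(label)
  eq <- function(x, y) outer(x, y, "==")
  pair <- function(node1, sign1, node2, sign2) {
    eq(node1, node2) & outer(sign1, -sign2, "==")
  }
  checks <- list(
    head_tail = identical(pair(head, hsign, tail, tsign), eq(suf, pre)),
    head_head = identical(pair(head, hsign, head, hsign), eq(suf, rc_suf)),
    tail_tail = identical(pair(tail, tsign, tail, tsign), eq(rc_pre, pre)),
    tail_head = identical(pair(tail, tsign, head, hsign), eq(rc_pre, rc_suf))
  )
  bad <- names(checks)[!unlist(checks)]
  if (length(bad) > 0L) {
    stop("label soundness violated for incidence case(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Contract non-branching nodes into merged arcs (unitig compaction)
#'
#' Contracts every node that is either (a) self-complemental with exactly two
#' arcs holding exactly one incidence to it each, or (b) normal with exactly
#' one incoming and one outgoing arc, neither a self-loop. Nodes incident to
#' any self-loop are never contracted. The two arcs through a contracted node
#' are merged, overlapping their labels by k-1 characters; merged labels are
#' normalised to canonical orientation (label <= its reverse complement, with
#' the incidences swapped when the orientation flips). A cycle all of whose
#' nodes are contractible is collapsed onto its node with the smallest id,
#' leaving one self-loop arc.
#'
#' The multiset of k-mers spelled by the labels is unchanged, as are degrees
#' (and hence imbalance) at every surviving node, so the Eulertig pipeline
#' gives identical cumulative length and string count on the compacted and
#' uncompacted graph.
#'
#' @param g An uncompacted \code{bigraph} without breaking arcs.
#' @return A compacted \code{bigraph}.
#' @export
compact_dbg <- function(g) {
  if (any(g$breaking)) stop("cannot compact a graph with breaking arcs")
  m <- n_arcs(g)
  if (m == 0L) return(g)
  k <- g$k
  ab <- g$alphabet
  dr <- degrees_and_imbalance(g)$nodes
  loop_node <- unique(g$tail[g$tail == g$head])
  contractible <- logical(n_nodes(g))
  normal_ok <- !g$node_selfc & !is.na(dr$outdegree) &
    dr$outdegree == 1L & dr$indegree == 1L
  selfc_ok <- g$node_selfc & dr$degree == 2L
  contractible[normal_ok | selfc_ok] <- TRUE
  contractible[loop_node] <- FALSE

  tr <- .traversals(g)
  adj <- .state_adjacency(g, tr)
  succ <- function(t) {
    cands <- adj[[.state_key(tr$to_node[t], -tr$to_sign[t])]]
    cands <- cands[tr$arc[cands] != tr$arc[t]]
    if (length(cands) != 1L) {
      stop("internal error: contractible node without unique continuation")
    }
    cands
  }

  visited <- logical(m)
  chains <- list()
  follow <- function(t0) {
    chain <- integer(0)
    t <- t0
    repeat {
      chain <- c(chain, t)
      visited[tr$arc[t]] <<- TRUE
      if (!contractible[tr$to_node[t]]) break
      t <- succ(t)
      if (visited[tr$arc[t]]) break  # closed a cycle back onto its start
    }
    chain
  }
  starts <- which(!contractible[tr$from_node])
  for (t0 in starts) {
    if (visited[tr$arc[t0]]) next
    chains[[length(chains) + 1L]] <- follow(t0)
  }
  # cycles whose nodes are all contractible: anchor at the smallest arc uid
  while (any(!visited)) {
    a0 <- which(!visited)[1L]
    chains[[length(chains) + 1L]] <- follow(2L * a0 - 1L)
  }

  merged <- lapply(chains, function(chain) {
    km <- ifelse(tr$forward[chain], g$label[tr$arc[chain]],
                 .rc(g$label[tr$arc[chain]], ab))
    s <- paste0(km[1L], paste(substring(km[-1L], k), collapse = ""))
    t1 <- chain[1L]; tl <- chain[length(chain)]
    tail_node <- tr$from_node[t1]; tail_sign <- tr$from_sign[t1]
    head_node <- tr$to_node[tl]; head_sign <- tr$to_sign[tl]
    rs <- .rc(s, ab)
    if (s > rs) {
      s <- rs
      tmp_n <- tail_node; tmp_s <- tail_sign
      tail_node <- head_node; tail_sign <- head_sign
      head_node <- tmp_n; head_sign <- tmp_s
    }
    list(label = s, tail = tail_node, tsign = tail_sign,
         head = head_node, hsign = head_sign)
  })

  labels <- vapply(merged, `[[`, character(1), "label")
  ord <- order(labels)
  merged <- merged[ord]
  labels <- labels[ord]
  tails <- vapply(merged, `[[`, integer(1), "tail")
  heads <- vapply(merged, `[[`, integer(1), "head")
  keep <- sort(unique(c(tails, heads)))
  remap <- integer(n_nodes(g))
  remap[keep] <- seq_along(keep)
  .new_bigraph(
    k,
    g$node_mer[keep], g$node_selfc[keep],
    remap[tails], vapply(merged, `[[`, integer(1), "tsign"),
    remap[heads], vapply(merged, `[[`, integer(1), "hsign"),
    labels, rep(FALSE, length(labels)), ab, compacted = TRUE
  )
}

# Canonical k-spectrum of the arc labels of a graph (breaking arcs skipped).
.label_spectrum <- function(g) {
  lab <- g$label[!g$breaking]
  if (length(lab) == 0L) return(character(0))
  sort(unique(.canonical(.all_windows(lab, g$k), g$alphabet)))
}

# Number of k-mers represented by the arcs (one per label window).
.n_label_kmers <- function(g) {
  lab <- g$label[!g$breaking]
  sum(nchar(lab) - g$k + 1L)
}

# Subgraph induced by a set of arcs (used for per-component processing).
# Arc uids are renumbered 1..m in ascending original uid; node ids densely in
# ascending original id.
.subgraph <- function(g, arcs) {
  arcs <- sort(arcs)
  keep <- sort(unique(c(g$tail[arcs], g$head[arcs])))
  remap <- integer(n_nodes(g))
  remap[keep] <- seq_along(keep)
  sub <- .new_bigraph(
    g$k, g$node_mer[keep], g$node_selfc[keep],
    remap[g$tail[arcs]], g$tsign[arcs],
    remap[g$head[arcs]], g$hsign[arcs],
    g$label[arcs], g$breaking[arcs], g$alphabet, g$compacted
  )
  sub$orig_uid <- arcs
  sub
}
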