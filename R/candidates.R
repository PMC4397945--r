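#' Enumerate transcript candidates from one splice graph
#'
#' All source-to-sink paths of the graph are enumerated by depth-first search.
#' If the number of paths would exceed `max_candidates`, the edge-coverage
#' threshold (starting at one read) is incremented and every edge below it
#' removed, until a complete search stays within the cap or no edges remain;
#' in the latter case each remaining isolated exon yields a single-exon
#' candidate. Children are visited in genomic order, so enumeration is
#' deterministic.
#'
#' @param graph A `SpliceGraph`.
#' @param max_candidates Per-graph cap on the number of paths (default 100).
#' @return A `CandidateSet`: list with `candidates` (list of
#'   `TranscriptCandidate`), `m`, `chrom`, `strand`, `fragments`, and the
#'   final edge-coverage `threshold` used.
#' @export
enumerate_paths <- function(graph, max_candidates = 100L) {
  stopifnot(inherits(graph, "SpliceGraph"), nrow(graph$exons) >= 1L)
  threshold <- 1L
  nv <- nrow(graph$exons)
  # path endpoints are fixed by the unpruned topology: transcripts start at
  # original source exons and end at original sink exons, so pruning can
  # only remove paths (monotone in the threshold)
  indeg0 <- tabulate(graph$edges$to, nbins = nv)
  outdeg0 <- tabulate(graph$edges$from, nbins = nv)
  sources0 <- which(indeg0 == 0L)
  sinks0 <- which(outdeg0 == 0L)
  repeat {
    keep <- graph$edges$coverage >= threshold
    edges <- graph$edges[keep, , drop = FALSE]
    if (nrow(edges) == 0L) {
      # no edges left: isolated exons each become a single-exon path,
      # regardless of the cap
      paths <- lapply(seq_len(nv), identity)
      break
    }
    paths <- dfs_paths(nv, edges, max_candidates,
                       sources = sources0, sinks = sinks0)
    if (!is.null(paths)) break
    threshold <- threshold + 1L
  }
  cands <- lapply(paths, function(p) candidate_from_path(graph, p))
  if (graph$strand == "reverse") cands <- rev(cands)
  cs <- list(chrom = graph$chrom, strand = graph$strand, candidates = cands,
             m = length(cands), fragments = graph$fragments,
             threshold = threshold)
  class(cs) <- "CandidateSet"
  cs
}

# All source-to-sink paths, or NULL if their number exceeds `cap`. `sources`
# and `sinks` default to the in/out-degree-zero vertices of `edges`; callers
# enumerating a pruned graph pass the unpruned endpoints instead, so that a
# dead end created by pruning does not spawn a truncated path.
dfs_paths <- function(n_vertices, edges, cap, sources = NULL, sinks = NULL) {
  adj <- vector("list", n_vertices)
  indeg <- integer(n_vertices)
  outdeg <- integer(n_vertices)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
      indeg[edges$to[k]] <- indeg[edges$to[k]] + 1L
      outdeg[edges$from[k]] <- outdeg[edges$from[k]] + 1L
    }
    adj <- lapply(adj, sort)
  }
  sources <- sources %||% which(indeg == 0L)
  sinks <- sinks %||% which(outdeg == 0L)
  is_sink <- logical(n_vertices)
  is_sink[sinks] <- TRUE
  paths <- list()
  overflow <- FALSE
  visit <- function(v, trail) {
    if (overflow) return()
    if (outdeg[v] == 0L) {
      if (!is_sink[v]) return()  # dead end created by pruning
      if (length(paths) + 1L > cap) { overflow <<- TRUE; return() }
      paths[[length(paths) + 1L]] <<- c(trail, v)
      return()
    }
    for (w in adj[[v]]) visit(w, c(trail, v))
  }
  for (s in sources) {
    visit(s, integer(0))
    if (overflow) return(NULL)
  }
  paths
}

# Turn a vertex path into a TranscriptCandidate: abutting segments merge
# into maximal exons; gaps become the intron chain.
candidate_from_path <- function(graph, path) {
  ex <- graph$exons[path, , drop = FALSE]
  merged <- reduce_intervals(ex)
  new_candidate(graph$chrom, graph$strand, merged, is_premrna = FALSE)
}

new_candidate <- function(chrom, strand, exons, is_premrna = FALSE) {
  stopifnot(nrow(exons) >= 1L, all(exons[, 2L] > exons[, 1L]))
  exons <- interval_matrix(exons[, 1L], exons[, 2L])
  cand <- list(chrom = chrom, strand = strand,
               exons = exons,
               introns = blocks_introns(exons),
               length = sum(exons[, 2L] - exons[, 1L]),
               is_premrna = is_premrna,
               effective_length = NA_real_)
  class(cand) <- "TranscriptCandidate"
  cand
}

#' @export
print.TranscriptCandidate <- function(x, ...) {
  cat(sprintf("TranscriptCandidate %s:%s [%s] len=%d%s\n", x$chrom, x$strand,
              paste(sprintf("%d-%d", x$exons[, 1L], x$exons[, 2L]),
                    collapse = ","),
              x$length, if (x$is_premrna) " (pre-mRNA)" else ""))
  invisible(x)
}

candidate_key <- function(cand) {
  paste(cand$chrom, cand$strand,
        paste(cand$exons[, 1L], cand$exons[, 2L], sep = "-", collapse = ","))
}

#' Finalize candidate sets for inference
#'
#' Per graph: enumerates paths, appends the pre-mRNA candidate (one exon
#' spanning the graph's whole genomic interval, modeling unspliced
#' precursor), and removes multi-exon candidates having any splice junction
#' without paired-end fragment support. Graphs whose genomic intervals
#' overlap on the same strand are then combined: candidates unioned
#' (duplicates collapsed) and attached fragments pooled, giving one
#' inference unit per locus cluster.
#'
#' @param graphs List of `SpliceGraph`s (typically [build_splice_graphs()]
#'   output).
#' @param max_candidates Passed to [enumerate_paths()].
#' @param path_sets Optional pre-computed list of `CandidateSet`s parallel to
#'   `graphs` (avoids re-enumeration).
#' @return List of `CandidateSet`s, one per locus cluster, each with a
#'   `locus_id`.
#' @export
finalize_candidates <- function(graphs, max_candidates = 100L,
                                path_sets = NULL) {
  if (length(graphs) == 0L) return(list())
  if (is.null(path_sets)) {
    path_sets <- lapply(graphs, enumerate_paths,
                        max_candidates = max_candidates)
  }
  per_graph <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    cands <- path_sets[[i]]$candidates
    pre <- new_candidate(g$chrom, g$strand,
                         cbind(start = g$interval[1L], end = g$interval[2L]),
                         is_premrna = TRUE)
    cands <- c(cands, list(pre))
    keep <- vapply(cands, function(cand) {
      if (nrow(cand$introns) == 0L) return(TRUE)
      junction_support_ok(cand, g$fragments)
    }, logical(1L))
    cands[keep]
  })

  # cluster graphs overlapping >= 1 bp on the same chrom and strand
  nb <- NULL
  ng <- length(graphs)
  if (ng > 1L) {
    for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
      gi <- graphs[[i]]; gj <- graphs[[j]]
      if (gi$chrom == gj$chrom && gi$strand == gj$strand &&
          gi$interval[1L] < gj$interval[2L] &&
          gj$interval[1L] < gi$interval[2L]) {
        nb <- rbind(nb, c(i, j))
      }
    }
  }
  comp <- components_from_edges(ng, nb %||% matrix(integer(0), ncol = 2L))

  out <- list()
  for (cl in sort(unique(comp))) {
    members <- which(comp == cl)
    cands <- do.call(c, per_graph[members])
    if (length(cands) == 0L) next  # all filtered: cluster skipped
    cands <- cands[!duplicated(vapply(cands, candidate_key, character(1L)))]
    frags <- do.call(rbind, lapply(members, function(i) graphs[[i]]$fragments))
    frags <- frags[!duplicated(frags$fragment_id), , drop = FALSE]
    cs <- list(chrom = cands[[1L]]$chrom, strand = cands[[1L]]$strand,
               candidates = cands, m = length(cands), fragments = frags,
               locus_id = sprintf("LOC%04d", length(out) + 1L))
    class(cs) <- "CandidateSet"
    out[[length(out) + 1L]] <- cs
  }
  out
}

# TRUE iff every intron of the candidate is carried by >= 1 attached fragment.
junction_support_ok <- function(cand, fragments) {
  need <- paste(cand$introns[, 1L], cand$introns[, 2L])
  seen <- unlist(lapply(fragments$introns, function(m) {
    if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L])
  }))
  all(need %in% seen)
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet %s (%s): m=%d candidates, %d fragments\n",
              x$chrom, x$strand, x$m, nrow(x$fragments)))
  invisible(x)
}
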