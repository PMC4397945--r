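#' Build per-locus splice graphs from filtered fragments
#'
#' Fragments are clustered into loci: covered genomic segments separated by at
#' least one uncovered base start distinct loci, but segments bridged by a
#' spliced fragment belong to the same locus. One strand-resolved graph is
#' built per locus (per strand for stranded libraries). Exon vertices are the
#' covered segments split at every junction donor/acceptor position, so
#' vertices are minimal disjoint segments; edges are either splice junctions
#' (an observed intron) or adjacency between abutting segments, each weighted
#' by the number of attached fragments supporting it. Loci attached to fewer
#' than two fragments are dropped, and in unstranded mode loci without any
#' spliced strand evidence are discarded.
#'
#' @param fragment_set A `FragmentSet` from [load_fragments()].
#' @param verbose Emit per-filter counts.
#' @return List of `SpliceGraph` objects; attribute `dropped` carries counts
#'   of discarded loci (too few fragments, unresolvable strand).
#' @export
build_splice_graphs <- function(fragment_set, verbose = FALSE) {
  stopifnot(inherits(fragment_set, "FragmentSet"))
  frag <- fragment_set$fragments
  stranded <- fragment_set$library_type != "unstranded"
  dropped <- c(too_few = 0L, no_strand = 0L, undetermined_fragments = 0L)
  graphs <- list()
  if (nrow(frag) > 0L) {
    groups <- if (stranded) split(seq_len(nrow(frag)),
                                  paste(frag$chrom, frag$strand))
              else split(seq_len(nrow(frag)), frag$chrom)
    for (idx in groups) {
      cl <- cluster_fragments(frag[idx, , drop = FALSE])
      for (loc_rows in cl) {
        sub <- frag[idx[loc_rows], , drop = FALSE]
        if (stranded) {
          if (nrow(sub) < 2L) { dropped["too_few"] <- dropped["too_few"] + 1L; next }
          graphs[[length(graphs) + 1L]] <-
            splice_graph_from_fragments(sub, sub$strand[1L])
        } else {
          ev <- unique(sub$strand[sub$strand != "none"])
          if (length(ev) == 0L) { dropped["no_strand"] <- dropped["no_strand"] + 1L; next }
          if (length(ev) == 1L) {
            # undetermined fragments inherit the locus strand
            if (nrow(sub) < 2L) { dropped["too_few"] <- dropped["too_few"] + 1L; next }
            graphs[[length(graphs) + 1L]] <-
              splice_graph_from_fragments(sub, ev)
          } else {
            # both strands seen: one graph per strand from its own evidence;
            # fragments without evidence cannot be attached unambiguously
            dropped["undetermined_fragments"] <-
              dropped["undetermined_fragments"] + sum(sub$strand == "none")
            for (s in c("forward", "reverse")) {
              ssub <- sub[sub$strand == s, , drop = FALSE]
              if (nrow(ssub) < 2L) { dropped["too_few"] <- dropped["too_few"] + 1L; next }
              graphs[[length(graphs) + 1L]] <-
                splice_graph_from_fragments(ssub, s)
            }
          }
        }
      }
    }
  }
  ord <- order(vapply(graphs, function(g) g$chrom, character(1L)),
               vapply(graphs, function(g) g$interval[1L], integer(1L)))
  graphs <- graphs[ord]
  if (verbose) {
    message(sprintf(
      "build_splice_graphs: %d graphs; dropped %d loci (<2 fragments), %d (no strand); %d strandless fragments unattached",
      length(graphs), dropped["too_few"], dropped["no_strand"],
      dropped["undetermined_fragments"]))
  }
  attr(graphs, "dropped") <- dropped
  graphs
}

# Partition fragments (one chrom, optionally one strand) into loci.
# Returns a list of integer row-index vectors into `frag`.
cluster_fragments <- function(frag) {
  n <- nrow(frag)
  if (n == 0L) return(list())
  all_blocks <- do.call(rbind, c(frag$blocks1, frag$blocks2))
  segs <- reduce_intervals(all_blocks)
  seg_ir <- IRanges::IRanges(start = segs[, 1L] + 1L, end = segs[, 2L])
  # map each fragment's blocks to segments; fragments touching several
  # segments (via introns) merge them into one locus
  frag_edges <- NULL
  frag_seg <- integer(n)
  for (i in seq_len(n)) {
    b <- rbind(frag$blocks1[[i]], frag$blocks2[[i]])
    ir <- IRanges::IRanges(start = b[, 1L] + 1L, end = b[, 2L])
    hit <- unique(S4Vectors::subjectHits(IRanges::findOverlaps(ir, seg_ir)))
    frag_seg[i] <- hit[1L]
    if (length(hit) > 1L) {
      frag_edges <- rbind(frag_edges,
                          cbind(hit[-length(hit)], hit[-1L]))
    }
  }
  comp <- components_from_edges(
    length(seg_ir), frag_edges %||% matrix(integer(0), ncol = 2L))
  split(seq_len(n), comp[frag_seg])
}

# Build one SpliceGraph from the fragments attached to a locus.
splice_graph_from_fragments <- function(frag, strand) {
  all_blocks <- do.call(rbind, c(frag$blocks1, frag$blocks2))
  segs <- reduce_intervals(all_blocks)
  introns <- unique_intervals(do.call(rbind, c(list(matrix(integer(0), ncol = 2L)),
                                               frag$introns)))
  # split covered segments at every donor/acceptor strictly inside them
  exon_s <- integer(0); exon_e <- integer(0)
  bp_all <- sort(unique(c(introns[, 1L], introns[, 2L])))
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, 1L]; e <- segs[k, 2L]
    bp <- bp_all[bp_all > s & bp_all < e]
    cuts <- c(s, bp, e)
    exon_s <- c(exon_s, cuts[-length(cuts)])
    exon_e <- c(exon_e, cuts[-1L])
  }
  ord <- order(exon_s)
  exons <- interval_matrix(exon_s[ord], exon_e[ord])

  frag_intron_keys <- lapply(frag$introns, function(m) {
    if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L])
  })
  from <- integer(0); to <- integer(0); cov <- integer(0); type <- character(0)
  if (nrow(introns) > 0L) {
    for (k in seq_len(nrow(introns))) {
      d <- introns[k, 1L]; a <- introns[k, 2L]
      fi <- which(exons[, "end"] == d)
      ti <- which(exons[, "start"] == a)
      if (length(fi) != 1L || length(ti) != 1L) next  # splice site outside coverage
      key <- paste(d, a)
      support <- sum(vapply(frag_intron_keys, function(kk) key %in% kk,
                            logical(1L)))
      if (support >= 1L) {
        from <- c(from, fi); to <- c(to, ti)
        cov <- c(cov, support); type <- c(type, "junction")
      }
    }
  }
  # adjacency edges between abutting exon segments, supported by a read
  # block that runs contiguously across the boundary
  if (nrow(exons) > 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      if (exons[i, "end"] != exons[i + 1L, "start"]) next
      b <- exons[i, "end"]
      support <- sum(vapply(seq_len(nrow(frag)), function(j) {
        bl <- rbind(frag$blocks1[[j]], frag$blocks2[[j]])
        any(bl[, 1L] < b & bl[, 2L] > b)
      }, logical(1L)))
      if (support >= 1L) {
        from <- c(from, i); to <- c(to, i + 1L)
        cov <- c(cov, support); type <- c(type, "adjacency")
      }
    }
  }
  g <- list(chrom = frag$chrom[1L], strand = strand, exons = exons,
            edges = data.frame(from = from, to = to, coverage = cov,
                               type = type, stringsAsFactors = FALSE),
            fragments = frag,
            interval = c(min(exons[, "start"]), max(exons[, "end"])))
  class(g) <- "SpliceGraph"
  g
}

#' @export
print.SpliceGraph <- function(x, ...) {
  cat(sprintf("SpliceGraph %s:%d-%d (%s): %d exons, %d edges, %d fragments\n",
              x$chrom, x$interval[1L], x$interval[2L], x$strand,
              nrow(x$exons), nrow(x$edges), nrow(x$fragments)))
  invisible(x)
}

# Debug dump (unstable format): one line per exon and edge.
format_splice_graph <- function(g) {
  c(sprintf("# %s %s %d-%d", g$chrom, g$strand, g$interval[1L], g$interval[2L]),
    sprintf("exon\t%d\t%d", g$exons[, 1L], g$exons[, 2L]),
    if (nrow(g$edges) > 0L)
      sprintf("edge\t%d\t%d\t%d\t%s", g$edges$from, g$edges$to,
              g$edges$coverage, g$edges$type))
}
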