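# Internal helpers shared across modules. All genomic intervals are 0-based
# half-open; conversion to 1-based inclusive happens only in the GTF writer.

# Parse a CIGAR string into reference-space blocks.
# pos: 1-based leftmost mapping position (SAM convention).
# Returns an integer matrix with columns start, end (0-based half-open);
# N gaps split blocks, M/D/=/X consume reference within a block.
cigar_blocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L) stop("unparsable CIGAR: ", cigar)
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  type <- substr(ops, nchar(ops), nchar(ops))
  cur <- pos - 1L
  starts <- integer(0)
  ends <- integer(0)
  open_start <- NA_integer_
  for (k in seq_along(ops)) {
    tk <- type[k]
    if (tk %in% c("M", "D", "=", "X")) {
      if (is.na(open_start)) open_start <- cur
      cur <- cur + lens[k]
    } else if (tk == "N") {
      if (!is.na(open_start)) {
        starts <- c(starts, open_start)
        ends <- c(ends, cur)
        open_start <- NA_integer_
      }
      cur <- cur + lens[k]
    }
    # I, S, H, P do not consume reference
  }
  if (!is.na(open_start)) {
    starts <- c(starts, open_start)
    ends <- c(ends, cur)
  }
  cbind(start = starts, end = ends)
}

# Introns implied by one mate's blocks: the gaps between successive blocks.
blocks_introns <- function(blocks) {
  k <- nrow(blocks)
  if (k < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  interval_matrix(blocks[-k, 2L], blocks[-1L, 1L])
}

# Canonical interval matrix shape: no rownames, columns start/end.
interval_matrix <- function(start, end) {
  matrix(as.integer(c(start, end)), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

# Sorted unique rows of a 2-column interval matrix.
unique_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  x[!duplicated(x), , drop = FALSE]
}

# Merge overlapping or abutting intervals (matrix in, matrix out).
reduce_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  out_s <- x[1L, 1L]; out_e <- x[1L, 2L]
  ss <- integer(0); ee <- integer(0)
  if (nrow(x) > 1L) {
    for (i in 2L:nrow(x)) {
      if (x[i, 1L] <= out_e) {
        out_e <- max(out_e, x[i, 2L])
      } else {
        ss <- c(ss, out_s); ee <- c(ee, out_e)
        out_s <- x[i, 1L]; out_e <- x[i, 2L]
      }
    }
  }
  interval_matrix(c(ss, out_s), c(ee, out_e))
}

# Canonical single-string key for a fragment's block structure (dedup).
blocks_key <- function(b1, b2) {
  paste(paste(b1[, 1L], b1[, 2L], sep = "-", collapse = ","),
        paste(b2[, 1L], b2[, 2L], sep = "-", collapse = ","), sep = "|")
}

# Union-find with path compression; `edges` is a 2-column index matrix.
components_from_edges <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

log_sum_exp <- function(lx) {
  mx <- max(lx)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(lx - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
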