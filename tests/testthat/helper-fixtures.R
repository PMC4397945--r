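# Fixture builders: all test data is constructed in code.

SAM_HEADER <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT\tLN:100000")

# One SAM line; blocks are 0-based half-open reference intervals.
sam_line <- function(qname, blocks, mate_pos1, is_first, fwd, tlen = 0L,
                     chrom = "chrT", nh = 1L, xs = NULL, proper = TRUE) {
  cigar <- {
    k <- nrow(blocks)
    parts <- sprintf("%dM", blocks[, 2L] - blocks[, 1L])
    if (k > 1L) {
      gaps <- sprintf("%dN", blocks[-1L, 1L] - blocks[-k, 2L])
      parts <- c(rbind(parts[-k], gaps), parts[k])
    }
    paste(parts, collapse = "")
  }
  rl <- sum(blocks[, 2L] - blocks[, 1L])
  flag <- 1L + (if (proper) 2L else 0L) + (if (is_first) 64L else 128L) +
    (if (fwd) 32L else 16L)
  tags <- c(sprintf("NH:i:%d", nh), if (!is.null(xs)) sprintf("XS:A:%s", xs))
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s\t%s",
          qname, flag, chrom, blocks[1L, 1L] + 1L, cigar, mate_pos1, tlen,
          strrep("A", rl), strrep("I", rl), paste(tags, collapse = "\t"))
}

# A proper FR pair from two block matrices (left mate forward, right reverse).
sam_pair <- function(qname, blocks1, blocks2, nh = 1L, xs = NULL,
                     chrom = "chrT") {
  p1 <- blocks1[1L, 1L] + 1L
  p2 <- blocks2[1L, 1L] + 1L
  xs1 <- if (!is.null(xs) && nrow(blocks1) > 1L) xs else NULL
  xs2 <- if (!is.null(xs) && nrow(blocks2) > 1L) xs else NULL
  c(sam_line(qname, blocks1, p2, TRUE, TRUE, nh = nh, xs = xs1,
             chrom = chrom),
    sam_line(qname, blocks2, p1, FALSE, FALSE, nh = nh, xs = xs2,
             chrom = chrom))
}

write_sam <- function(lines, path = tempfile(fileext = ".sam"),
                      header = SAM_HEADER) {
  # SAM records must be coordinate sorted for asBam
  pos <- as.integer(vapply(strsplit(lines, "\t"), `[`, character(1L), 4L))
  writeLines(c(header, lines[order(pos)]), path)
  path
}

iv <- function(...) {
  x <- matrix(as.integer(c(...)), ncol = 2L, byrow = TRUE)
  colnames(x) <- c("start", "end")
  x
}

# Hand-built SpliceGraph (bypasses the constructor for candidate-layer tests).
make_graph <- function(exons, edges, strand = "forward", chrom = "chrT",
                       fragments = NULL) {
  g <- list(chrom = chrom, strand = strand, exons = exons,
            edges = edges, fragments = fragments %||% empty_frag_df(),
            interval = c(min(exons[, 1L]), max(exons[, 2L])))
  class(g) <- "SpliceGraph"
  g
}

edges_df <- function(from = integer(0), to = integer(0),
                     coverage = integer(0), type = NULL) {
  data.frame(from = from, to = to, coverage = coverage,
             type = type %||% rep("junction", length(from)),
             stringsAsFactors = FALSE)
}

empty_frag_df <- function() {
  df <- data.frame(fragment_id = character(0), chrom = character(0),
                   strand = character(0), stringsAsFactors = FALSE)
  df$blocks1 <- list(); df$blocks2 <- list(); df$introns <- list()
  df$start <- integer(0); df$end <- integer(0)
  df
}

# Minimal fragment data frame row for graph/candidate tests.
frag_row <- function(id, blocks1, blocks2, strand = "forward",
                     chrom = "chrT") {
  df <- data.frame(fragment_id = id, chrom = chrom, strand = strand,
                   stringsAsFactors = FALSE)
  df$blocks1 <- list(blocks1)
  df$blocks2 <- list(blocks2)
  intr <- rbind(bayestx:::blocks_introns(blocks1),
                bayestx:::blocks_introns(blocks2))
  df$introns <- list(bayestx:::unique_intervals(intr))
  df$start <- min(blocks1[, 1L], blocks2[, 1L])
  df$end <- max(blocks1[, 2L], blocks2[, 2L])
  df
}

make_candidate <- function(exons, strand = "forward", chrom = "chrT",
                           is_premrna = FALSE) {
  bayestx:::new_candidate(chrom, strand, exons, is_premrna)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
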