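#' Summarize posterior samples for one inference unit
#'
#' Confidence is the fraction of retained iterations in which a candidate is
#' expressed. The abundance estimate is the mean, over expressed iterations,
#' of the sampled relative abundance normalized to the candidate's effective
#' length and the total library size on the FPKM convention:
#' `e_j * n_locus / effective_length_j * 1e9 / library_size`. The expected
#' count is the mean assigned-fragment count over all retained iterations.
#'
#' @param samples A `PosteriorSamples` from [run_gibbs()].
#' @param candidate_set The matching `CandidateSet`.
#' @param model `FragmentLengthModel` (for effective lengths).
#' @param library_size Total retained fragments across all loci; defaults to
#'   the locus size (single-locus usage).
#' @return A `PosteriorSummary` data frame: one row per candidate with
#'   `confidence`, `mean_abundance`, `expected_count`.
#' @export
summarize_posterior <- function(samples, candidate_set, model,
                                library_size = samples$n) {
  stopifnot(inherits(samples, "PosteriorSamples"),
            samples$m == candidate_set$m)
  eff <- vapply(candidate_set$candidates, effective_length, numeric(1L),
                model = model)
  conf <- samples$expressed_count / samples$retained
  mean_e <- ifelse(samples$expressed_count > 0,
                   samples$sum_e / pmax(samples$expressed_count, 1L), 0)
  fpkm <- mean_e * samples$n / eff * 1e9 / library_size
  out <- data.frame(
    candidate = seq_len(samples$m),
    confidence = conf,
    mean_abundance = fpkm,
    expected_count = samples$sum_c / samples$retained)
  class(out) <- c("PosteriorSummary", class(out))
  out
}

#' Select the final assembly
#'
#' Keeps candidates with confidence strictly above `confidence_threshold`
#' and expected fragment count at least `count_threshold` (the count filter
#' removes putative transcript fragments).
#'
#' @param summary A `PosteriorSummary`.
#' @param candidate_set The matching `CandidateSet`.
#' @param confidence_threshold Default 0.5 (strict inequality).
#' @param count_threshold Default 12 (kept iff `expected_count >=` this).
#' @return An `Assembly`: list with `transcripts` (list of candidates, each
#'   carrying its summary row as `$summary`) and `provenance`.
#' @export
select_final_assembly <- function(summary, candidate_set,
                                  confidence_threshold = 0.5,
                                  count_threshold = 12) {
  keep <- summary$confidence > confidence_threshold &
    summary$expected_count >= count_threshold
  transcripts <- lapply(which(keep), function(j) {
    cand <- candidate_set$candidates[[j]]
    cand$summary <- summary[j, , drop = FALSE]
    cand$locus_id <- candidate_set$locus_id %||% "LOC0001"
    cand
  })
  structure(list(transcripts = transcripts,
                 provenance = list(
                   confidence_threshold = confidence_threshold,
                   count_threshold = count_threshold,
                   version = as.character(utils::packageVersion("bayestx")))),
            class = "Assembly")
}

# Merge per-locus assemblies into one.
combine_assemblies <- function(assemblies, provenance = NULL) {
  structure(list(
    transcripts = do.call(c, c(list(list()),
                               lapply(assemblies, `[[`, "transcripts"))),
    provenance = provenance %||%
      (if (length(assemblies)) assemblies[[1L]]$provenance else list())),
    class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly: %d transcripts\n", length(x$transcripts)))
  invisible(x)
}

#' Write an assembly as GTF
#'
#' One `transcript` feature plus per-exon features per retained candidate,
#' 1-based inclusive coordinates, with `gene_id` (cluster of overlapping
#' retained transcripts on the same strand), `transcript_id`, `confidence`,
#' `FPKM` and `expected_count` attributes. An empty assembly yields a valid
#' file containing only the header comment.
#'
#' @param assembly An `Assembly`.
#' @param output_path Destination file.
#' @return `output_path`, invisibly.
#' @export
write_gtf <- function(assembly, output_path) {
  con <- tryCatch(file(output_path, "w"),
                  error = function(e) stop("cannot write GTF to ",
                                           output_path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines("## bayestx assembly", con)
  txs <- assembly$transcripts
  if (length(txs) == 0L) return(invisible(output_path))

  # gene_id: connected components of same-strand genomic overlap
  key <- paste(vapply(txs, `[[`, character(1L), "chrom"),
               vapply(txs, `[[`, character(1L), "strand"))
  starts <- vapply(txs, function(t) t$exons[1L, 1L], numeric(1L))
  ends <- vapply(txs, function(t) t$exons[nrow(t$exons), 2L], numeric(1L))
  edges <- NULL
  nt <- length(txs)
  if (nt > 1L) {
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
      if (key[i] == key[j] && starts[i] < ends[j] && starts[j] < ends[i])
        edges <- rbind(edges, c(i, j))
    }
  }
  gene <- components_from_edges(nt, edges %||% matrix(integer(0), ncol = 2L))

  strand_char <- function(s) if (s == "forward") "+" else "-"
  k <- 0L
  for (i in order(vapply(txs, `[[`, character(1L), "chrom"), starts)) {
    t <- txs[[i]]
    k <- k + 1L
    gid <- sprintf("GENE%04d", gene[i])
    tid <- sprintf("%s.TX%04d", t$locus_id %||% "LOC0000", k)
    s <- t$summary
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; confidence "%.4f"; FPKM "%.4f"; expected_count "%.2f";',
      gid, tid, s$confidence %||% NA_real_, s$mean_abundance %||% NA_real_,
      s$expected_count %||% NA_real_)
    writeLines(sprintf("%s\tbayestx\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       t$chrom, t$exons[1L, 1L] + 1L,
                       t$exons[nrow(t$exons), 2L], strand_char(t$strand),
                       attrs), con)
    for (ei in seq_len(nrow(t$exons))) {
      writeLines(sprintf(
        "%s\tbayestx\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        t$chrom, t$exons[ei, 1L] + 1L, t$exons[ei, 2L],
        strand_char(t$strand), attrs, ei), con)
    }
  }
  invisible(output_path)
}

#' Read a GTF file into transcript models
#'
#' Minimal GTF reader used for round-trip tests and assembly evaluation:
#' groups `exon` features by `transcript_id` and reconstructs exon chains
#' (internally 0-based half-open) and intron chains.
#'
#' @param path GTF file.
#' @return List of transcript models (`chrom`, `strand`, `exons`, `introns`,
#'   `transcript_id`, `attributes`).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) x[3L] == "exon", logical(1L))
  f <- f[keep]
  if (length(f) == 0L) return(list())
  tid <- vapply(f, function(x)
    sub('.*transcript_id "([^"]+)".*', "\\1", x[9L]), character(1L))
  out <- lapply(split(seq_along(f), tid), function(idx) {
    rows <- f[idx]
    ex <- cbind(start = vapply(rows, function(x) as.integer(x[4L]) - 1L,
                               integer(1L)),
                end = vapply(rows, function(x) as.integer(x[5L]),
                             integer(1L)))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    list(chrom = rows[[1L]][1L],
         strand = if (rows[[1L]][7L] == "+") "forward" else "reverse",
         exons = ex, introns = blocks_introns(ex),
         transcript_id = sub('.*transcript_id "([^"]+)".*', "\\1",
                             rows[[1L]][9L]),
         attributes = rows[[1L]][9L])
  })
  unname(out)
}
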