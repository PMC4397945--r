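#' Specify a simulation of the generative model
#'
#' Describes a synthetic dataset drawn from the assembler's own generative
#' model: per locus, a zero-truncated Bernoulli draw picks the expressed
#' transcripts, a symmetric Dirichlet draws their relative abundances, each
#' fragment picks a transcript categorically, and its length is Gaussian
#' truncated to the transcript. Gene structures are random multi-exon genes
#' sharing first and last exons across isoforms (so alternative splicing is
#' internal-exon skipping).
#'
#' Defaults mirror the stated conditions of the model: `gamma_true = 1`
#' (uniform Dirichlet), `mu_true = 250`, `sigma_true = 25` (typical Illumina
#' libraries; the benchmark simulations in this problem domain use a mean
#' fragment length of ~249 nt and 100 nt reads).
#'
#' @param n_loci Number of gene loci.
#' @param n_transcripts Isoforms per locus (chains are distinct; capped by
#'   the number of internal exons).
#' @param n_expressed If given, exactly this many isoforms are expressed per
#'   locus (uniformly chosen); otherwise `z ~ Bernoulli(pi_true)` truncated
#'   away from all-zero.
#' @param pi_true Bernoulli expression probability.
#' @param gamma_true Symmetric Dirichlet concentration for abundances.
#' @param mu_true,sigma_true Fragment length mean / sd (nt).
#' @param n_fragments Fragments per locus.
#' @param read_length Read length (nt).
#' @param min_abundance If positive, Dirichlet draws are rejected until every
#'   expressed abundance is at least this.
#' @param calibration_locus Also emit one single-isoform locus with a
#'   transcript longer than 2500 nt, so the fragment-length estimator has a
#'   qualifying locus.
#' @param unique_fragments Resample fragments that would be byte-identical
#'   duplicates of an earlier one (so the loader's duplicate filter removes
#'   nothing).
#' @param library_type Strandedness of the emitted SAM (see
#'   [load_fragments()]).
#' @param seed RNG seed; the whole dataset is a deterministic function of the
#'   spec.
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(n_loci = 3L, n_transcripts = 4L,
                            n_expressed = NULL, pi_true = 0.5,
                            gamma_true = 1, mu_true = 250, sigma_true = 25,
                            n_fragments = 500L, read_length = 100L,
                            min_abundance = 0, calibration_locus = FALSE,
                            unique_fragments = TRUE,
                            library_type = "fr-firststrand", seed = 1L) {
  stopifnot(n_loci >= 1L, n_transcripts >= 1L, pi_true > 0, pi_true <= 1,
            gamma_true > 0, mu_true > 0, sigma_true >= 0, n_fragments >= 1L,
            read_length >= 1L, min_abundance >= 0, min_abundance < 1)
  structure(as.list(environment()), class = "SimulationSpec")
}

# One random gene structure with two linked alternative-splicing events:
# e1 - (a1|a2|a3 mutually exclusive) - e2 - (b skippable) - e3, which admits
# exactly six isoform chains. The middle exon e2 is short (human-typical
# internal exon, ~100-150 nt), so a ~250 nt fragment frequently links the
# choice at the first event to the choice at the second, keeping the isoform
# deconvolution identifiable; terminal exons are longer, as in real genes.
# Coordinates are locus-relative (0-based half-open).
random_locus_structure <- function(n_transcripts,
                                   exon_range = c(80L, 200L),
                                   linker_range = c(100L, 150L),
                                   terminal_range = c(200L, 400L),
                                   intron_range = c(200L, 800L)) {
  ex_len <- c(sample(terminal_range[1L]:terminal_range[2L], 1L),     # e1
              sample(exon_range[1L]:exon_range[2L], 3L, TRUE),       # a1-a3
              sample(linker_range[1L]:linker_range[2L], 1L),         # e2
              sample(exon_range[1L]:exon_range[2L], 1L),             # b
              sample(terminal_range[1L]:terminal_range[2L], 1L))     # e3
  K <- 7L
  in_len <- sample(intron_range[1L]:intron_range[2L], K - 1L, TRUE)
  starts <- cumsum(c(0L, head(ex_len, -1L) + in_len))
  exons <- cbind(start = starts, end = starts + ex_len)
  chains <- list()
  for (a in 2:4) for (skip_b in c(FALSE, TRUE)) {
    chains[[length(chains) + 1L]] <- c(1L, a, 5L, if (!skip_b) 6L, 7L)
  }
  n_tx <- min(n_transcripts, length(chains))
  chains <- chains[sort(sample.int(length(chains), n_tx))]
  list(exons = exons, chains = chains, span = max(exons[, "end"]))
}

# Calibration gene: one isoform, three long exons, total length >= 2500 nt.
calibration_locus_structure <- function() {
  exons <- cbind(start = c(0L, 1500L, 3000L),
                 end = c(1000L, 2500L, 3900L))
  list(exons = exons, chains = list(1:3), span = 3900L)
}

#' Simulate alignments from the generative model
#'
#' Draws expression, abundances, fragment assignments and fragment lengths
#' per the model, places each fragment uniformly on its transcript, and
#' writes the mates as a coordinate-sorted proper-pair SAM file with spliced
#' CIGARs, `NH:i:1` and (on junction reads) `XS:A` strand tags. Also writes a
#' truth GTF and a truth table.
#'
#' @param spec A `SimulationSpec`.
#' @param dir Output directory (created if needed).
#' @return List with `sam`, `truth_gtf`, `truth_table` (paths/data frame) and
#'   `truth`: per locus the transcripts, `z`, `e` and fragment source counts.
#' @export
simulate_dataset <- function(spec, dir = tempfile("bayestx_sim")) {
  stopifnot(inherits(spec, "SimulationSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  rl <- spec$read_length
  chrom <- "chrS"
  gap <- 10000L

  loci <- lapply(seq_len(spec$n_loci), function(i)
    random_locus_structure(spec$n_transcripts))
  if (spec$calibration_locus) {
    loci <- c(loci, list(calibration_locus_structure()))
  }
  offset <- 0L
  strands <- character(length(loci))
  for (i in seq_along(loci)) {
    loci[[i]]$offset <- offset
    loci[[i]]$exons_g <- loci[[i]]$exons + offset
    strands[i] <- sample(c("forward", "reverse"), 1L)
    loci[[i]]$strand <- strands[i]
    offset <- offset + loci[[i]]$span + gap
  }
  chrom_len <- offset

  sam_records <- list()
  truth <- list()
  truth_rows <- list()
  gtf_lines <- "## bayestx simulated truth"
  for (li in seq_along(loci)) {
    loc <- loci[[li]]
    n_tx <- length(loc$chains)
    tx_exons <- lapply(loc$chains, function(ch)
      loc$exons_g[ch, , drop = FALSE])
    tx_len <- vapply(tx_exons, function(e) sum(e[, 2L] - e[, 1L]),
                     integer(1L))
    if (any(tx_len < rl)) stop("transcript shorter than the read length")

    is_cal <- spec$calibration_locus && li == length(loci)
    if (!is.null(spec$n_expressed) && !is_cal) {
      k <- min(spec$n_expressed, n_tx)
      z <- integer(n_tx)
      z[sample.int(n_tx, k)] <- 1L
    } else {
      repeat {  # zero-truncated Bernoulli, matching the prior normalization
        z <- rbinom(n_tx, 1L, spec$pi_true)
        if (sum(z) > 0L) break
      }
    }
    b <- sum(z)
    guard <- 0L
    repeat {
      g <- rgamma(b, shape = spec$gamma_true, rate = 1)
      e_plus <- g / sum(g)
      guard <- guard + 1L
      if (all(e_plus >= spec$min_abundance) || guard > 10000L) break
    }
    e <- numeric(n_tx)
    e[z == 1L] <- e_plus

    t_src <- which(z == 1L)[sample.int(b, spec$n_fragments, replace = TRUE,
                                       prob = e_plus)]
    seen <- new.env(hash = TRUE)
    frag_t <- integer(spec$n_fragments)
    for (fi in seq_len(spec$n_fragments)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        tx <- if (tries == 1L) t_src[fi]
              else which(z == 1L)[sample.int(b, 1L, prob = e_plus)]
        L <- tx_len[tx]
        len <- draw_fragment_length(spec$mu_true, spec$sigma_true, rl, L)
        s <- sample.int(L - len + 1L, 1L) - 1L
        left <- tcoord_to_blocks(tx_exons[[tx]], s, s + rl)
        right <- tcoord_to_blocks(tx_exons[[tx]], s + len - rl, s + len)
        # uniqueness keyed on genomic blocks: distinct isoforms can emit
        # byte-identical fragments within shared exons
        key <- blocks_key(left, right)
        fresh <- !spec$unique_fragments || is.null(seen[[key]])
        if (fresh || tries > 200L) break
      }
      seen[[key]] <- TRUE
      frag_t[fi] <- tx
      qn <- sprintf("L%02dF%05d", li, fi)
      sam_records[[length(sam_records) + 1L]] <-
        fragment_sam_records(qn, chrom, left, right, rl, loc$strand,
                             spec$library_type)
    }

    truth[[li]] <- list(exons = tx_exons, strand = loc$strand, z = z, e = e,
                        t = frag_t, length = tx_len)
    for (ti in seq_len(n_tx)) {
      tid <- sprintf("SIM%02d.T%02d", li, ti)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        locus = li, transcript = tid, expressed = z[ti], abundance = e[ti],
        stringsAsFactors = FALSE)
      ex <- tx_exons[[ti]]
      sc <- if (loc$strand == "forward") "+" else "-"
      at <- sprintf('gene_id "SIM%02d"; transcript_id "%s";', li, tid)
      gtf_lines <- c(gtf_lines,
        sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s", chrom,
                ex[1L, 1L] + 1L, ex[nrow(ex), 2L], sc, at),
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s", chrom,
                ex[, 1L] + 1L, ex[, 2L], sc, at))
    }
  }

  recs <- do.call(rbind, sam_records)
  recs <- recs[order(as.integer(recs[, "pos"])), , drop = FALSE]
  sam_path <- file.path(dir, "simulated.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  writeLines(c(header, recs[, "line"]), sam_path)
  gtf_path <- file.path(dir, "truth.gtf")
  writeLines(gtf_lines, gtf_path)
  tt <- do.call(rbind, truth_rows)
  utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sam = sam_path, truth_gtf = gtf_path, truth_table = tt, truth = truth,
       spec = spec, dir = dir)
}

# Gaussian fragment length truncated (by rejection) to [read_len, L].
draw_fragment_length <- function(mu, sigma, read_len, L) {
  if (L < read_len) stop("transcript shorter than realizable fragments")
  if (sigma == 0) return(min(max(round(mu), read_len), L))
  for (k in seq_len(10000L)) {
    len <- as.integer(round(rnorm(1L, mu, sigma)))
    if (len >= read_len && len <= L) return(len)
  }
  min(max(as.integer(round(mu)), read_len), L)  # guard: clamp
}

# Map a transcript-coordinate interval [a, b) (genomic-left origin) to
# genomic blocks on the candidate exon chain.
tcoord_to_blocks <- function(exons, a, b) {
  cumw <- c(0L, cumsum(exons[, 2L] - exons[, 1L]))
  ss <- integer(0); ee <- integer(0)
  for (k in seq_len(nrow(exons))) {
    lo <- max(a, cumw[k]); hi <- min(b, cumw[k + 1L])
    if (lo < hi) {
      ss <- c(ss, exons[k, 1L] + (lo - cumw[k]))
      ee <- c(ee, exons[k, 1L] + (hi - cumw[k]))
    }
  }
  cbind(start = ss, end = ee)
}

blocks_cigar <- function(blocks) {
  k <- nrow(blocks)
  parts <- sprintf("%dM", blocks[, 2L] - blocks[, 1L])
  if (k > 1L) {
    gaps <- sprintf("%dN", blocks[-1L, 1L] - blocks[-k, 2L])
    parts <- c(rbind(parts[-k], gaps), parts[k])
  }
  paste(parts, collapse = "")
}

# Two SAM lines (as a matrix row per mate) for one fragment; `left`/`right`
# are the genomic block matrices of the two mates.
fragment_sam_records <- function(qname, chrom, left, right, rl,
                                 strand, library_type) {
  # FR pair: genomic-left mate aligns '+', right mate '-'. For dUTP
  # (fr-firststrand) the sense read is mate 2; sense is genomic-left for
  # forward transcripts. fr-secondstrand swaps mate roles; unstranded data
  # is emitted with the firststrand layout (orientation then carries no
  # signal, as in real unstranded libraries).
  sense_left <- strand == "forward"
  mate2_left <- switch(library_type,
                       "fr-firststrand" = sense_left,
                       "fr-secondstrand" = !sense_left,
                       sense_left)
  xs <- if (strand == "forward") "+" else "-"
  span_l <- min(left[, 1L])
  span_r <- max(right[, 2L])
  tlen <- span_r - span_l
  mk <- function(blocks, is_first, fwd, mate_pos, tl) {
    flag <- 1L + 2L + (if (is_first) 64L else 128L) +
      (if (fwd) 0L else 16L) + (if (fwd) 32L else 0L)
    spliced <- nrow(blocks) > 1L
    tags <- c("NH:i:1", if (spliced) sprintf("XS:A:%s", xs))
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s\t%s",
            qname, flag, chrom, blocks[1L, 1L] + 1L, blocks_cigar(blocks),
            mate_pos, tl, strrep("A", rl), strrep("I", rl),
            paste(tags, collapse = "\t"))
  }
  lpos <- left[1L, 1L] + 1L
  rpos <- right[1L, 1L] + 1L
  l_first <- !mate2_left
  rows <- rbind(
    c(pos = lpos, line = mk(left, l_first, TRUE, rpos, tlen)),
    c(pos = rpos, line = mk(right, !l_first, FALSE, lpos, -tlen)))
  rows
}

#' Score an assembly against a truth annotation
#'
#' A multi-exon transcript matches when a counterpart has the identical
#' intron chain (terminal exon ends are free). A single-exon transcript
#' matches when a predicted single-exon transcript is contained in, and
#' covers at least 75% of, a truth single-exon transcript. Comparison is
#' strand-agnostic by default (the conservative convention).
#'
#' @param predicted An `Assembly`, a GTF path, or a [read_gtf()]-style list.
#' @param truth Same forms as `predicted`.
#' @param strand_agnostic Ignore strand when matching (default TRUE).
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_predicted`,
#'   `truth_matched` (logical vector).
#' @export
match_transcripts <- function(predicted, truth, strand_agnostic = TRUE) {
  pred <- as_transcript_models(predicted)
  tru <- as_transcript_models(truth)
  if (length(tru) == 0L || length(pred) == 0L) {
    return(list(sensitivity = 0, precision = 0, n_truth = length(tru),
                n_predicted = length(pred),
                truth_matched = logical(length(tru))))
  }
  key <- function(tx) {
    s <- if (strand_agnostic) "" else tx$strand
    if (nrow(tx$introns) > 0L) {
      paste(tx$chrom, s, paste(tx$introns[, 1L], tx$introns[, 2L],
                               sep = "-", collapse = ","))
    } else NA_character_
  }
  pk <- vapply(pred, key, character(1L))
  tk <- vapply(tru, key, character(1L))
  single_match <- function(p, t) {
    if (nrow(p$introns) > 0L || nrow(t$introns) > 0L) return(FALSE)
    if (p$chrom != t$chrom) return(FALSE)
    if (!strand_agnostic && p$strand != t$strand) return(FALSE)
    ps <- p$exons[1L, 1L]; pe <- p$exons[1L, 2L]
    ts <- t$exons[1L, 1L]; te <- t$exons[1L, 2L]
    ps >= ts && pe <= te && (pe - ps) >= 0.75 * (te - ts)
  }
  truth_matched <- vapply(seq_along(tru), function(i) {
    if (!is.na(tk[i])) return(tk[i] %in% pk)
    any(vapply(pred, single_match, logical(1L), t = tru[[i]]))
  }, logical(1L))
  pred_matched <- vapply(seq_along(pred), function(i) {
    if (!is.na(pk[i])) return(pk[i] %in% tk)
    any(vapply(tru, function(t) single_match(pred[[i]], t), logical(1L)))
  }, logical(1L))
  list(sensitivity = mean(truth_matched), precision = mean(pred_matched),
       n_truth = length(tru), n_predicted = length(pred),
       truth_matched = truth_matched)
}

# Coerce assemblies / GTF paths / model lists to a list of transcript models.
as_transcript_models <- function(x) {
  if (inherits(x, "Assembly")) {
    return(lapply(x$transcripts, function(t)
      list(chrom = t$chrom, strand = t$strand, exons = t$exons,
           introns = t$introns)))
  }
  if (is.character(x) && length(x) == 1L) return(read_gtf(x))
  x
}
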