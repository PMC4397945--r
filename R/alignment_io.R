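#' Load paired-end fragments from a SAM/BAM file
#'
#' Reads a coordinate-sorted SAM or BAM file and returns the set of sequencing
#' fragments (read pairs) that survive the assembler's input filters: only
#' proper pairs are kept, multimapping pairs are removed, and putative PCR
#' duplicates (pairs with identical chromosome, block structure of both mates
#' and strand evidence) are collapsed to a single representative.
#'
#' Strand evidence per fragment is resolved by [infer_fragment_strand()]:
#' deterministically from mate orientation for stranded protocols, from the
#' `XS:A` transcription-strand tag of spliced aligners for unstranded data.
#'
#' @param alignment_source Path to a SAM or BAM file. SAM input is converted
#'   on the fly with [Rsamtools::asBam()].
#' @param library_type One of `"unstranded"`, `"fr-firststrand"`,
#'   `"fr-secondstrand"`.
#' @param verbose Emit per-filter counts as messages.
#' @return A `FragmentSet`: list with `fragments` (data frame with one row per
#'   retained fragment and list-columns `blocks1`, `blocks2`, `introns` of
#'   0-based half-open interval matrices), `n`, `library_type` and a `stats`
#'   list of filter counts.
#' @export
load_fragments <- function(alignment_source,
                           library_type = c("unstranded", "fr-firststrand",
                                            "fr-secondstrand"),
                           verbose = FALSE) {
  library_type <- match.arg(library_type)
  if (!file.exists(alignment_source)) {
    stop("alignment source not readable: ", alignment_source)
  }
  bam <- alignment_source
  if (grepl("\\.sam$", alignment_source, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(alignment_source, destination = dest,
                       overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("failed to read SAM input: ",
                               conditionMessage(e)))
  }
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = c("NH", "XS"))
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) stop("failed to read alignments: ",
                                           conditionMessage(e)))
  qname <- res$qname
  stats <- list(records = length(qname), orphans = 0L, multimapping = 0L,
                duplicates = 0L)
  empty <- function() {
    fs <- list(fragments = empty_fragment_table(), n = 0L,
               library_type = library_type, stats = stats)
    class(fs) <- "FragmentSet"
    fs
  }
  if (length(qname) == 0L) return(empty())

  fl <- res$flag
  is_first <- bitwAnd(fl, 64L) > 0L
  is_second <- bitwAnd(fl, 128L) > 0L
  nh <- res$tag$NH %||% rep(NA_integer_, length(qname))
  xs <- res$tag$XS %||% rep(NA_character_, length(qname))

  # Pair mates by name; a usable pair has exactly one first and one second
  # mate record. Names violating that are multimapping (too many records)
  # or orphaned (mate record missing despite the paired flag).
  n_first <- table(factor(qname[is_first]))
  n_second <- table(factor(qname[is_second]))
  all_names <- union(names(n_first), names(n_second))
  c1 <- as.integer(n_first[all_names]); c1[is.na(c1)] <- 0L
  c2 <- as.integer(n_second[all_names]); c2[is.na(c2)] <- 0L
  multi <- (c1 > 1L) | (c2 > 1L)
  orphan <- !multi & ((c1 == 0L) | (c2 == 0L))
  good <- all_names[!multi & !orphan]
  stats$multimapping <- sum(multi)
  stats$orphans <- sum(orphan)

  i1 <- match(good, qname[is_first])
  i2 <- match(good, qname[is_second])
  idx1 <- which(is_first)[i1]
  idx2 <- which(is_second)[i2]

  # NH-declared multimappers: the aligner reported >1 hits for either mate.
  nh_multi <- !is.na(nh[idx1]) & nh[idx1] > 1L |
              !is.na(nh[idx2]) & nh[idx2] > 1L
  stats$multimapping <- stats$multimapping + sum(nh_multi)
  keep <- !nh_multi
  idx1 <- idx1[keep]; idx2 <- idx2[keep]; good <- good[keep]

  same_chrom <- as.character(res$rname[idx1]) == as.character(res$rname[idx2])
  idx1 <- idx1[same_chrom]; idx2 <- idx2[same_chrom]; good <- good[same_chrom]
  if (length(good) == 0L) return(empty())

  blocks1 <- mapply(cigar_blocks, res$pos[idx1], res$cigar[idx1],
                    SIMPLIFY = FALSE)
  blocks2 <- mapply(cigar_blocks, res$pos[idx2], res$cigar[idx2],
                    SIMPLIFY = FALSE)
  strand1 <- as.character(res$strand[idx1])
  strand_ev <- vapply(seq_along(good), function(i) {
    infer_fragment_strand(
      list(mate1_strand = strand1[i],
           xs = c(xs[idx1[i]], xs[idx2[i]]),
           spliced = nrow(blocks1[[i]]) > 1L || nrow(blocks2[[i]]) > 1L),
      library_type)
  }, character(1L))
  strand_ev[strand_ev == "undetermined"] <- "none"

  frag <- data.frame(
    fragment_id = good,
    chrom = as.character(res$rname[idx1]),
    strand = strand_ev,
    stringsAsFactors = FALSE)
  frag$blocks1 <- blocks1
  frag$blocks2 <- blocks2
  frag$introns <- lapply(seq_along(good), function(i) {
    unique_intervals(rbind(blocks_introns(blocks1[[i]]),
                           blocks_introns(blocks2[[i]])))
  })
  frag$start <- vapply(seq_along(good), function(i)
    min(blocks1[[i]][, 1L], blocks2[[i]][, 1L]), integer(1L))
  frag$end <- vapply(seq_along(good), function(i)
    max(blocks1[[i]][, 2L], blocks2[[i]][, 2L]), integer(1L))

  # Putative PCR duplicates: identical chrom + block structure + strand.
  key <- paste(frag$chrom, frag$strand,
               mapply(blocks_key, frag$blocks1, frag$blocks2))
  dup <- duplicated(key)
  stats$duplicates <- sum(dup)
  frag <- frag[!dup, , drop = FALSE]
  frag <- frag[order(frag$chrom, frag$start, frag$end), , drop = FALSE]
  rownames(frag) <- NULL

  if (verbose) {
    message(sprintf(
      "load_fragments: %d records; %d pairs kept (%d orphans, %d multimapping, %d duplicates removed)",
      stats$records, nrow(frag), stats$orphans, stats$multimapping,
      stats$duplicates))
  }
  fs <- list(fragments = frag, n = nrow(frag), library_type = library_type,
             stats = stats)
  class(fs) <- "FragmentSet"
  fs
}

empty_fragment_table <- function() {
  frag <- data.frame(fragment_id = character(0), chrom = character(0),
                     strand = character(0), stringsAsFactors = FALSE)
  frag$blocks1 <- list()
  frag$blocks2 <- list()
  frag$introns <- list()
  frag$start <- integer(0)
  frag$end <- integer(0)
  frag
}

#' Resolve the strand of transcription for one fragment
#'
#' For stranded protocols the strand is a deterministic function of the first
#' mate's alignment orientation: `fr-firststrand` (dUTP) libraries sequence
#' mate 1 antisense to the transcript, `fr-secondstrand` libraries sequence it
#' sense. For unstranded libraries the only evidence is the `XS:A` tag that
#' spliced aligners attach to junction-spanning reads; contradictory tags
#' between the two mates, or no tag at all, yield `"undetermined"`.
#'
#' @param fragment A list with `mate1_strand` (`"+"` or `"-"`, alignment
#'   strand of the first mate), `xs` (character vector of XS tag values from
#'   both mates, `NA` where absent).
#' @param library_type See [load_fragments()].
#' @return `"forward"`, `"reverse"` or `"undetermined"`.
#' @export
infer_fragment_strand <- function(fragment,
                                  library_type = c("unstranded",
                                                   "fr-firststrand",
                                                   "fr-secondstrand")) {
  library_type <- match.arg(library_type)
  if (library_type == "fr-firststrand") {
    return(if (fragment$mate1_strand == "-") "forward" else "reverse")
  }
  if (library_type == "fr-secondstrand") {
    return(if (fragment$mate1_strand == "+") "forward" else "reverse")
  }
  tags <- unique(fragment$xs[!is.na(fragment$xs)])
  if (length(tags) != 1L) return("undetermined")
  if (tags == "+") "forward" else if (tags == "-") "reverse" else "undetermined"
}
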