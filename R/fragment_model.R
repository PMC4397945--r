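#' Fragment-length model
#'
#' Gaussian model of the cDNA fragment length (in transcript coordinates),
#' used both for the fragment-given-candidate likelihood and for effective
#' transcript lengths.
#'
#' @param mu Mean fragment length (nt).
#' @param sigma Standard deviation (nt); `sigma = 0` is the degenerate
#'   point-mass model (useful in tests).
#' @return A `FragmentLengthModel`.
#' @export
fragment_length_model <- function(mu, sigma) {
  stopifnot(mu > 0, sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "FragmentLengthModel")
}

#' @export
print.FragmentLengthModel <- function(x, ...) {
  cat(sprintf("FragmentLengthModel: mu=%.2f sigma=%.2f\n", x$mu, x$sigma))
  invisible(x)
}

#' Estimate fragment-length parameters from single-transcript loci
#'
#' Fragment lengths are measured in transcript coordinates on loci whose
#' splice graph admits exactly one path at least `min_len` nt long, where the
#' transcript identity is unambiguous. Robust estimators are used: the median
#' for `mu` and the (Gaussian-consistent, 1.4826-scaled) median absolute
#' deviation for `sigma`.
#'
#' @param graphs List of `SpliceGraph`s.
#' @param min_len Minimum transcript length for a locus to qualify (default
#'   2500 nt).
#' @param default_mu,default_sigma Fallback parameters used, with a warning,
#'   when no locus qualifies.
#' @param path_sets Optional pre-computed [enumerate_paths()] results.
#' @return A `FragmentLengthModel`; attribute `n_fragments` records how many
#'   lengths entered the estimate (0 on the fallback path).
#' @export
estimate_fragment_length_model <- function(graphs, min_len = 2500L,
                                           default_mu = 250,
                                           default_sigma = 25,
                                           path_sets = NULL) {
  if (is.null(path_sets)) path_sets <- lapply(graphs, enumerate_paths)
  lens <- numeric(0)
  for (i in seq_along(graphs)) {
    cs <- path_sets[[i]]
    if (cs$m != 1L) next
    cand <- cs$candidates[[1L]]
    if (cand$length < min_len) next
    frag <- graphs[[i]]$fragments
    li <- vapply(seq_len(nrow(frag)), function(j) {
      fragment_transcript_length(frag$blocks1[[j]], frag$blocks2[[j]], cand)
    }, numeric(1L))
    lens <- c(lens, li[!is.na(li)])
  }
  if (length(lens) == 0L) {
    warning("no single-transcript locus >= ", min_len,
            " nt; falling back to mu=", default_mu, ", sigma=", default_sigma)
    m <- fragment_length_model(default_mu, default_sigma)
    attr(m, "n_fragments") <- 0L
    return(m)
  }
  m <- fragment_length_model(median(lens), mad(lens))
  attr(m, "n_fragments") <- length(lens)
  m
}

# Transcript-coordinate span (length) of a fragment on a candidate, or NA if
# incompatible. A mate is compatible when each aligned block sits inside a
# single candidate exon and successive blocks are contiguous in transcript
# coordinates (i.e. the mate's introns are exactly candidate introns).
# Candidate introns falling wholly inside the unsequenced inter-mate insert
# are allowed: they are spliced out of the fragment.
fragment_transcript_length <- function(blocks1, blocks2, cand) {
  ex <- cand$exons
  cumw <- c(0L, cumsum(ex[, 2L] - ex[, 1L]))
  tproj <- function(blocks) {
    t0 <- NA_integer_; t1 <- NA_integer_
    prev_end <- NA_integer_
    for (k in seq_len(nrow(blocks))) {
      bs <- blocks[k, 1L]; be <- blocks[k, 2L]
      e <- which(ex[, 1L] <= bs & ex[, 2L] >= be)
      if (length(e) != 1L) return(NULL)
      ts <- cumw[e] + (bs - ex[e, 1L])
      te <- ts + (be - bs)
      if (k == 1L) t0 <- ts else if (ts != prev_end) return(NULL)
      prev_end <- te
      t1 <- te
    }
    c(t0, t1)
  }
  p1 <- tproj(blocks1)
  if (is.null(p1)) return(NA_real_)
  p2 <- tproj(blocks2)
  if (is.null(p2)) return(NA_real_)
  len <- max(p1[2L], p2[2L]) - min(p1[1L], p2[1L])
  if (len < 1L || len > cand$length) return(NA_real_)
  len
}

# Discrete truncated-Gaussian pmf weights over lengths 1..L.
trunc_length_pmf <- function(L, model) {
  if (model$sigma == 0) {
    ell <- min(max(round(model$mu), 1L), L)
    w <- numeric(L)
    w[ell] <- 1
    return(w)
  }
  w <- dnorm(seq_len(L), model$mu, model$sigma)
  s <- sum(w)
  if (s <= 0) {
    # fragment distribution has essentially no mass on [1, L]; fall back to
    # the nearest boundary point
    w <- numeric(L)
    w[if (model$mu > L) L else 1L] <- 1
    return(w)
  }
  w / s
}

#' Effective transcript length
#'
#' The expected number of valid fragment start positions on a transcript of
#' length `L`: `sum_l P(length = l | model, truncated to [1, L]) * (L - l + 1)`,
#' clamped below at 1. Divides the fragment likelihood and converts abundances
#' to length-normalized units.
#'
#' @param candidate A `TranscriptCandidate`, or a plain transcript length.
#' @param model A `FragmentLengthModel`.
#' @return Positive scalar.
#' @export
effective_length <- function(candidate, model) {
  L <- if (inherits(candidate, "TranscriptCandidate")) candidate$length
       else as.integer(candidate)
  stopifnot(L >= 1L)
  w <- trunc_length_pmf(L, model)
  max(sum(w * (L - seq_len(L) + 1L)), 1)
}

#' Fragment-given-candidate likelihood
#'
#' Zero when the fragment's block structure is incompatible with the
#' candidate (an observed intron absent from the candidate, an aligned base
#' outside candidate exons, or an invalid implied transcript-coordinate
#' span); otherwise the truncated-Gaussian probability of the implied
#' fragment length divided by the candidate's effective length.
#'
#' @param fragment One row of a `FragmentSet$fragments` data frame (or any
#'   list with `blocks1`, `blocks2` interval matrices).
#' @param candidate A `TranscriptCandidate`.
#' @param model A `FragmentLengthModel`.
#' @return Non-negative scalar.
#' @export
fragment_likelihood <- function(fragment, candidate, model) {
  b1 <- if (is.data.frame(fragment)) fragment$blocks1[[1L]] else fragment$blocks1
  b2 <- if (is.data.frame(fragment)) fragment$blocks2[[1L]] else fragment$blocks2
  len <- fragment_transcript_length(b1, b2, candidate)
  if (is.na(len)) return(0)
  w <- trunc_length_pmf(candidate$length, model)
  w[len] / effective_length(candidate, model)
}

#' Fragment-by-candidate likelihood matrix
#'
#' Dense `n x m` matrix of [fragment_likelihood()] values for one inference
#' unit. Fragments incompatible with every candidate carry no information
#' under a model without a noise component and are dropped (their count is
#' recorded in the `dropped` attribute); every returned row has at least one
#' positive entry.
#'
#' @param candidate_set A `CandidateSet` from [finalize_candidates()].
#' @param model A `FragmentLengthModel`.
#' @return Numeric matrix with attributes `dropped` (number of all-zero rows
#'   removed) and `effective_lengths` (per-candidate).
#' @export
build_likelihood_matrix <- function(candidate_set, model) {
  frag <- candidate_set$fragments
  cands <- candidate_set$candidates
  n <- nrow(frag); m <- length(cands)
  eff <- vapply(cands, effective_length, numeric(1L), model = model)
  pmfs <- lapply(cands, function(cand) trunc_length_pmf(cand$length, model))
  L <- matrix(0, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    cand <- cands[[j]]
    for (i in seq_len(n)) {
      len <- fragment_transcript_length(frag$blocks1[[i]], frag$blocks2[[i]],
                                        cand)
      if (!is.na(len)) L[i, j] <- pmfs[[j]][len] / eff[j]
    }
  }
  keep <- rowSums(L) > 0
  out <- L[keep, , drop = FALSE]
  rownames(out) <- frag$fragment_id[keep]
  attr(out, "dropped") <- sum(!keep)
  attr(out, "effective_lengths") <- eff
  out
}
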