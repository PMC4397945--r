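# helper: single-exon transcript graph with fragments of given lengths
length_fixture_graph <- function(lengths, L = 3000L, rl = 100L) {
  frags <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    len <- lengths[i]
    s <- (i * 37L) %% (L - len)  # deterministic spread of start positions
    frag_row(sprintf("f%d", i), iv(s, s + rl), iv(s + len - rl, s + len))
  }))
  make_graph(iv(0L, L), edges_df(), fragments = frags)
}

test_that("median/MAD estimators recover simple and Gaussian lengths", {
  g <- length_fixture_graph(c(240L, 250L, 260L))
  m <- estimate_fragment_length_model(list(g), min_len = 2500L)
  expect_identical(m$mu, 250)
  # Monte-Carlo consistency: 1e4 Gaussian(250, 25) lengths
  set.seed(88)
  lens <- pmax(100L, as.integer(round(rnorm(1e4, 250, 25))))
  g2 <- length_fixture_graph(lens)
  m2 <- estimate_fragment_length_model(list(g2), min_len = 2500L)
  expect_lt(abs(m2$mu - 250), 1)
  expect_lt(abs(m2$sigma - 25), 1)
  expect_identical(attr(m2, "n_fragments"), 10000L)
})

test_that("estimation falls back to defaults without qualifying loci", {
  short <- make_graph(iv(0L, 2400L), edges_df(), fragments = rbind(
    frag_row("a", iv(0, 100), iv(150, 250)),
    frag_row("b", iv(10, 110), iv(160, 260))))
  expect_warning(
    m <- estimate_fragment_length_model(list(short), min_len = 2500L,
                                        default_mu = 200, default_sigma = 20),
    "falling back")
  expect_identical(m$mu, 200)
  expect_identical(m$sigma, 20)
  # multi-path graphs never qualify, whatever their length
  bubble <- make_graph(iv(0, 2000, 2100, 2600, 2700, 5000),
                       edges_df(c(1L, 1L, 2L), c(2L, 3L, 3L), c(2L, 2L, 2L)),
                       fragments = rbind(
                         frag_row("a", iv(0, 100), iv(150, 250)),
                         frag_row("b", iv(10, 110), iv(160, 260))))
  expect_warning(estimate_fragment_length_model(list(bubble)), "falling back")
})

test_that("effective length follows the truncated-length expectation", {
  delta <- fragment_length_model(200, 0)
  expect_identical(effective_length(1000L, delta), 801)  # L - mu + 1
  expect_identical(effective_length(200L, delta), 1)     # L = mu
  # fragment longer than the transcript: truncation + clamp keep it >= 1
  expect_gte(effective_length(150L, delta), 1)
  expect_gte(effective_length(5L, fragment_length_model(250, 25)), 1)
  # analytic cross-check for a two-point truncated distribution
  m <- fragment_length_model(10, 25)
  L <- 30L
  w <- dnorm(1:L, 10, 25); w <- w / sum(w)
  expect_equal(effective_length(L, m), sum(w * (L - 1:L + 1)))
})

test_that("incompatible fragments get zero likelihood", {
  cand <- make_candidate(iv(0, 100, 200, 300, 400, 500))
  model <- fragment_length_model(150, 20)
  # intron absent from the candidate
  f_bad <- frag_row("x", iv(0, 50, 350, 400), iv(420, 480))
  expect_identical(fragment_likelihood(f_bad, cand, model), 0)
  # aligned base inside a candidate intron
  f_in_intron <- frag_row("y", iv(120, 180), iv(220, 280))
  expect_identical(fragment_likelihood(f_in_intron, cand, model), 0)
  # unspliced block running across a candidate intron
  f_span <- frag_row("z", iv(80, 220), iv(230, 290))
  expect_identical(fragment_likelihood(f_span, cand, model), 0)
  # compatible spliced fragment: intron chain matches exactly
  f_ok <- frag_row("ok", iv(50, 100, 200, 250), iv(260, 300, 400, 410))
  expect_gt(fragment_likelihood(f_ok, cand, model), 0)
})

test_that("likelihood is the truncated density over effective length", {
  cand <- make_candidate(iv(0, 1000))
  model <- fragment_length_model(250, 25)
  f <- frag_row("f", iv(100, 200), iv(250, 350))  # length_t = 250 = mu
  w <- dnorm(1:1000, 250, 25); w <- w / sum(w)
  expect_equal(fragment_likelihood(f, cand, model),
               w[250] / effective_length(1000L, model))
  # two candidates, equal effective length, equidistant lengths => equal
  cand2 <- make_candidate(iv(5000, 6000))
  f_lo <- frag_row("lo", iv(100, 200), iv(240, 340))      # span 240
  f_hi <- frag_row("hi", iv(5100, 5200), iv(5260, 5360))  # span 260
  expect_equal(fragment_likelihood(f_lo, cand, model),
               fragment_likelihood(f_hi, cand2, model))
})

test_that("positive likelihood implies per-mate intron-chain containment", {
  set.seed(31)
  model <- fragment_length_model(250, 25)
  for (rep in 1:20) {
    ne <- sample(2:5, 1L)
    starts <- cumsum(c(0L, sample(150:500, ne - 1L, TRUE)))
    widths <- sample(100:300, ne, TRUE)
    cand <- make_candidate(cbind(start = starts, end = starts + widths))
    # random (not necessarily compatible) fragment blocks
    b1 <- iv(sample(0:600, 1L), 0)
    b1[1L, 2L] <- b1[1L, 1L] + sample(50:150, 1L)
    b2s <- b1[1L, 1L] + sample(50:300, 1L)
    b2 <- iv(b2s, b2s + sample(50:150, 1L))
    f <- frag_row("r", b1, b2)
    lik <- fragment_likelihood(f, cand, model)
    if (lik > 0) {
      for (bl in list(b1, b2)) {
        intr <- bayestx:::blocks_introns(bl)
        if (nrow(intr) > 0L) {
          expect_true(all(paste(intr[, 1L], intr[, 2L]) %in%
                            paste(cand$introns[, 1L], cand$introns[, 2L])))
        }
        # every aligned base inside the exon union
        for (k in seq_len(nrow(bl))) {
          expect_true(any(cand$exons[, 1L] <= bl[k, 1L] &
                            cand$exons[, 2L] >= bl[k, 2L]))
        }
      }
    }
  }
})

test_that("likelihood matrix has positive rows and records drops", {
  cands <- list(make_candidate(iv(0, 500)),
                make_candidate(iv(0, 200, 300, 600)))
  frags <- rbind(
    frag_row("a", iv(10, 110), iv(150, 250)),     # compatible with both
    frag_row("b", iv(100, 200, 300, 350), iv(320, 420)),  # only spliced
    frag_row("c", iv(2000, 2100), iv(2200, 2300)))  # compatible with none
  cs <- structure(list(chrom = "chrT", strand = "forward",
                       candidates = cands, m = 2L, fragments = frags,
                       locus_id = "L1"), class = "CandidateSet")
  L <- build_likelihood_matrix(cs, fragment_length_model(250, 25))
  expect_identical(dim(L), c(2L, 2L))
  expect_identical(attr(L, "dropped"), 1L)
  expect_true(all(rowSums(L > 0) >= 1))
  expect_identical(unname(L["b", 1L]), 0)
  expect_gt(L["b", 2L], 0)
})

test_that("common effective-length scaling leaves the posterior unchanged", {
  set.seed(12)
  L <- matrix(rexp(8), 4L, 2L)
  p1 <- exact_posterior(L, 0.5, 1)
  p2 <- exact_posterior(L * 3.7, 0.5, 1)
  expect_equal(p1$p_expressed, p2$p_expressed, tolerance = 1e-12)
  expect_equal(p1$mean_e, p2$mean_e, tolerance = 1e-12)
})

test_that("pre-mRNA rows are positive for unspliced in-locus fragments", {
  pre <- make_candidate(iv(0, 9000), is_premrna = TRUE)
  model <- fragment_length_model(250, 25)
  f_unspliced <- frag_row("u", iv(1000, 1100), iv(1150, 1250))
  f_spliced <- frag_row("s", iv(1000, 1100, 2000, 2050), iv(2010, 2110))
  expect_gt(fragment_likelihood(f_unspliced, pre, model), 0)
  expect_identical(fragment_likelihood(f_spliced, pre, model), 0)
})
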