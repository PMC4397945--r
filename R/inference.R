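#' Estimate the sparsity prior by greedy minimum set cover
#'
#' The Bernoulli parameter of the spike-and-slab prior is set to
#' `pi = m_min / m`, where `m_min` is the size of a greedy minimum set cover:
#' the smallest number of candidates (greedily chosen) needed to explain every
#' fragment, a fragment being explainable by any candidate with positive
#' likelihood for it. Ties are broken toward the lowest candidate index.
#'
#' @param likelihood_matrix `n x m` matrix, every row with a positive entry.
#' @return A `SparsityPrior`: list with `pi`, `m`, `m_min` and the
#'   normalization constant `k_z0 = 1 / (1 - (1 - pi)^m)` of the
#'   zero-truncated Bernoulli prior.
#' @export
estimate_pi <- function(likelihood_matrix) {
  stopifnot(is.matrix(likelihood_matrix), nrow(likelihood_matrix) >= 1L)
  stopifnot(all(rowSums(likelihood_matrix > 0) > 0))
  inc <- likelihood_matrix > 0
  m <- ncol(inc)
  uncovered <- rep(TRUE, nrow(inc))
  m_min <- 0L
  while (any(uncovered)) {
    gain <- colSums(inc & uncovered)
    pick <- which.max(gain)  # which.max takes the first (lowest index) tie
    uncovered <- uncovered & !inc[, pick]
    m_min <- m_min + 1L
  }
  sparsity_prior(m_min / m, m, m_min = m_min)
}

#' @rdname estimate_pi
#' @param pi Bernoulli inclusion probability in (0, 1].
#' @param m Number of candidates.
#' @param m_min Optional set-cover size stored for reporting.
#' @export
sparsity_prior <- function(pi, m, m_min = NA_integer_) {
  stopifnot(pi > 0, pi <= 1, m >= 1L)
  structure(list(pi = pi, m = as.integer(m),
                 k_z0 = 1 / (1 - (1 - pi)^m), m_min = m_min),
            class = "SparsityPrior")
}

#' Conditional distribution of the number of expressed candidates
#'
#' Probabilities of `b_z` (the number of expressed candidates) given the
#' current assignment counts `c`, marginalizing the Dirichlet abundances:
#' on the support `|J+| .. m`,
#' `P(b) \propto choose(|J0|, b - |J+|) * Gamma(b*gamma) / Gamma(n + b*gamma)
#'  * pi^b * (1 - pi)^(m - b)`,
#' where `J+`/`J0` are the candidate index sets with `c > 0` / `c = 0`.
#' Computed in log space with log-sum-exp normalization.
#'
#' @param c_counts Integer vector of per-candidate assignment counts.
#' @param prior A `SparsityPrior` (or a plain probability `pi`).
#' @param gamma Symmetric Dirichlet concentration (default 1).
#' @return Numeric vector of probabilities named by `b_z` values
#'   `|J+|, ..., m`.
#' @export
num_expressed_distribution <- function(c_counts, prior, gamma = 1) {
  pi <- if (inherits(prior, "SparsityPrior")) prior$pi else prior
  m <- length(c_counts)
  n <- sum(c_counts)
  stopifnot(n >= 1L, pi > 0, pi <= 1)
  jp <- sum(c_counts > 0L)
  j0 <- m - jp
  b <- seq.int(max(jp, 1L), m)
  lw <- lchoose(j0, b - jp) + lgamma(b * gamma) - lgamma(n + b * gamma) +
    b * log(pi) + ifelse(m - b == 0L, 0, (m - b) * log1p(-pi))
  p <- exp(lw - log_sum_exp(lw))
  setNames(p / sum(p), b)
}

#' @rdname num_expressed_distribution
#' @return `sample_num_expressed` draws one value of `b_z`.
#' @export
sample_num_expressed <- function(c_counts, prior, gamma = 1) {
  p <- num_expressed_distribution(c_counts, prior, gamma)
  b <- as.integer(names(p))
  if (length(b) == 1L) return(b)
  b[sample.int(length(b), 1L, prob = p)]
}

#' Sample the binary expression vector given its sum
#'
#' Candidates with assigned fragments (`c > 0`) are necessarily expressed;
#' the remaining `b_z - |J+|` expressed slots are drawn uniformly without
#' replacement from the zero-count candidates.
#'
#' @param b_z Number of expressed candidates, `|J+| <= b_z <= m`.
#' @param c_counts Assignment counts.
#' @return Integer 0/1 vector of length `m`.
#' @export
sample_expression_vector <- function(b_z, c_counts) {
  m <- length(c_counts)
  j_plus <- which(c_counts > 0L)
  j_zero <- which(c_counts == 0L)
  extra <- b_z - length(j_plus)
  stopifnot(extra >= 0L, b_z <= m)
  z <- integer(m)
  z[j_plus] <- 1L
  if (extra > 0L) {
    h <- if (length(j_zero) == 1L) j_zero
         else j_zero[sample.int(length(j_zero), extra)]
    z[h] <- 1L
  }
  z
}

#' Sample abundances given expression and counts
#'
#' Expressed abundances follow `Dirichlet(c+ + gamma)`; unexpressed
#' candidates have exactly zero abundance.
#'
#' @param z 0/1 expression vector.
#' @param c_counts Assignment counts consistent with `z` (`c > 0 => z = 1`).
#' @param gamma Dirichlet concentration.
#' @return Numeric abundance vector summing to 1, zero where `z` is zero.
#' @export
sample_abundances <- function(z, c_counts, gamma = 1) {
  stopifnot(all(c_counts[z == 0L] == 0L), sum(z) >= 1L)
  e <- numeric(length(z))
  idx <- which(z == 1L)
  g <- rgamma(length(idx), shape = c_counts[idx] + gamma, rate = 1)
  if (all(g == 0)) g[] <- 1  # numerically impossible Dirichlet draw guard
  e[idx] <- g / sum(g)
  e
}

#' Sample fragment-to-candidate assignments
#'
#' Each fragment is assigned independently with probability proportional to
#' `likelihood * abundance`.
#'
#' @param e Abundance vector summing to 1.
#' @param likelihood_matrix `n x m` likelihood values.
#' @return List with `t` (assignments) and `c` (tallied counts).
#' @export
sample_assignments <- function(e, likelihood_matrix) {
  n <- nrow(likelihood_matrix)
  m <- ncol(likelihood_matrix)
  W <- likelihood_matrix * rep(e, each = n)
  tot <- rowSums(W)
  if (any(tot <= 0)) {
    stop("fragment with zero posterior mass under all expressed candidates")
  }
  cs <- W %*% upper.tri(diag(m), diag = TRUE)  # row-wise cumulative sums
  u <- runif(n) * tot
  t_idx <- pmin(as.integer(rowSums(cs < u) + 1L), m)  # pmin: float guard
  list(t = t_idx, c = tabulate(t_idx, nbins = m))
}

#' Gibbs schedule
#'
#' Burn-in is the affine function `60 m + 1000` of the number of candidates;
#' the retained sample size is 10 times the burn-in.
#'
#' @param m Number of candidates.
#' @return List with `burn_in` and `samples`.
#' @export
gibbs_schedule <- function(m) {
  stopifnot(m >= 1L)
  burn <- 60L * as.integer(m) + 1000L
  list(burn_in = burn, samples = 10L * burn)
}

#' Run the Gibbs sampler for one inference unit
#'
#' Assignments are initialized uniformly over each fragment's
#' positive-likelihood candidates; each iteration then samples, in order, the
#' number of expressed candidates, the expression vector, the abundances and
#' the fragment assignments. The default engine is compiled (identical model,
#' much faster); the pure-R engine exists for cross-checking and uses the
#' exported single-step samplers.
#'
#' @param likelihood_matrix `n x m` matrix, all rows with a positive entry.
#' @param prior A `SparsityPrior`.
#' @param gamma Dirichlet concentration (default 1).
#' @param schedule List with `burn_in`, `samples`; default [gibbs_schedule()]
#'   of `m`.
#' @param engine `"cpp"` or `"r"`.
#' @param keep_trace Keep per-iteration `z` and `e` (memory: samples x m).
#' @return A `PosteriorSamples`: streaming accumulators `expressed_count`,
#'   `sum_e` (abundance summed over expressed iterations), `sum_c`, plus
#'   `retained`, `n`, `m` and optional `trace_z`, `trace_e`.
#' @export
run_gibbs <- function(likelihood_matrix, prior, gamma = 1, schedule = NULL,
                      engine = c("cpp", "r"), keep_trace = FALSE) {
  engine <- match.arg(engine)
  n <- nrow(likelihood_matrix)
  m <- ncol(likelihood_matrix)
  stopifnot(n >= 1L, m >= 1L, all(rowSums(likelihood_matrix > 0) > 0))
  if (is.null(schedule)) schedule <- gibbs_schedule(m)
  pi <- prior$pi

  # initialization: uniform over positive-likelihood candidates per fragment
  t0 <- vapply(seq_len(n), function(i) {
    ok <- which(likelihood_matrix[i, ] > 0)
    if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L)]
  }, integer(1L))

  res <- if (engine == "cpp") {
    gibbs_core(likelihood_matrix, pi, gamma, schedule$burn_in,
               schedule$samples, t0 - 1L, keep_trace)
  } else {
    gibbs_core_r(likelihood_matrix, pi, gamma, schedule, t0, keep_trace)
  }
  out <- list(expressed_count = as.integer(res$expressed_count),
              sum_e = as.numeric(res$sum_e),
              sum_c = as.numeric(res$sum_c),
              retained = as.integer(res$retained),
              n = n, m = m, schedule = schedule)
  if (keep_trace) {
    out$trace_z <- res$trace_z
    out$trace_e <- res$trace_e
    out$trace_c <- res$trace_c
  }
  class(out) <- "PosteriorSamples"
  out
}

# Reference R engine: same model and update order as the compiled core.
gibbs_core_r <- function(L, pi, gamma, schedule, t0, keep_trace) {
  n <- nrow(L); m <- ncol(L)
  prior <- sparsity_prior(pi, m)
  c_counts <- tabulate(t0, nbins = m)
  total <- schedule$burn_in + schedule$samples
  cnt <- integer(m); sum_e <- numeric(m); sum_c <- numeric(m)
  trace_z <- if (keep_trace) matrix(FALSE, schedule$samples, m)
  trace_e <- if (keep_trace) matrix(0, schedule$samples, m)
  trace_c <- if (keep_trace) matrix(0L, schedule$samples, m)
  retained <- 0L
  for (it in seq_len(total)) {
    b_z <- sample_num_expressed(c_counts, prior, gamma)
    z <- sample_expression_vector(b_z, c_counts)
    e <- sample_abundances(z, c_counts, gamma)
    a <- sample_assignments(e, L)
    c_counts <- a$c
    if (it > schedule$burn_in) {
      retained <- retained + 1L
      on <- z == 1L
      cnt[on] <- cnt[on] + 1L
      sum_e <- sum_e + e
      sum_c <- sum_c + c_counts
      if (keep_trace) {
        trace_z[retained, ] <- on
        trace_e[retained, ] <- e
        trace_c[retained, ] <- c_counts
      }
    }
  }
  list(expressed_count = cnt, sum_e = sum_e, sum_c = sum_c,
       retained = retained, trace_z = trace_z, trace_e = trace_e,
       trace_c = trace_c)
}

#' @export
print.PosteriorSamples <- function(x, ...) {
  cat(sprintf("PosteriorSamples: n=%d fragments, m=%d candidates, %d retained iterations\n",
              x$n, x$m, x$retained))
  conf <- x$expressed_count / x$retained
  cat("confidence:", paste(sprintf("%.3f", conf), collapse = " "), "\n")
  invisible(x)
}

#' Exact posterior by enumeration (testing oracle)
#'
#' Enumerates every assignment vector `t` in `{1..m}^n` and, for each, sums
#' analytically over all consistent expression vectors `z` of the collapsed
#' joint `P(z | pi) * Gamma(b_z g) / Gamma(n + b_z g) *
#' prod_k Gamma(c_k + g) / Gamma(g) * prod_i P(f_i | t_i)`. Returns exact
#' expression marginals and posterior mean abundances. Deliberately
#' independent of the Gibbs code path; refuses instances with `m^n > 1e6`.
#'
#' @param likelihood_matrix Small `n x m` matrix.
#' @param prior A `SparsityPrior` (or plain `pi`).
#' @param gamma Dirichlet concentration.
#' @return List with `p_expressed` (length m), `mean_e` (length m), and the
#'   log normalizing constant `log_evidence`.
#' @export
exact_posterior <- function(likelihood_matrix, prior, gamma = 1) {
  L <- likelihood_matrix
  n <- nrow(L); m <- ncol(L)
  pi <- if (inherits(prior, "SparsityPrior")) prior$pi else prior
  if (m^n > 1e6) stop("instance too large for exact enumeration: m^n > 1e6")
  logL <- log(L)
  lg <- lgamma(gamma)
  acc_norm <- -Inf
  acc_z <- rep(-Inf, m)
  acc_e <- rep(-Inf, m)
  t_vec <- rep(1L, n)
  repeat {
    ll <- sum(logL[cbind(seq_len(n), t_vec)])
    if (is.finite(ll)) {
      c_counts <- tabulate(t_vec, nbins = m)
      jp <- which(c_counts > 0L)
      j0n <- m - length(jp)
      lw_t <- ll + sum(lgamma(c_counts[jp] + gamma) - lg)
      b <- seq.int(length(jp), m)
      lwb <- lchoose(j0n, b - length(jp)) +
        lgamma(b * gamma) - lgamma(n + b * gamma) +
        b * log(pi) + ifelse(m - b == 0L, 0, (m - b) * log1p(-pi))
      tot_b <- log_sum_exp(lwb)
      acc_norm <- log_sum_exp(c(acc_norm, lw_t + tot_b))
      # z marginals: j in J+ always expressed; j in J0 expressed with
      # probability (b - |J+|)/|J0| within the b-stratum
      acc_z[jp] <- vapply(acc_z[jp], function(a)
        log_sum_exp(c(a, lw_t + tot_b)), numeric(1L))
      if (j0n > 0L) {
        frac <- (b - length(jp)) / j0n
        lz0 <- log_sum_exp(lwb + ifelse(frac > 0, log(frac), -Inf))
        jz <- which(c_counts == 0L)
        acc_z[jz] <- vapply(acc_z[jz], function(a)
          log_sum_exp(c(a, lw_t + lz0)), numeric(1L))
      }
      # E[e_j | t, b]: (c_j + g)/(n + b g) when expressed
      for (j in seq_len(m)) {
        if (c_counts[j] > 0L) {
          le <- log_sum_exp(lwb + log(c_counts[j] + gamma) -
                              log(n + b * gamma))
        } else {
          frac <- (b - length(jp)) / j0n
          le <- log_sum_exp(lwb + ifelse(frac > 0, log(frac), -Inf) +
                              log(gamma) - log(n + b * gamma))
        }
        acc_e[j] <- log_sum_exp(c(acc_e[j], lw_t + le))
      }
    }
    # advance the mixed-radix counter
    k <- 1L
    while (k <= n) {
      t_vec[k] <- t_vec[k] + 1L
      if (t_vec[k] <= m) break
      t_vec[k] <- 1L
      k <- k + 1L
    }
    if (k > n) break
  }
  list(p_expressed = exp(acc_z - acc_norm),
       mean_e = exp(acc_e - acc_norm),
       log_evidence = acc_norm)
}
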