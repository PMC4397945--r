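test_that("greedy set cover calibrates the sparsity prior", {
  # candidate 1 covers all 10 fragments, m = 4 => pi = 1/4
  L <- cbind(rep(1, 10), c(rep(1, 3), rep(0, 7)), rep(0.5, 10), rep(0, 10))
  L[, 4L][1L] <- 1
  prior <- estimate_pi(L)
  expect_identical(prior$m_min, 1L)
  expect_equal(prior$pi, 0.25)
  expect_equal(prior$k_z0, 1 / (1 - 0.75^4))
  # identity coverage: every candidate required
  expect_equal(estimate_pi(diag(3))$pi, 1)
  # single candidate
  expect_equal(estimate_pi(matrix(1, 5, 1))$pi, 1)
  # ties go to the lowest index
  L2 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_identical(estimate_pi(L2)$m_min, 2L)
})

test_that("b_z distribution matches hand-derived values and normalizes", {
  p <- num_expressed_distribution(c(2L, 0L), 0.5, 1)
  expect_equal(unname(p), c(0.75, 0.25), tolerance = 1e-12)
  expect_identical(names(p), c("1", "2"))
  p2 <- num_expressed_distribution(c(4L, 1L, 0L), 0.3, 1)
  expect_equal(unname(p2), c(0.89090909, 0.10909091), tolerance = 1e-6)
  expect_lt(abs(sum(p2) - 1), 1e-12)
})

test_that("b_z distribution agrees with brute-force z enumeration", {
  set.seed(2024)
  for (rep in 1:10) {
    m <- sample(2:5, 1L)
    n <- sample(1:12, 1L)
    c_counts <- as.integer(tabulate(sample.int(m, n, replace = TRUE),
                                    nbins = m))
    pi <- sample(c(0.1, 0.5, 0.9), 1L)
    gam <- sample(c(0.5, 1, 2), 1L)
    imp <- num_expressed_distribution(c_counts, pi, gam)
    ora <- oracle_bz_distribution(c_counts, pi, gam)
    expect_identical(names(imp), names(ora))
    expect_lt(max(abs(imp - ora) / ora), 1e-10)
  }
})

test_that("support collapses when every candidate has fragments", {
  p <- num_expressed_distribution(c(3L, 2L, 1L), 0.2, 1)
  expect_identical(names(p), "3")
  expect_equal(unname(p), 1)
  expect_identical(sample_num_expressed(c(3L, 2L, 1L),
                                        sparsity_prior(0.2, 3L)), 3L)
})

test_that("expression vector sampling is exact at the edges and uniform", {
  expect_identical(sample_expression_vector(1L, c(2L, 0L, 0L)),
                   c(1L, 0L, 0L))
  expect_identical(sample_expression_vector(3L, c(2L, 0L, 0L)),
                   c(1L, 1L, 1L))
  # uniformity of the H draw over J0 = {2, 3}
  set.seed(1)
  picks <- replicate(1e4, sample_expression_vector(2L, c(5L, 0L, 0L))[2L])
  p_hat <- mean(picks)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("abundances are Dirichlet with the conjugate update", {
  set.seed(2)
  draws <- replicate(1e4, sample_abundances(c(1L, 1L), c(2L, 0L), 1)[1L])
  # Dirichlet(3, 1): mean 3/4, var 3/80
  se <- sqrt(3 / 80 / 1e4)
  expect_lt(abs(mean(draws) - 0.75), 3 * se)
  e <- sample_abundances(c(1L, 0L, 1L), c(3L, 0L, 0L), 0.5)
  expect_equal(sum(e), 1)
  expect_identical(e[2L], 0)
  # b_z = 1: a degenerate one-point simplex
  expect_identical(sample_abundances(c(0L, 1L), c(0L, 4L), 1), c(0, 1))
})

test_that("assignment sampling follows likelihood x abundance", {
  L <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  a <- sample_assignments(c(1, 0), L)
  expect_identical(a$t, c(1L, 1L))
  expect_identical(a$c, c(2L, 0L))
  set.seed(3)
  t1 <- replicate(1e4, sample_assignments(c(0.5, 0.5),
                                          L[1L, , drop = FALSE])$t)
  expect_lt(abs(mean(t1 == 1L) - 0.9), 3 * sqrt(0.09 / 1e4))
  t2 <- replicate(1e4, sample_assignments(c(0.8, 0.2),
                                          L[2L, , drop = FALSE])$t)
  expect_lt(abs(mean(t2 == 1L) - 0.8), 3 * sqrt(0.16 / 1e4))
})

test_that("the Gibbs schedule is the affine rule", {
  s <- gibbs_schedule(100L)
  expect_identical(s$burn_in, 7000L)
  expect_identical(s$samples, 70000L)
  expect_identical(gibbs_schedule(1L)$burn_in, 1060L)
})

test_that("single-candidate inference is exact", {
  L <- matrix(runif(5, 0.1, 1), 5L, 1L)
  set.seed(4)
  g <- run_gibbs(L, sparsity_prior(0.5, 1L))
  expect_equal(g$expressed_count / g$retained, 1)
  expect_equal(g$sum_e / g$retained, 1)
  expect_equal(g$sum_c / g$retained, 5)
})

test_that("pi = 1 reduces to Dirichlet-multinomial quantification", {
  # each fragment compatible with exactly one candidate: c is fixed, so
  # E[e_j] = (c_j + gamma) / (n + m gamma)
  L <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1))
  set.seed(5)
  g <- run_gibbs(L, sparsity_prior(1, 2L), gamma = 1, keep_trace = TRUE)
  expect_true(all(g$trace_z))
  post_mean <- g$sum_e / g$retained
  expect_equal(post_mean, c(4, 2) / 6, tolerance = 0.02)
})

test_that("both engines satisfy state invariants at every iteration", {
  set.seed(6)
  L <- matrix(rexp(12 * 3), 12L, 3L) * (runif(36) < 0.7)
  L[rowSums(L) == 0, 1L] <- 1
  for (eng in c("cpp", "r")) {
    set.seed(7)
    g <- run_gibbs(L, sparsity_prior(0.5, 3L), gamma = 1,
                   schedule = list(burn_in = 50L, samples = 400L),
                   engine = eng, keep_trace = TRUE)
    expect_true(all(rowSums(g$trace_c) == 12L))              # sum c = n
    expect_equal(rowSums(g$trace_e), rep(1, 400L), tolerance = 1e-9)
    expect_true(all(g$trace_z[g$trace_c > 0L]))              # c>0 => z=1
    expect_true(all((g$trace_e > 0) == g$trace_z))           # e>0 <=> z=1
  }
})

test_that("runs are deterministic given the seed", {
  L <- matrix(runif(20), 10L, 2L) + 0.05
  for (eng in c("cpp", "r")) {
    set.seed(11)
    g1 <- run_gibbs(L, sparsity_prior(0.4, 2L), engine = eng,
                    schedule = list(burn_in = 100L, samples = 500L))
    set.seed(11)
    g2 <- run_gibbs(L, sparsity_prior(0.4, 2L), engine = eng,
                    schedule = list(burn_in = 100L, samples = 500L))
    expect_identical(g1$expressed_count, g2$expressed_count)
    expect_identical(g1$sum_e, g2$sum_e)
    expect_identical(g1$sum_c, g2$sum_c)
  }
})

test_that("exact posterior handles degenerate and symmetric cases", {
  # m = 1: the truncated prior forces expression
  p <- exact_posterior(matrix(1, 3L, 1L), 0.3, 1)
  expect_equal(p$p_expressed, 1)
  expect_equal(p$mean_e, 1)
  # identical likelihood columns: exchangeable marginals
  L <- matrix(rep(c(0.3, 0.7, 0.5), 2L), 3L, 2L)
  p2 <- exact_posterior(L, 0.5, 1)
  expect_equal(p2$p_expressed[1L], p2$p_expressed[2L], tolerance = 1e-12)
  expect_equal(p2$mean_e[1L], p2$mean_e[2L], tolerance = 1e-12)
  expect_equal(sum(p2$mean_e), 1, tolerance = 1e-12)
  # guard against oversized enumeration
  expect_error(exact_posterior(matrix(1, 30L, 5L), 0.5, 1), "too large")
})

test_that("Gibbs marginals track the exact posterior on a tiny instance", {
  L <- rbind(c(1.0, 0.2), c(0.1, 0.9), c(0.6, 0.5))
  prior <- sparsity_prior(0.5, 2L)
  ex <- exact_posterior(L, prior, 1)
  set.seed(21)
  g <- run_gibbs(L, prior, gamma = 1, keep_trace = TRUE)
  for (j in 1:2) {
    se <- max(batch_se(as.numeric(g$trace_z[, j])), 1e-4)
    expect_lt(abs(mean(g$trace_z[, j]) - ex$p_expressed[j]), 3 * se)
  }
})
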