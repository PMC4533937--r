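# exact analyses at n = 2 are audited against the dense brute-force
# oracle; model-level facts (MFPT invariance, absorption symmetry,
# attempt counts) are checked at n = 2..10

kernel_n2 <- function(alpha = 0.35, beta = 0.6, p = 0.07, q = 0.12) {
  build_kernel(kmt_params(n = 2, p = p, q = q, alpha = alpha, beta = beta))
}

test_that("propagation conserves probability and matches the dense oracle", {
  K <- kernel_n2()
  tr <- propagate(K, c(0, 0, 0, 0), 40)
  expect_equal(tr$distributions[1, state_index(K$space, 0, 0, 0, 0)], 1)
  expect_lt(max(abs(rowSums(tr$distributions) - 1)), 1e-10)
  expect_true(all(tr$distributions >= -1e-15))
  ok <- oracle_kernel(2, 0.07, 0.12, 0.35, 0.6, 1)
  v0 <- numeric(36); v0[1] <- 1
  expect_equal(tr$distributions, oracle_propagate(ok$K, v0, 40),
               tolerance = 1e-10)
  # T = 0 returns the initial law unchanged
  tr0 <- propagate(K, c(1, 0, 0, 1), 0)
  expect_equal(sum(tr0$distributions), 1)
  expect_equal(which(tr0$distributions[1, ] == 1),
               state_index(K$space, 1, 0, 0, 1))
})

test_that("mean first passage time matches the dense oracle at n = 2", {
  K <- kernel_n2()
  ok <- oracle_kernel(2, 0.07, 0.12, 0.35, 0.6, 1)
  fpt <- mean_first_passage_time(K, 5L)
  for (s in c(1L, 7L, 20L))
    expect_equal(fpt$mfpt[s], oracle_mfpt(ok, 5L, s), tolerance = 1e-10)
  # states already amphitelic have zero passage time
  expect_true(all(fpt$mfpt[K$space$class == 5L] == 0))
  expect_equal(mean_first_passage_time(K, 5L, c(1, 0, 0, 1)), 0)
})

test_that("MFPT to class 5 is independent of alpha and beta", {
  vals <- sapply(c(0, 0.5, 1), function(a)
    sapply(c(0, 0.5, 1), function(b)
      mean_first_passage_time(
        build_kernel(kmt_params(n = 4, p = 0.05, q = 0.05, alpha = a,
                                beta = b)),
        5L, c(0, 0, 0, 0))))
  expect_lt(diff(range(vals)) / mean(vals), 1e-9)
})

test_that("stationary law matches the eigen oracle and the balance equations", {
  K <- kernel_n2(alpha = 1, beta = 1)
  pi_st <- stationary_distribution(K)
  expect_true(pi_st$is_unique)
  expect_equal(sum(pi_st$probabilities), 1)
  expect_lt(pi_st$residual, 1e-10)
  ok <- oracle_kernel(2, 0.07, 0.12, 1, 1, 1)
  expect_equal(pi_st$probabilities, oracle_stationary(ok$K),
               tolerance = 1e-10)
})

test_that("stationary law is refused in the multi-recurrent beta = 0 regime", {
  K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05, beta = 0))
  expect_error(stationary_distribution(K), "absorption_statistics")
})

test_that("long-run propagation converges to the stationary law", {
  K <- kernel_n2(alpha = 1, beta = 1)
  pi_st <- stationary_distribution(K)$probabilities
  tr <- propagate(K, c(0, 0, 0, 0), 600)
  tv <- function(v) 0.5 * sum(abs(v - pi_st))
  tv_mid <- tv(tr$distributions[301, ])
  tv_end <- tv(tr$distributions[601, ])
  expect_lt(tv_end, 1e-6)
  expect_lt(tv_end, tv_mid + 1e-12)
})

test_that("stationary law at alpha = beta = gamma = 1 depends only on p/q", {
  K1 <- build_kernel(kmt_params(n = 3, p = 0.2, q = 0.1, alpha = 1,
                                beta = 1))
  K2 <- build_kernel(kmt_params(n = 3, p = 0.1, q = 0.05, alpha = 1,
                                beta = 1))
  expect_equal(stationary_distribution(K1)$probabilities,
               stationary_distribution(K2)$probabilities,
               tolerance = 1e-10)
})

test_that("beta = 0 absorption hits the two full amphitelic states equally", {
  K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05, alpha = 0.8,
                               beta = 0))
  ab <- absorption_statistics(K, c(0, 0, 0, 0))
  expect_setequal(ab$absorbing,
                  state_index(K$space, c(2, 0), c(0, 2), c(0, 2), c(2, 0)))
  expect_equal(sum(ab$absorption_prob), 1, tolerance = 1e-10)
  expect_equal(unname(ab$absorption_prob[1]), 0.5, tolerance = 1e-10)
  # starting inside an absorbing state is a fixed point
  ab2 <- absorption_statistics(K, c(2, 0, 0, 2))
  expect_equal(unname(ab2$absorption_prob[["(2,0,0,2)"]]), 1)
})

test_that("expected visits reproduce the fundamental matrix at n = 2", {
  K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05, alpha = 0.8,
                               beta = 0))
  ab <- absorption_statistics(K, c(0, 0, 0, 0))
  trans <- setdiff(seq_len(K$space$S), ab$absorbing)
  Nmat <- solve(diag(length(trans)) - as.matrix(K$matrix[trans, trans]))
  expect_equal(ab$expected_visits[trans],
               Nmat[match(ab$start, trans), ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("bi-orientation attempts: exactly one when class 5 cannot be exited", {
  for (n in c(2L, 10L)) {
    K <- build_kernel(kmt_params(n = n, p = 0.05, q = 1 / (2 * n) / 2,
                                 alpha = 0, beta = 0))
    expect_equal(biorientation_attempts(K), 1, tolerance = 1e-10)
  }
  Kb <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05, beta = 0.5))
  expect_error(biorientation_attempts(Kb), "beta")
})

test_that("attempts grow with alpha and shrink as q is reduced", {
  att <- sapply(c(0.1, 0.3, 0.5), function(q_over) {
    sapply(c(0.2, 0.5, 1), function(a)
      biorientation_attempts(build_kernel(
        kmt_params(n = 4, p = 0.05, q = q_over / 4, alpha = a, beta = 0))))
  })
  # rows: alpha increasing; cols: q increasing
  for (cc in 1:3) expect_true(all(diff(att[, cc]) > 0))
  for (rr in 1:3) expect_true(all(diff(att[rr, ]) > 0))
})
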