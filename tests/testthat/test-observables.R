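test_that("class curves partition probability and show the known transients", {
  # ideal meiosis I: merotelic peaks transiently, then amphitelic takes over
  K <- build_kernel(kmt_params(n = 10, p = 0.05, q = 0.05, alpha = 0,
                               beta = 0))
  curve <- class_probabilities(propagate(K, c(0, 0, 0, 0), 400))
  expect_equal(curve[1, -1], data.frame(class1 = 1, class2 = 0, class3 = 0,
                                        class4 = 0, class5 = 0),
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(curve[, -1]) - 1)), 1e-10)
  peak4 <- which.max(curve$class4)
  expect_gt(curve$class4[peak4], tail(curve$class4, 1))
  expect_true(peak4 > 1 && peak4 < nrow(curve))
  expect_gt(tail(curve$class5, 1), 0.9)
  # class-5 probability is nondecreasing beyond the transient
  late <- curve$class5[100:401]
  expect_true(all(diff(late) > -1e-12))

  # ideal mitosis: monotelic dominates before amphitelic
  Km <- build_kernel(kmt_params(n = 10, p = 0.05, q = 0.05, beta = 0,
                                gamma = 0.1, mode = "mitosis"))
  cm <- class_probabilities(propagate(Km, c(0, 0, 0, 0), 400))
  peak2 <- which.max(cm$class2)
  expect_gt(cm$class2[peak2], 0.5)
  expect_lt(peak2, which(cm$class5 > 0.5)[1])
})

test_that("kMT densities decompose by class and stay consistent", {
  K <- build_kernel(kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0,
                               beta = 0.5))
  tr <- propagate(K, c(0, 0, 0, 0), 60)
  v <- tr$distributions[61, ]
  d_all <- kmt_density(v, K$space)
  d5 <- kmt_density(v, K$space, classes = 5)
  d_rest <- kmt_density(v, K$space, classes = 1:4)
  expect_equal(d_all$total_mass, 1, tolerance = 1e-10)
  expect_equal(d5$density + d_rest$density, d_all$density,
               tolerance = 1e-12)
  expect_equal(d5$total_mass + d_rest$total_mass, 1, tolerance = 1e-10)
  # kinetochore-symmetric start gives a transpose-symmetric table
  expect_equal(d_all$density, t(d_all$density), tolerance = 1e-12)
  dn <- kmt_density(v, K$space, classes = 5, normalize = TRUE)
  expect_equal(sum(dn$density), 1, tolerance = 1e-10)
  expect_error(kmt_density(v, K$space, classes = integer(0)), "subset")
})

test_that("amphitelic mass concentrates at capacity when beta = 0", {
  K <- build_kernel(kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0,
                               beta = 0))
  tr <- propagate(K, c(0, 0, 0, 0), 2000)
  d5 <- kmt_density(tr$distributions[2001, ], K$space, classes = 5,
                    normalize = TRUE)
  expect_gt(d5$density["4", "4"], 0.99)
})

test_that("conditional occupancy moments behave and match degenerate cases", {
  sp <- enumerate_states(4)
  v <- numeric(sp$S); v[state_index(sp, 3, 0, 0, 3)] <- 1
  mm <- mean_kmt(v, sp, classes = 5)
  expect_equal(mm$mean, 3)
  expect_equal(mm$sd, 0)
  expect_error(mean_kmt(v, sp, classes = 3), "zero probability")
  K <- build_kernel(kmt_params(n = 4, p = 0.1, q = 0.1, alpha = 1,
                               beta = 1))
  pi_st <- stationary_distribution(K)$probabilities
  expect_equal(mean_kmt(pi_st, K$space)$mean,
               steady_state_mean_kmt(4, 0.1, 0.1), tolerance = 1e-10)
})

test_that("synchrony is the k-th power of the single-pair curve", {
  theta <- c(0, 0.2, 0.6, 0.9, 1)
  sc3 <- synchrony_curve(theta, 3)
  expect_equal(sc3$synchrony, theta^3)
  expect_equal(synchrony_curve(theta, 1)$synchrony, theta)
  # independence: synchrony over k1 + k2 pairs factorises
  sc2 <- synchrony_curve(theta, 2)
  sc5 <- synchrony_curve(theta, 5)
  expect_equal(sc5$synchrony, sc2$synchrony * sc3$synchrony,
               tolerance = 1e-12)
  # nonincreasing in k; threshold crossing time delays with k
  K <- build_kernel(kmt_params(n = 10, p = 0.05, q = 0.05, alpha = 0,
                               beta = 0))
  th <- class_probabilities(propagate(K, c(0, 0, 0, 0), 300))$class5
  cross <- sapply(c(1, 5, 20), function(k)
    which(synchrony_curve(th, k)$synchrony >= 0.5)[1])
  expect_true(all(diff(cross) > 0))
  expect_true(all(synchrony_curve(th, 5)$synchrony <=
                    synchrony_curve(th, 1)$synchrony + 1e-15))
  expect_error(synchrony_curve(th, 0), "k")
})

test_that("steady-state synchrony: 1 in the absorbing regime, monotone in alpha and beta", {
  expect_equal(steady_state_synchrony(
    kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0.7, beta = 0), 7), 1)
  base <- list(n = 4, p = 0.05, q = 0.1)
  val <- function(a, b) steady_state_synchrony(
    kmt_params(n = base$n, p = base$p, q = base$q, alpha = a, beta = b), 5)
  expect_gt(val(0.2, 0.5), val(0.8, 0.5))
  expect_gt(val(0.5, 0.2), val(0.5, 0.8))
  # k-th power of the stationary class-5 probability
  K <- build_kernel(kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 1,
                               beta = 1))
  th <- sum(stationary_distribution(K)$probabilities[K$space$class == 5])
  expect_equal(val(1, 1), th^5, tolerance = 1e-10)
})

test_that("synchrony half-life: infinite without exits, scales as 1/k, steep near 0", {
  expect_identical(synchrony_half_life(
    kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0, beta = 0), 3), Inf)
  pars <- kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0.3, beta = 0.3)
  h1 <- synchrony_half_life(pars, 1)
  h2 <- synchrony_half_life(pars, 2)
  h4 <- synchrony_half_life(pars, 4)
  # in the geometric-decay regime the joint half-life scales like 1/k
  expect_equal(h2 / h1, 0.5, tolerance = 0.1)
  expect_equal(h4 / h2, 0.5, tolerance = 0.1)
  hsmall <- synchrony_half_life(
    kmt_params(n = 4, p = 0.05, q = 0.1, alpha = 0.05, beta = 0.05), 1)
  expect_gt(hsmall, 3 * h1)
})
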