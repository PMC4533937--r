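# Derived observables: per-class probability curves, 2D kMT-number
# densities, per-kinetochore occupancy moments, and multi-chromosome
# synchrony (all k chromosome pairs simultaneously amphitelic).

#' Per-class probability curve of a trajectory
#'
#' Aggregates the per-state law at each time into the five attachment
#' classes.
#'
#' @param trajectory A `"kmt_trajectory"` from [propagate()] or
#'   [empirical_class_curve()] input run.
#' @return A data frame with columns `t`, `class1` ... `class5`; each row
#'   sums to 1.
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05))
#' head(class_probabilities(propagate(K, steps = 5)))
#' @export
class_probabilities <- function(trajectory) {
  stopifnot(inherits(trajectory, "kmt_trajectory"))
  cls <- trajectory$space$class
  agg <- sapply(1:5, function(cc)
    rowSums(trajectory$distributions[, cls == cc, drop = FALSE]))
  agg <- matrix(agg, ncol = 5L)
  out <- data.frame(t = trajectory$times, agg)
  names(out) <- c("t", paste0("class", 1:5))
  out
}

#' 2D density of kMT numbers, decomposed by attachment class
#'
#' Accumulates the probability mass of each state at the cell
#' `(i1 + j1, i2 + j2)` of an `(n + 1) x (n + 1)` table, restricted to a
#' subset of classes. By default the table is left unnormalised, so its
#' total equals the probability of the class subset and the class-5 table
#' plus the class-1..4 table reproduces the full density cellwise; set
#' `normalize = TRUE` to rescale the table to total mass 1.
#'
#' @param distribution Probability vector over the state space (e.g. one
#'   row of a trajectory, or `probabilities` of a stationary law).
#' @param space The matching `"kmt_space"`.
#' @param classes Subset of `1:5` (default all five).
#' @param normalize Rescale the table to sum to 1? Default `FALSE`.
#' @return A `"kmt_density"` object: list with `density` (matrix with
#'   dimnames `0:n` by `0:n`, rows = kinetochore-1 total), `total_mass`,
#'   `classes`, `normalized`.
#' @export
kmt_density <- function(distribution, space, classes = 1:5,
                        normalize = FALSE) {
  stopifnot(inherits(space, "kmt_space"))
  classes <- as.integer(classes)
  if (length(classes) == 0L || !all(classes %in% 1:5))
    stop("'classes' must be a non-empty subset of 1:5", call. = FALSE)
  if (length(distribution) != space$S)
    stop("'distribution' length does not match the state space", call. = FALSE)
  n <- space$n
  st <- space$states
  keep <- space$class %in% classes
  m1 <- st$i1[keep] + st$j1[keep]
  m2 <- st$i2[keep] + st$j2[keep]
  w <- distribution[keep]
  dens <- matrix(0, n + 1L, n + 1L, dimnames = list(0:n, 0:n))
  for (kk in seq_along(w))
    dens[m1[kk] + 1L, m2[kk] + 1L] <- dens[m1[kk] + 1L, m2[kk] + 1L] + w[kk]
  total <- sum(w)
  if (normalize) {
    if (total <= 0)
      stop("cannot normalise: zero mass in the selected classes", call. = FALSE)
    dens <- dens / total
  }
  structure(list(density = dens, total_mass = total, classes = classes,
                 normalized = normalize),
            class = "kmt_density")
}

#' Conditional mean and standard deviation of kMT number per kinetochore
#'
#' Moments of the per-kinetochore kMT count `i + j`, conditioned on the
#' state belonging to a subset of classes. By kinetochore-exchange
#' symmetry the two kinetochores have the same conditional law whenever
#' the distribution is exchange-symmetric; both are computed and checked
#' to agree before the common value is returned.
#'
#' @inheritParams kmt_density
#' @param tol Maximal tolerated discrepancy between the two kinetochores'
#'   moments (default `1e-8`).
#' @return List with `mean` and `sd` (per kinetochore), and `mass` (the
#'   conditioning probability).
#' @export
mean_kmt <- function(distribution, space, classes = 1:5, tol = 1e-8) {
  stopifnot(inherits(space, "kmt_space"))
  classes <- as.integer(classes)
  if (length(classes) == 0L || !all(classes %in% 1:5))
    stop("'classes' must be a non-empty subset of 1:5", call. = FALSE)
  keep <- space$class %in% classes
  w <- distribution[keep]
  mass <- sum(w)
  if (mass <= 0)
    stop("zero probability mass in the selected classes", call. = FALSE)
  st <- space$states
  mom <- function(m) {
    mu <- sum(w * m) / mass
    v <- sum(w * (m - mu)^2) / mass
    c(mu, sqrt(max(v, 0)))
  }
  m1 <- mom(st$i1[keep] + st$j1[keep])
  m2 <- mom(st$i2[keep] + st$j2[keep])
  if (max(abs(m1 - m2)) > tol)
    stop("kinetochore-exchange asymmetry exceeds tolerance; supply a symmetric distribution",
         call. = FALSE)
  list(mean = m1[1], sd = m1[2], mass = mass)
}

#' Synchrony curve for k independent chromosome pairs
#'
#' The cell achieves synchrony at time `t` when all `k` chromosome pairs
#' are simultaneously amphitelic. With pairs evolving as independent
#' copies of the chain, the synchrony probability is `theta_t^k`, where
#' `theta_t` is the single-pair class-5 probability.
#'
#' @param theta Numeric vector of per-time class-5 probabilities (in
#'   `[0, 1]`).
#' @param k Number of chromosome pairs (`>= 1`).
#' @param times Optional time axis (default `0:(length(theta) - 1)`).
#' @return A data frame with columns `t`, `theta`, `synchrony`.
#' @examples
#' synchrony_curve(c(0, 0.5, 0.9, 1), k = 3)
#' @export
synchrony_curve <- function(theta, k, times = NULL) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  if (any(theta < -1e-12 | theta > 1 + 1e-12))
    stop("'theta' values must lie in [0, 1]", call. = FALSE)
  theta <- pmin(pmax(theta, 0), 1)
  if (is.null(times)) times <- seq_along(theta) - 1L
  stopifnot(length(times) == length(theta))
  data.frame(t = times, theta = theta, synchrony = theta^k)
}

#' Steady-state probability of synchrony
#'
#' The long-run probability that all `k` chromosome pairs are
#' simultaneously amphitelic. In the ergodic regime (`beta > 0`) this is
#' the stationary class-5 probability raised to the `k`-th power. With
#' `beta = 0` the chain is absorbed in fully occupied amphitelic states,
#' so the limit is 1 for any `alpha` and `k`.
#'
#' @param params A [kmt_params()] object.
#' @param k Number of chromosome pairs.
#' @return A single probability.
#' @export
steady_state_synchrony <- function(params, k) {
  params <- as_kmt_params(params)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  if (params$beta == 0) return(1)
  kern <- build_kernel(params)
  pi_st <- stationary_distribution(kern)
  theta <- sum(pi_st$probabilities[kern$space$class == 5L])
  theta^k
}

#' Half-life of synchrony at steady state
#'
#' Dwell-time definition: start each of the `k` independent pairs from
#' the stationary distribution conditioned on the amphitelic class, and
#' ask for the smallest duration `s` (linearly interpolated between
#' integer steps) at which the probability that all `k` pairs have
#' remained continuously amphitelic for `s` consecutive steps falls to
#' 1/2. Per-pair persistence is the survival function of the
#' substochastic restriction of the kernel to class-5 states. With
#' `alpha = beta = 0` class 5 is never exited and the half-life is
#' infinite.
#'
#' @param params A [kmt_params()] object.
#' @param k Number of chromosome pairs.
#' @param max_steps Iteration cap on the survival recursion (default
#'   `1e5`); exceeding it returns `Inf` with a warning.
#' @return Half-life in steps (possibly `Inf`).
#' @export
synchrony_half_life <- function(params, k, max_steps = 1e5) {
  params <- as_kmt_params(params)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  if (params$alpha == 0 && params$beta == 0) return(Inf)
  kern <- build_kernel(params)
  cls <- kern$space$class
  idx5 <- which(cls == 5L)
  if (params$beta > 0) {
    pi_st <- stationary_distribution(kern)$probabilities
  } else {
    # beta = 0: the t -> Inf law concentrates on the absorbing amphitelic
    # states; condition on those
    pi_st <- numeric(kern$space$S)
    pi_st[absorbing_states(kern)] <- 1
  }
  mass5 <- sum(pi_st[idx5])
  if (mass5 <= 0)
    stop("zero stationary probability of the amphitelic class", call. = FALSE)
  v <- pi_st[idx5] / mass5
  K5 <- kern$matrix[idx5, idx5, drop = FALSE]
  target <- 0.5^(1 / k)     # per-pair survival at the joint half-life
  surv_prev <- 1
  for (s in seq_len(max_steps)) {
    v <- as.numeric(v %*% K5)
    surv <- sum(v)
    if (surv <= target) {
      # linear interpolation of the joint survival between s - 1 and s
      j_prev <- surv_prev^k
      j_cur <- surv^k
      return((s - 1) + (j_prev - 0.5) / (j_prev - j_cur))
    }
    surv_prev <- surv
  }
  warning("synchrony survival did not fall to 1/2 within 'max_steps'; returning Inf")
  Inf
}
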