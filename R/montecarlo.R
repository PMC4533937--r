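# Seeded Monte Carlo simulator. Event probabilities are recomputed on the
# fly from the elementary attachment/detachment rules and the class
# scaling factors -- never read from the assembled transition matrix -- so
# simulation is an implementation-independent cross-check of the exact
# linear-algebra analyses.

# scaled probabilities of the 8 elementary events for a matrix of states;
# column order: attach L-k1, R-k1, L-k2, R-k2, detach L-k1, R-k1, L-k2, R-k2
step_event_probs <- function(counts, params) {
  n <- params$n
  R <- nrow(counts)
  cls <- classify_state(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  occ1 <- counts[, 1] + counts[, 2]
  occ2 <- counts[, 3] + counts[, 4]
  pr <- matrix(0, R, 8L)
  for (e in 1:8) {
    slot <- if (e <= 4L) e else e - 4L
    occ <- if (slot <= 2L) occ1 else occ2
    if (e <= 4L) {
      base <- (n - occ) / n * params$p
      tgt <- counts
      tgt[, slot] <- tgt[, slot] + 1L
      feas <- occ < n
      tcls <- rep(NA_integer_, R)
      tcls[feas] <- classify_state(tgt[feas, 1], tgt[feas, 2],
                                   tgt[feas, 3], tgt[feas, 4])
      sc <- rep(1, R)
      sc[feas & cls == 5L & tcls == 4L] <- params$alpha
      sc[feas & cls == 2L & (tcls == 3L | tcls == 4L)] <- params$gamma
      pr[, e] <- ifelse(feas, base * sc, 0)
    } else {
      base <- counts[, slot] * params$q
      sc <- ifelse(cls == 5L, params$beta, 1)
      pr[, e] <- base * sc
    }
  }
  pr
}

# one vectorised chain step for all replicates, given one uniform per
# replicate: partition [0, 1) over the ordered event list, self-loop last
advance_states <- function(counts, u, params) {
  pr <- step_event_probs(counts, params)
  cum <- pr
  for (e in 2:8) cum[, e] <- cum[, e - 1L] + pr[, e]
  choice <- rowSums(u > cum) + 1L   # 9 = self-loop
  act <- choice <= 8L
  if (any(act)) {
    slot <- ifelse(choice[act] <= 4L, choice[act], choice[act] - 4L)
    delta <- ifelse(choice[act] <= 4L, 1L, -1L)
    idx <- cbind(which(act), slot)
    counts[idx] <- counts[idx] + delta
  }
  counts
}

#' Simulate attachment trajectories
#'
#' Runs `n_replicates` independent sample paths of the chain for a fixed
#' number of steps. Each step draws a single uniform per replicate and
#' partitions it over the ordered event list (attach left/right on
#' kinetochore 1, attach left/right on kinetochore 2, the four
#' detachments in the same order, then the self-loop), so paths are
#' bit-reproducible. Replicate `r` consumes uniforms from its own stream,
#' seeded with `seed + r`, making every replicate individually
#' reproducible regardless of how many replicates are run together.
#'
#' @param params A [kmt_params()] object.
#' @param init Initial state tuple (default empty).
#' @param horizon Number of steps (`>= 0`).
#' @param n_replicates Number of independent paths (`>= 1`).
#' @param seed Integer base seed (mandatory; no silent nondeterminism).
#' @return A `"kmt_simulation"` object: list with `paths` (integer array
#'   `n_replicates x (horizon + 1) x 4`), `params`, `horizon`,
#'   `n_replicates`, `seed`.
#' @examples
#' run <- simulate_paths(kmt_params(n = 2, p = 0.05, q = 0.05),
#'                       horizon = 20, n_replicates = 5, seed = 1)
#' dim(run$paths)
#' @export
simulate_paths <- function(params, init = c(0, 0, 0, 0), horizon,
                           n_replicates, seed) {
  params <- as_kmt_params(params)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' is mandatory and must be a single integer", call. = FALSE)
  seed <- as.integer(seed)
  stopifnot(horizon >= 0, horizon == round(horizon),
            n_replicates >= 1, n_replicates == round(n_replicates))
  horizon <- as.integer(horizon); R <- as.integer(n_replicates)
  init <- as.integer(init)
  stopifnot(length(init) == 4L, all(init >= 0),
            init[1] + init[2] <= params$n, init[3] + init[4] <= params$n)
  # per-replicate uniform streams
  U <- matrix(0, nrow = max(horizon, 1L), ncol = R)
  if (horizon > 0) {
    for (r in seq_len(R)) {
      set.seed(seed + r)
      U[, r] <- stats::runif(horizon)
    }
  }
  paths <- array(0L, dim = c(R, horizon + 1L, 4L))
  counts <- matrix(rep(init, each = R), nrow = R)
  paths[, 1L, ] <- counts
  if (horizon > 0) {
    for (t in seq_len(horizon)) {
      counts <- advance_states(counts, U[t, ], params)
      paths[, t + 1L, ] <- counts
    }
  }
  structure(list(paths = paths, params = params, horizon = horizon,
                 n_replicates = R, seed = seed, init = init),
            class = "kmt_simulation")
}

#' @export
print.kmt_simulation <- function(x, ...) {
  cat(sprintf(
    "kMT simulation: %d replicates, horizon %d, seed %d (%s, n = %d)\n",
    x$n_replicates, x$horizon, x$seed, x$params$mode, x$params$n))
  invisible(x)
}

#' Empirical class-probability curve of a simulation run
#'
#' Per-time empirical frequencies of the five attachment classes across
#' replicates, with binomial standard errors.
#'
#' @param run A `"kmt_simulation"` from [simulate_paths()].
#' @return A data frame with columns `t`, `class1` ... `class5`,
#'   `se_class1` ... `se_class5`; class frequencies sum to 1 per row.
#' @export
empirical_class_curve <- function(run) {
  stopifnot(inherits(run, "kmt_simulation"))
  R <- run$n_replicates
  TT <- run$horizon + 1L
  freq <- matrix(0, TT, 5L)
  for (t in seq_len(TT)) {
    cls <- classify_state(run$paths[, t, 1], run$paths[, t, 2],
                          run$paths[, t, 3], run$paths[, t, 4])
    freq[t, ] <- tabulate(cls, nbins = 5L) / R
  }
  se <- sqrt(freq * (1 - freq) / R)
  out <- data.frame(t = 0:run$horizon, freq, se)
  names(out) <- c("t", paste0("class", 1:5), paste0("se_class", 1:5))
  out
}

#' Empirical mean first passage time to a class, by simulation
#'
#' Simulates replicates with the target class made absorbing (paths stop
#' advancing once the class is hit) and averages the hitting times.
#' Uniform draws come from a single stream seeded with `seed` (one draw
#' per active replicate per step).
#'
#' @param params A [kmt_params()] object.
#' @param init Initial state tuple (default empty).
#' @param target_class Class code in `1:5` (default 5).
#' @param n_replicates Number of paths.
#' @param seed Integer seed.
#' @param max_steps Cap on path length; replicates not absorbed by then
#'   raise an error (increase `max_steps`).
#' @return List with `mean` (empirical MFPT), `se` (standard error),
#'   `hit_times` (per-replicate hitting times).
#' @export
empirical_mfpt <- function(params, init = c(0, 0, 0, 0), target_class = 5L,
                           n_replicates, seed, max_steps = 100000L) {
  params <- as_kmt_params(params)
  target_class <- as.integer(target_class)
  stopifnot(target_class %in% 1:5)
  R <- as.integer(n_replicates)
  set.seed(as.integer(seed))
  counts <- matrix(rep(as.integer(init), each = R), nrow = R)
  hit <- rep(NA_integer_, R)
  cls0 <- classify_state(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  hit[cls0 == target_class] <- 0L
  active <- is.na(hit)
  t <- 0L
  while (any(active) && t < max_steps) {
    t <- t + 1L
    u <- stats::runif(sum(active))
    counts[active, ] <- advance_states(counts[active, , drop = FALSE], u,
                                       params)
    cls <- classify_state(counts[active, 1], counts[active, 2],
                          counts[active, 3], counts[active, 4])
    newly <- which(active)[cls == target_class]
    hit[newly] <- t
    active[newly] <- FALSE
  }
  if (any(active))
    stop(sprintf("%d replicate(s) did not reach class %d within max_steps = %d",
                 sum(active), target_class, max_steps), call. = FALSE)
  list(mean = mean(hit), se = stats::sd(hit) / sqrt(R), hit_times = hit)
}
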