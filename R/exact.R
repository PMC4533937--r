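# Exact linear-algebra analyses of the attachment chain: transient
# propagation by repeated vector-kernel products, first-passage times and
# absorption statistics through the fundamental matrix of the transient
# block, and stationary distributions via a sparse balance-equation solve.

# sparse LU solve with AMD fill-reducing ordering on A + A'; the natural
# lexicographic state order produces heavy fill-in, AMD is ~10x faster here
sparse_solve <- function(A, b) {
  as.numeric(Matrix::solve(
    Matrix::lu(methods::as(A, "CsparseMatrix"), order = 1L), b))
}

#' Propagate a distribution through the chain
#'
#' Computes the exact law of the chain at times `0, 1, ..., steps` by
#' repeated sparse vector-matrix products `v <- v %*% K` (never by dense
#' matrix powers).
#'
#' @param kernel A `"kmt_kernel"` from [build_kernel()].
#' @param init Initial condition: a length-4 state tuple, a single state
#'   index, or a full probability vector over the state space. Defaults to
#'   a point mass on the empty state `(0, 0, 0, 0)`.
#' @param steps Number of time steps `T >= 0`.
#' @return An object of class `"kmt_trajectory"`: list with `times`
#'   (`0:steps`), `distributions` (a `(steps + 1) x S` matrix, row `t + 1`
#'   = law at time `t`), and `space`.
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05))
#' tr <- propagate(K, steps = 10)
#' rowSums(tr$distributions)   # all 1
#' @export
propagate <- function(kernel, init = c(0, 0, 0, 0), steps) {
  kernel <- as_kmt_kernel(kernel)
  S <- kernel$space$S
  if (length(steps) != 1L || !is.finite(steps) || steps < 0 ||
      steps != round(steps))
    stop("'steps' must be a single non-negative integer", call. = FALSE)
  v <- as_distribution(kernel$space, init)
  out <- matrix(0, nrow = steps + 1L, ncol = S)
  out[1L, ] <- v
  if (steps > 0) {
    m <- kernel$matrix
    for (t in seq_len(steps)) {
      v <- as.numeric(v %*% m)
      out[t + 1L, ] <- v
    }
  }
  structure(list(times = 0:steps, distributions = out,
                 space = kernel$space),
            class = "kmt_trajectory")
}

# accept a tuple, an index, or a full probability vector
# (S >= 36 for n >= 2, so a length-4 tuple is never ambiguous)
as_distribution <- function(space, init) {
  S <- space$S
  if (is.numeric(init) && length(init) == S) {
    if (any(init < 0) || abs(sum(init) - 1) > 1e-9)
      stop("'init' probability vector must be non-negative and sum to 1",
           call. = FALSE)
    return(as.numeric(init) / sum(init))
  }
  idx <- resolve_state(space, init)
  v <- numeric(S)
  v[idx] <- 1
  v
}

#' Mean first passage time to an attachment class
#'
#' Makes every state of the target class absorbing and solves the
#' fundamental-matrix system `(I - Q) t = 1` on the transient block by a
#' sparse LU factorisation. States already in the target class have mean
#' first passage time 0.
#'
#' @param kernel A `"kmt_kernel"`.
#' @param target_class Integer class code in `1:5` (default 5,
#'   amphitelic).
#' @param start Optional start state (tuple or index). If supplied, the
#'   scalar expected hitting time from that state is returned; otherwise
#'   an object with the full per-state vector.
#' @return If `start` is given, a single number (expected steps).
#'   Otherwise a `"kmt_fpt"` object: list with `mfpt` (length-S vector),
#'   `target_class`, `space`.
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05))
#' mean_first_passage_time(K, 5, start = c(0, 0, 0, 0))
#' @export
mean_first_passage_time <- function(kernel, target_class = 5L,
                                    start = NULL) {
  kernel <- as_kmt_kernel(kernel)
  target_class <- as.integer(target_class)
  stopifnot(length(target_class) == 1L, target_class %in% 1:5)
  cls <- kernel$space$class
  S <- kernel$space$S
  tgt <- cls == target_class
  mfpt <- numeric(S)
  if (any(!tgt)) {
    trans <- which(!tgt)
    Q <- kernel$matrix[trans, trans, drop = FALSE]
    A <- Matrix::Diagonal(length(trans)) - Q
    t_trans <- tryCatch(
      sparse_solve(A, rep(1, length(trans))),
      error = function(e)
        stop(sprintf(
          "first-passage system is singular: class %d is not reachable from every state",
          target_class), call. = FALSE))
    if (any(!is.finite(t_trans)) || any(t_trans < -1e-9))
      stop(sprintf("class %d is not reachable from every transient state",
                   target_class), call. = FALSE)
    mfpt[trans] <- t_trans
  }
  if (!is.null(start)) {
    idx <- resolve_state(kernel$space, start)
    return(mfpt[idx])
  }
  structure(list(mfpt = mfpt, target_class = target_class,
                 space = kernel$space),
            class = "kmt_fpt")
}

#' Stationary distribution of the chain
#'
#' Solves the balance equations `pi K = pi` with the normalisation
#' `sum(pi) = 1`, replacing one balance equation by the normalisation row
#' in a sparse linear solve. Requires an ergodic regime: `p > 0`, `q > 0`
#' and `beta > 0`. With `beta = 0` the chain has multiple closed
#' (absorbing) classes and no unique stationary law; use
#' [absorption_statistics()] instead.
#'
#' Entries that come out negative within `1e-12` of zero (solver round-off)
#' are clipped to 0 and the vector renormalised.
#'
#' @param kernel A `"kmt_kernel"`.
#' @return A `"kmt_stationary"` object: list with `probabilities`
#'   (length-S vector), `is_unique` (TRUE), `residual` (max norm of
#'   `pi K - pi`), `space`.
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05,
#'                              alpha = 1, beta = 1))
#' pi <- stationary_distribution(K)
#' sum(pi$probabilities)
#' @export
stationary_distribution <- function(kernel) {
  kernel <- as_kmt_kernel(kernel)
  pars <- kernel$params
  if (pars$beta == 0)
    stop(paste("beta = 0 creates multiple closed recurrent classes;",
               "the stationary law is not unique.",
               "Use absorption_statistics() for the absorbing regime."),
         call. = FALSE)
  if (pars$p == 0 || pars$q == 0)
    stop("stationary_distribution() requires p > 0 and q > 0 (ergodic regime)",
         call. = FALSE)
  S <- kernel$space$S
  # reference-state formulation: fix pi at the empty state (recurrent in
  # the ergodic regime) and solve the reduced balance equations, then
  # normalise; avoids the dense normalisation row that defeats the
  # fill-reducing ordering
  B <- Matrix::t(kernel$matrix) - Matrix::Diagonal(S)
  ref <- state_index(kernel$space, 0L, 0L, 0L, 0L)
  keep <- setdiff(seq_len(S), ref)
  x <- sparse_solve(B[keep, keep, drop = FALSE],
                    -as.numeric(B[keep, ref, drop = FALSE]))
  pi_vec <- numeric(S)
  pi_vec[ref] <- 1
  pi_vec[keep] <- x
  pi_vec <- pi_vec / sum(pi_vec)
  if (any(pi_vec < -1e-12))
    stop("stationary solve produced substantially negative probabilities",
         call. = FALSE)
  pi_vec[pi_vec < 0] <- 0
  pi_vec <- pi_vec / sum(pi_vec)
  resid <- max(abs(as.numeric(pi_vec %*% kernel$matrix) - pi_vec))
  structure(list(probabilities = pi_vec, is_unique = TRUE,
                 residual = resid, space = kernel$space),
            class = "kmt_stationary")
}

#' Absorption statistics of the chain started from a given state
#'
#' For parameter regimes with absorbing states (e.g. `beta = 0`, where the
#' fully occupied amphitelic states `(n,0,0,n)` and `(0,n,n,0)` absorb the
#' chain), computes the expected number of visits to every transient state
#' and the hitting probability of each absorbing state, via one sparse
#' solve against the transposed transient block.
#'
#' @param kernel A `"kmt_kernel"` with at least one absorbing state.
#' @param start Start state (tuple or index); default the empty state.
#' @return A list with
#'   \describe{
#'     \item{absorbing}{indices of the absorbing states,}
#'     \item{absorption_prob}{named hitting probabilities (sum to 1 when
#'       absorption is certain),}
#'     \item{expected_visits}{length-S vector of expected visit counts to
#'       each transient state before absorption (absorbing entries 0),}
#'     \item{start}{resolved start index.}
#'   }
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05,
#'                              alpha = 0, beta = 0))
#' ab <- absorption_statistics(K)
#' ab$absorption_prob   # 1/2 each by mirror symmetry
#' @export
absorption_statistics <- function(kernel, start = c(0, 0, 0, 0)) {
  kernel <- as_kmt_kernel(kernel)
  S <- kernel$space$S
  abs_idx <- absorbing_states(kernel)
  if (length(abs_idx) == 0L)
    stop("the chain has no absorbing state in this parameter regime",
         call. = FALSE)
  start_idx <- resolve_state(kernel$space, start)
  visits <- numeric(S)
  if (start_idx %in% abs_idx) {
    pr <- numeric(length(abs_idx))
    pr[match(start_idx, abs_idx)] <- 1
  } else {
    trans <- setdiff(seq_len(S), abs_idx)
    Q <- kernel$matrix[trans, trans, drop = FALSE]
    R <- kernel$matrix[trans, abs_idx, drop = FALSE]
    e <- numeric(length(trans))
    e[match(start_idx, trans)] <- 1
    # N[start, ] = e' (I - Q)^{-1}  <=>  (I - Q)' x = e
    x <- sparse_solve(Matrix::t(Matrix::Diagonal(length(trans)) - Q), e)
    visits[trans] <- x
    pr <- as.numeric(x %*% R)
    if (abs(sum(pr) - 1) > 1e-8)
      stop("absorption from the start state is not certain", call. = FALSE)
  }
  st <- kernel$space$states[abs_idx, 1:4, drop = FALSE]
  names(pr) <- apply(st, 1L, function(r)
    sprintf("(%d,%d,%d,%d)", r[1], r[2], r[3], r[4]))
  list(absorbing = abs_idx, absorption_prob = pr,
       expected_visits = visits, start = start_idx)
}

#' Expected number of bi-orientation attempts before absorption
#'
#' In the absorbing regime `beta = 0` the chain ends in a fully occupied
#' amphitelic state. This function counts the expected number of entries
#' into the amphitelic class (class 5) from a monotelic (class 2) or
#' merotelic (class 4) state before absorption -- the number of
#' bi-orientation attempts: `sum over transient u in {2,4}, v in class 5
#' of E[visits to u] * K[u, v]`.
#'
#' @param kernel A `"kmt_kernel"` built with `beta = 0`.
#' @param start Start state (tuple or index); default the empty state.
#' @return Expected attempt count (a single number; exactly 1 when
#'   `alpha = 0`, since class 5 is then never exited).
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05,
#'                              alpha = 1, beta = 0))
#' biorientation_attempts(K)
#' @export
biorientation_attempts <- function(kernel, start = c(0, 0, 0, 0)) {
  kernel <- as_kmt_kernel(kernel)
  if (kernel$params$beta != 0)
    stop("bi-orientation attempts are defined for the absorbing regime beta = 0",
         call. = FALSE)
  ab <- absorption_statistics(kernel, start)
  cls <- kernel$space$class
  from24 <- which(cls %in% c(2L, 4L) & ab$expected_visits > 0)
  if (length(from24) == 0L) return(0)
  into5 <- which(cls == 5L)
  M <- kernel$matrix[from24, into5, drop = FALSE]
  sum(ab$expected_visits[from24] * Matrix::rowSums(M))
}
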