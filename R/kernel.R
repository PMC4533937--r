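# The one-step transition kernel. Each step performs at most one
# elementary event: attachment or detachment of a single kMT at one
# kinetochore from one pole (8 possible events), with residual probability
# on the self-loop. The parameter bounds p <= 1/4, q <= 1/(2n) make the
# total exit probability of every state <= 1, so the diagonal is always
# non-negative.

#' Base probability of a single attachment or detachment event
#'
#' Returns the unscaled per-step probability of one elementary event from
#' a given state, before the class-dependent `alpha`/`beta`/`gamma`
#' scaling. Attachment to kinetochore `m` from either pole has probability
#' `((n - i_m - j_m)/n) * p` (proportional to the free kinetochore
#' surface); detachment of one kMT has probability `count * q`
#' (independent of occupancy). Infeasible events (attachment at full
#' capacity, detachment with count 0) have probability 0.
#'
#' @param state Length-4 count tuple `(i1, j1, i2, j2)`.
#' @param type `"attach"` or `"detach"`.
#' @param kinetochore 1 or 2.
#' @param pole `"left"` or `"right"`.
#' @param params A [kmt_params()] object.
#' @return A single probability.
#' @examples
#' pars <- kmt_params(n = 10, p = 0.05, q = 0.05)
#' event_probability(c(0, 0, 0, 0), "attach", 1, "left", pars)  # 0.05
#' event_probability(c(3, 1, 0, 0), "detach", 1, "left", pars)  # 0.15
#' @export
event_probability <- function(state, type = c("attach", "detach"),
                              kinetochore, pole = c("left", "right"),
                              params) {
  type <- match.arg(type)
  pole <- match.arg(pole)
  params <- as_kmt_params(params)
  stopifnot(length(state) == 4L, kinetochore %in% c(1, 2))
  state <- as.integer(state)
  n <- params$n
  if (any(state < 0L) || state[1] + state[2] > n || state[3] + state[4] > n)
    stop("invalid state for capacity n", call. = FALSE)
  occ <- if (kinetochore == 1) state[1] + state[2] else state[3] + state[4]
  slot <- 2L * (kinetochore - 1L) + if (pole == "left") 1L else 2L
  if (type == "attach") {
    if (occ >= n) return(0)
    (n - occ) / n * params$p
  } else {
    state[slot] * params$q
  }
}

#' Class-dependent scaling factor of a single transition
#'
#' For an adjacent pair of states (differing by exactly one attachment or
#' detachment event) returns the dimensionless factor applied on top of
#' the base event probability:
#'
#' * `alpha` if the origin is amphitelic (class 5) and the event is an
#'   attachment producing a merotelic state (class 4);
#' * `beta` if the origin is amphitelic and the event is a detachment
#'   (whether the target is still amphitelic or monotelic);
#' * `gamma` if the origin is monotelic (class 2) and the event is an
#'   attachment producing a syntelic (class 3) or merotelic (class 4)
#'   state;
#' * 1 otherwise.
#'
#' @param from,to Length-4 count tuples of adjacent states.
#' @param params A [kmt_params()] object.
#' @return A single factor in `[0, 1]`.
#' @examples
#' pars <- kmt_params(n = 10, p = 0.05, q = 0.05, alpha = 0.3, beta = 0.6)
#' scaling_factor(c(1, 0, 0, 1), c(1, 1, 0, 1), pars)  # alpha
#' scaling_factor(c(1, 0, 0, 1), c(0, 0, 0, 1), pars)  # beta
#' @export
scaling_factor <- function(from, to, params) {
  params <- as_kmt_params(params)
  stopifnot(length(from) == 4L, length(to) == 4L)
  from <- as.integer(from); to <- as.integer(to)
  d <- to - from
  nz <- which(d != 0L)
  if (length(nz) != 1L || abs(d[nz]) != 1L)
    stop("'from' and 'to' must differ by exactly one attachment or detachment event",
         call. = FALSE)
  type <- if (d[nz] == 1L) "attach" else "detach"
  cf <- classify_state(from[1], from[2], from[3], from[4])
  ct <- classify_state(to[1], to[2], to[3], to[4])
  if (cf == 5L && type == "attach" && ct == 4L) return(params$alpha)
  if (cf == 5L && type == "detach") return(params$beta)
  if (cf == 2L && type == "attach" && ct %in% c(3L, 4L)) return(params$gamma)
  1
}

#' Build the one-step transition kernel
#'
#' Assembles the sparse row-stochastic transition matrix over the state
#' space [enumerate_states()]. Off-diagonal entries are
#' `event_probability * scaling_factor` for each of the at most eight
#' feasible single events per state; the diagonal carries the residual
#' self-loop probability `1 - rowSums(off-diagonal)`, which the parameter
#' bounds keep non-negative.
#'
#' @param params A [kmt_params()] object.
#' @param space Optionally, a pre-built `"kmt_space"` for `params$n`
#'   (rebuilt if omitted).
#' @return An object of class `"kmt_kernel"`: list with `matrix` (a
#'   `dgCMatrix`, rows = origin states), `params`, and `space`.
#' @examples
#' K <- build_kernel(kmt_params(n = 2, p = 0.05, q = 0.05))
#' range(Matrix::rowSums(K$matrix))   # all 1
#' @export
build_kernel <- function(params, space = NULL) {
  params <- as_kmt_params(params)
  if (is.null(space)) space <- enumerate_states(params$n)
  stopifnot(inherits(space, "kmt_space"), space$n == params$n)
  n <- params$n
  st <- space$states
  S <- space$S
  cls <- space$class
  i1 <- st$i1; j1 <- st$j1; i2 <- st$i2; j2 <- st$j2
  occ1 <- i1 + j1; occ2 <- i2 + j2

  from_idx <- integer(0); to_idx <- integer(0); prob <- numeric(0)
  # events in documented order: attach L-k1, R-k1, L-k2, R-k2,
  #                             detach L-k1, R-k1, L-k2, R-k2
  events <- list(
    list(type = "attach", slot = 1L), list(type = "attach", slot = 2L),
    list(type = "attach", slot = 3L), list(type = "attach", slot = 4L),
    list(type = "detach", slot = 1L), list(type = "detach", slot = 2L),
    list(type = "detach", slot = 3L), list(type = "detach", slot = 4L))
  counts <- cbind(i1, j1, i2, j2)
  for (ev in events) {
    slot <- ev$slot
    kt_occ <- if (slot <= 2L) occ1 else occ2
    if (ev$type == "attach") {
      feas <- kt_occ < n
      base <- (n - kt_occ) / n * params$p
      delta <- +1L
    } else {
      feas <- counts[, slot] > 0L
      base <- counts[, slot] * params$q
      delta <- -1L
    }
    feas <- feas & base > 0
    if (!any(feas)) next
    tgt <- counts[feas, , drop = FALSE]
    tgt[, slot] <- tgt[, slot] + delta
    ti <- state_index(space, tgt[, 1], tgt[, 2], tgt[, 3], tgt[, 4])
    tcls <- cls[ti]
    fcls <- cls[feas]
    sc <- rep(1, length(ti))
    if (ev$type == "attach") {
      sc[fcls == 5L & tcls == 4L] <- params$alpha
      sc[fcls == 2L & (tcls == 3L | tcls == 4L)] <- params$gamma
    } else {
      sc[fcls == 5L] <- params$beta
    }
    pr <- base[feas] * sc
    keep <- pr > 0
    from_idx <- c(from_idx, which(feas)[keep])
    to_idx <- c(to_idx, ti[keep])
    prob <- c(prob, pr[keep])
  }
  exit <- numeric(S)
  tot <- tapply(prob, from_idx, sum)
  exit[as.integer(names(tot))] <- tot
  diagonal <- 1 - exit
  if (any(diagonal < -1e-12))
    stop("negative self-loop probability: parameter bounds violated",
         call. = FALSE)
  # at the exact corner p = 1/4, q = 1/(2n) the exit mass is 1 up to
  # round-off; clamp within the row-sum tolerance
  diagonal[diagonal < 0] <- 0
  mat <- Matrix::sparseMatrix(
    i = c(from_idx, seq_len(S)),
    j = c(to_idx, seq_len(S)),
    x = c(prob, diagonal),
    dims = c(S, S))
  structure(list(matrix = mat, params = params, space = space),
            class = "kmt_kernel")
}

#' @export
print.kmt_kernel <- function(x, ...) {
  cat(sprintf(
    "kMT attachment transition kernel: %d x %d, %d nonzeros (%s, n = %d)\n",
    x$space$S, x$space$S, Matrix::nnzero(x$matrix), x$params$mode,
    x$params$n))
  invisible(x)
}

as_kmt_kernel <- function(x) {
  if (inherits(x, "kmt_kernel")) return(x)
  stop("expected a 'kmt_kernel' object; see ?build_kernel", call. = FALSE)
}

# absorbing states = rows with no off-diagonal mass (all exit events have
# exactly zero probability, so this identification is exact)
absorbing_states <- function(kernel) {
  m <- kernel$matrix
  S <- nrow(m)
  tm <- methods::as(m, "TsparseMatrix")
  off <- tm@i[tm@i != tm@j & tm@x > 0] + 1L
  setdiff(seq_len(S), unique(off))
}
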