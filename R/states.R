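#' Attachment classes
#'
#' Integer codes and names of the five canonical kinetochore attachment
#' classes: 1 free, 2 monotelic, 3 syntelic, 4 merotelic, 5 amphitelic.
#'
#' @format Named integer vector of length 5.
#' @export
kmt_classes <- c(free = 1L, monotelic = 2L, syntelic = 3L,
                 merotelic = 4L, amphitelic = 5L)

#' Classify attachment states into the five canonical classes
#'
#' A state of the kinetochore pair is the count 4-tuple
#' `(i1, j1, i2, j2)`: left- and right-pole kMT counts on kinetochore 1,
#' then on kinetochore 2. The classification (applied in order of
#' precedence) is:
#'
#' * class 4 (merotelic) if either kinetochore carries kMTs from both
#'   poles;
#' * class 1 (free) if all counts are zero;
#' * class 5 (amphitelic) if one kinetochore is attached to the left pole
#'   only and the other to the right pole only;
#' * class 3 (syntelic) if both kinetochores are attached, to the same
#'   single pole;
#' * class 2 (monotelic) otherwise, i.e. exactly one kinetochore attached,
#'   to a single pole.
#'
#' All arguments are recycled to a common length, so the function is
#' vectorised over states.
#'
#' @param i1,j1,i2,j2 Non-negative integer kMT counts.
#' @return Integer vector of class codes in `1:5` (see [kmt_classes]).
#' @examples
#' classify_state(0, 0, 0, 0)   # free
#' classify_state(1, 0, 0, 1)   # amphitelic
#' classify_state(1, 1, 0, 0)   # merotelic
#' @export
classify_state <- function(i1, j1, i2, j2) {
  len <- max(length(i1), length(j1), length(i2), length(j2))
  i1 <- rep_len(as.integer(i1), len); j1 <- rep_len(as.integer(j1), len)
  i2 <- rep_len(as.integer(i2), len); j2 <- rep_len(as.integer(j2), len)
  if (any(i1 < 0 | j1 < 0 | i2 < 0 | j2 < 0))
    stop("kMT counts must be non-negative", call. = FALSE)
  both1 <- i1 > 0L & j1 > 0L
  both2 <- i2 > 0L & j2 > 0L
  lonly1 <- i1 > 0L & j1 == 0L; ronly1 <- j1 > 0L & i1 == 0L
  lonly2 <- i2 > 0L & j2 == 0L; ronly2 <- j2 > 0L & i2 == 0L
  none1 <- i1 == 0L & j1 == 0L; none2 <- i2 == 0L & j2 == 0L
  cls <- integer(len)
  cls[both1 | both2] <- 4L
  rest <- cls == 0L
  cls[rest & none1 & none2] <- 1L
  cls[rest & ((lonly1 & ronly2) | (ronly1 & lonly2))] <- 5L
  cls[rest & ((lonly1 & lonly2) | (ronly1 & ronly2))] <- 3L
  cls[cls == 0L] <- 2L
  cls
}

#' Enumerate the attachment state space of a kinetochore pair
#'
#' Lists every state `(i1, j1, i2, j2)` with `i1 + j1 <= n` and
#' `i2 + j2 <= n`, in lexicographic order of `(i1, j1, i2, j2)` (`i1`
#' most significant). With `m = (n + 1)(n + 2)/2` admissible
#' configurations per kinetochore, the space holds `m^2` states. The
#' ordering is deterministic and stable, so state indices and serialised
#' kernels are reproducible across sessions.
#'
#' @param n Integer `>= 2`; maximal number of kMTs per kinetochore.
#' @return An object of class `"kmt_space"`: a list with
#'   \describe{
#'     \item{n}{the capacity used for enumeration,}
#'     \item{S}{number of states,}
#'     \item{states}{data frame with columns `i1, j1, i2, j2, class`
#'       (row order = state index),}
#'     \item{class}{integer vector of per-state class codes.}
#'   }
#' @examples
#' sp <- enumerate_states(2)
#' sp$S                      # 36
#' table(sp$class)
#' @export
enumerate_states <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  # admissible (i, j) pairs for one kinetochore, lexicographic in (i, j)
  one <- do.call(rbind, lapply(0:n, function(i)
    cbind(i = i, j = 0:(n - i))))
  m <- nrow(one)
  k1 <- one[rep(seq_len(m), each = m), , drop = FALSE]
  k2 <- one[rep(seq_len(m), times = m), , drop = FALSE]
  states <- data.frame(i1 = k1[, 1], j1 = k1[, 2],
                       i2 = k2[, 1], j2 = k2[, 2])
  cls <- classify_state(states$i1, states$j1, states$i2, states$j2)
  states$class <- cls
  key <- state_key(n, states$i1, states$j1, states$i2, states$j2)
  lookup <- integer(state_key(n, n, 0L, n, 0L) + 1L)
  lookup[key + 1L] <- seq_len(nrow(states))
  structure(
    list(n = n, S = nrow(states), states = states, class = cls,
         .lookup = lookup),
    class = "kmt_space"
  )
}

# dense integer key of a state tuple; used only for O(1) index lookup
state_key <- function(n, i1, j1, i2, j2) {
  b <- n + 1L
  ((as.integer(i1) * b + as.integer(j1)) * b + as.integer(i2)) * b +
    as.integer(j2)
}

#' Index of a state in an enumerated state space
#'
#' Inverse of the enumeration order of [enumerate_states()]: maps a count
#' 4-tuple to its 1-based row index. Vectorised; invalid tuples
#' (negative counts or per-kinetochore sums exceeding `n`) raise an error.
#'
#' @param space A `"kmt_space"` from [enumerate_states()].
#' @param i1,j1,i2,j2 kMT counts, recycled to a common length.
#' @return Integer vector of 1-based state indices.
#' @examples
#' sp <- enumerate_states(2)
#' state_index(sp, 0, 0, 0, 0)   # 1: enumeration starts at the empty state
#' @export
state_index <- function(space, i1, j1, i2, j2) {
  stopifnot(inherits(space, "kmt_space"))
  len <- max(length(i1), length(j1), length(i2), length(j2))
  i1 <- rep_len(as.integer(i1), len); j1 <- rep_len(as.integer(j1), len)
  i2 <- rep_len(as.integer(i2), len); j2 <- rep_len(as.integer(j2), len)
  n <- space$n
  bad <- i1 < 0L | j1 < 0L | i2 < 0L | j2 < 0L |
    (i1 + j1) > n | (i2 + j2) > n
  if (any(bad))
    stop("invalid state tuple(s): counts must be >= 0 with per-kinetochore sums <= n",
         call. = FALSE)
  space$.lookup[state_key(n, i1, j1, i2, j2) + 1L]
}

#' @export
print.kmt_space <- function(x, ...) {
  cat(sprintf("kMT attachment state space: n = %d, %d states\n", x$n, x$S))
  tab <- table(factor(x$class, levels = 1:5,
                      labels = names(kmt_classes)))
  print(tab)
  invisible(x)
}

# resolve a user-supplied state (index or 4-tuple) to a 1-based index
resolve_state <- function(space, state) {
  if (length(state) == 4L)
    return(state_index(space, state[1], state[2], state[3], state[4]))
  if (length(state) == 1L) {
    state <- as.integer(state)
    if (is.na(state) || state < 1L || state > space$S)
      stop("state index out of range", call. = FALSE)
    return(state)
  }
  stop("'state' must be a length-4 count tuple or a single state index",
       call. = FALSE)
}
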