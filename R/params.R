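#' Model parameters for the kinetochore-microtubule attachment chain
#'
#' Bundles and validates the six parameters of the discrete-time Markov
#' chain of kinetochore-microtubule (kMT) attachment, together with the
#' division mode. A kinetochore accommodates at most `n` kMTs; `2*p` is the
#' per-step association probability of a single microtubule to a fully free
#' kinetochore (so each pole contributes `p`); `q` is the per-step
#' dissociation probability of a single kMT. Three dimensionless factors in
#' `[0, 1]` rescale specific class transitions:
#'
#' * `alpha` scales attachments that take an amphitelic state (class 5) to a
#'   merotelic one (class 4), modelling the geometric constraint on
#'   bi-oriented kinetochores. Fixed at 0 in mitosis.
#' * `beta` scales every detachment event originating in class 5, modelling
#'   kMT stabilisation by inter-kinetochore tension.
#' * `gamma` scales attachments that take a monotelic state (class 2) to a
#'   syntelic (class 3) or merotelic (class 4) one, modelling the biased
#'   back-to-back orientation of sister kinetochores in mitosis. Fixed at 1
#'   in meiosis I.
#'
#' The admissible ranges `0 <= p <= 1/4` and `0 <= q <= 1/(2n)` guarantee
#' that the eight single-event probabilities of any state sum to at most 1,
#' so the self-loop always carries non-negative residual mass.
#'
#' @param n Integer `>= 2`; maximal number of kMTs per kinetochore.
#' @param p Association probability per pole per step, in `[0, 1/4]`.
#' @param q Dissociation probability per kMT per step, in `[0, 1/(2n)]`.
#' @param alpha Scaling of class-5 to class-4 attachments, in `[0, 1]`.
#'   Must be 0 in mitosis (the default there).
#' @param beta Scaling of detachments out of class 5, in `[0, 1]`.
#' @param gamma Scaling of class-2 to class-3/4 attachments, in `[0, 1]`.
#'   Must be 1 in meiosis I (the default there); the conventional mitotic
#'   value is 0.1.
#' @param mode `"meiosis_I"` or `"mitosis"`.
#'
#' @return An object of class `"kmt_params"`: a validated list with fields
#'   `n`, `p`, `q`, `alpha`, `beta`, `gamma`, `mode`.
#' @examples
#' kmt_params(n = 10, p = 0.05, q = 0.05, alpha = 0, beta = 0)
#' kmt_params(n = 10, p = 0.05, q = 0.05, beta = 1, gamma = 0.1,
#'            mode = "mitosis")
#' @export
kmt_params <- function(n = 10, p = 0.05, q = 0.05, alpha = NULL, beta = 0,
                       gamma = NULL, mode = c("meiosis_I", "mitosis")) {
  mode <- match.arg(mode)
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  n <- as.integer(n)
  chk01 <- function(x, nm, hi, hi_lab) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > hi)
      stop(sprintf("'%s' must lie in [0, %s]", nm, hi_lab), call. = FALSE)
    as.numeric(x)
  }
  p <- chk01(p, "p", 0.25, "1/4")
  q <- chk01(q, "q", 1 / (2 * n), "1/(2n)")
  beta <- chk01(beta, "beta", 1, "1")
  if (mode == "mitosis") {
    if (is.null(alpha)) alpha <- 0
    alpha <- chk01(alpha, "alpha", 1, "1")
    if (alpha != 0)
      stop("'alpha' is fixed at 0 in mitosis", call. = FALSE)
    if (is.null(gamma)) gamma <- 0.1
    gamma <- chk01(gamma, "gamma", 1, "1")
  } else {
    if (is.null(alpha)) alpha <- 0
    alpha <- chk01(alpha, "alpha", 1, "1")
    if (is.null(gamma)) gamma <- 1
    gamma <- chk01(gamma, "gamma", 1, "1")
    if (gamma != 1)
      stop("'gamma' is fixed at 1 in meiosis I", call. = FALSE)
  }
  structure(
    list(n = n, p = p, q = q, alpha = alpha, beta = beta, gamma = gamma,
         mode = mode),
    class = "kmt_params"
  )
}

#' @export
print.kmt_params <- function(x, ...) {
  cat(sprintf(
    "kMT attachment chain parameters (%s)\n  n = %d, p = %g, q = %g, alpha = %g, beta = %g, gamma = %g\n",
    x$mode, x$n, x$p, x$q, x$alpha, x$beta, x$gamma))
  invisible(x)
}

as_kmt_params <- function(x) {
  if (inherits(x, "kmt_params")) return(x)
  stop("expected a 'kmt_params' object; see ?kmt_params", call. = FALSE)
}
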