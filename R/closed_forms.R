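# Closed-form stationary occupancy results. In the fully unscaled regime
# alpha = beta = gamma = 1 the two kinetochores decouple and each follows
# a reversible birth-death process over (left, right, free) attachment
# slots; the stationary per-kinetochore occupancy is then available in
# closed form. For alpha = 0 an analytical approximation gives the mean
# occupancy conditional on the amphitelic class.

#' Exact stationary mean kMT number per kinetochore (unscaled regime)
#'
#' In the special case `alpha = beta = gamma = 1` the stationary mean
#' number of kMTs per kinetochore is `n * rho / (n + rho)` with
#' `rho = 2p/q`. For `p = q` and `n = 10` this equals `5/3`.
#'
#' @param n Capacity per kinetochore (`>= 2`).
#' @param p Association probability per pole, in `[0, 1/4]`.
#' @param q Dissociation probability per kMT, in `(0, 1/(2n)]`; `q = 0`
#'   is rejected (the ratio `rho` is undefined).
#' @return Mean kMT count per kinetochore, in `[0, n]`.
#' @examples
#' steady_state_mean_kmt(10, 0.05, 0.05)   # 5/3
#' @export
steady_state_mean_kmt <- function(n, p, q) {
  if (length(q) != 1L || !is.finite(q) || q <= 0)
    stop("'q' must be > 0: rho = 2p/q is undefined at q = 0", call. = FALSE)
  pars <- kmt_params(n = n, p = p, q = q, alpha = 1, beta = 1, gamma = 1,
                     mode = "meiosis_I")
  rho <- 2 * pars$p / pars$q
  pars$n * rho / (pars$n + rho)
}

#' Approximate stationary mean kMT number in amphitelic states
#'
#' Analytical approximation (valid in the `alpha = 0` regime, both
#' mitosis and meiosis I) of the stationary mean kMT count per
#' kinetochore conditional on the amphitelic class:
#' `rho_bar * x^(n-1) / (x^n - 2^n)` with `x = rho_bar/n + 2` and
#' `rho_bar = 2p / (beta q)`. Evaluated in log space when `x^n` would
#' overflow (large `n` or small `beta q`); the `beta -> 0+` limit is `n`,
#' consistent with kMT numbers approaching capacity when detachment out
#' of the amphitelic class is blocked.
#'
#' @param n Capacity per kinetochore (`>= 2`).
#' @param p Association probability per pole, in `[0, 1/4]`.
#' @param q Dissociation probability per kMT, `> 0`.
#' @param beta Tension scaling of amphitelic detachments, `> 0` (the
#'   exact limit at `beta = 0` is the capacity `n`; request it explicitly
#'   rather than through this approximation).
#' @return Approximate conditional mean kMT count, in `(0, n]`.
#' @examples
#' amphitelic_mean_kmt_approx(10, 0.05, 0.05, beta = 1)  # about 1.479
#' @export
amphitelic_mean_kmt_approx <- function(n, p, q, beta) {
  if (length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2", call. = FALSE)
  if (length(p) != 1L || p < 0) stop("'p' must be >= 0", call. = FALSE)
  if (length(q) != 1L || q <= 0)
    stop("'q' must be > 0; the beta*q -> 0 limit of the mean is n",
         call. = FALSE)
  if (length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]; the beta -> 0 limit of the mean is n",
         call. = FALSE)
  if (p == 0) return(0)
  rho_bar <- 2 * p / (beta * q)
  # factor out 2^n: N5 = rho_bar * y^(n-1) / (2 * (y^n - 1)), y = x/2
  y <- rho_bar / (2 * n) + 1
  nlogy <- n * log(y)
  if (nlogy < 700) {
    rho_bar * y^(n - 1) / (2 * expm1(nlogy))
  } else {
    # y^n dominates; log-space evaluation of rho_bar/(2y) * 1/(1 - y^-n)
    rho_bar / (2 * y) / (1 - exp(-nlogy))
  }
}
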