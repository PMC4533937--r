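# Brute-force dense reference implementation, written independently of
# the package internals (pattern-string classification, explicit event
# loops, dense linear algebra). Used to audit the production code at
# small n.

oracle_classify <- function(i1, j1, i2, j2) {
  pat <- function(i, j) {
    if (i > 0 && j > 0) "LR" else if (i > 0) "L" else if (j > 0) "R" else "0"
  }
  p1 <- pat(i1, j1); p2 <- pat(i2, j2)
  if (p1 == "LR" || p2 == "LR") return(4L)
  if (p1 == "0" && p2 == "0") return(1L)
  if ((p1 == "L" && p2 == "R") || (p1 == "R" && p2 == "L")) return(5L)
  if (p1 == p2) return(3L)
  2L
}

# all states with per-kinetochore sums <= n, lexicographic (i1,j1,i2,j2)
oracle_states <- function(n) {
  out <- NULL
  for (i1 in 0:n) for (j1 in 0:(n - i1))
    for (i2 in 0:n) for (j2 in 0:(n - i2))
      out <- rbind(out, c(i1, j1, i2, j2))
  out
}

# dense one-step transition matrix built event by event
oracle_kernel <- function(n, p, q, alpha, beta, gamma) {
  st <- oracle_states(n)
  S <- nrow(st)
  cls <- apply(st, 1, function(s) oracle_classify(s[1], s[2], s[3], s[4]))
  key <- function(s) paste(s, collapse = ",")
  idx <- structure(seq_len(S), names = apply(st, 1, key))
  K <- matrix(0, S, S)
  for (u in seq_len(S)) {
    s <- st[u, ]
    for (slot in 1:4) {
      kt <- if (slot <= 2) 1 else 2
      occ <- if (kt == 1) s[1] + s[2] else s[3] + s[4]
      # attachment
      if (occ < n) {
        t_ <- s; t_[slot] <- t_[slot] + 1
        pr <- (n - occ) / n * p
        cf <- cls[u]; ct <- oracle_classify(t_[1], t_[2], t_[3], t_[4])
        if (cf == 5 && ct == 4) pr <- pr * alpha
        if (cf == 2 && ct %in% c(3, 4)) pr <- pr * gamma
        v <- idx[[key(t_)]]
        K[u, v] <- K[u, v] + pr
      }
      # detachment
      if (s[slot] > 0) {
        t_ <- s; t_[slot] <- t_[slot] - 1
        pr <- s[slot] * q
        if (cls[u] == 5) pr <- pr * beta
        v <- idx[[key(t_)]]
        K[u, v] <- K[u, v] + pr
      }
    }
    K[u, u] <- K[u, u] + 1 - sum(K[u, ])
  }
  list(K = K, states = st, class = cls)
}

oracle_propagate <- function(K, v0, steps) {
  out <- matrix(0, steps + 1, length(v0))
  out[1, ] <- v0
  v <- v0
  for (t in seq_len(steps)) {
    v <- as.numeric(v %*% K)
    out[t + 1, ] <- v
  }
  out
}

oracle_mfpt <- function(ok, target_class, start_idx) {
  tgt <- ok$class == target_class
  t_full <- numeric(nrow(ok$K))
  trans <- which(!tgt)
  Q <- ok$K[trans, trans, drop = FALSE]
  t_full[trans] <- solve(diag(length(trans)) - Q, rep(1, length(trans)))
  t_full[start_idx]
}

oracle_stationary <- function(K) {
  ev <- eigen(t(K))
  i1 <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i1])
  v / sum(v)
}

# shared fixture parameters used across test files
oracle_pars_n2 <- list(n = 2, p = 0.05, q = 0.05)
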