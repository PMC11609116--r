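# Independent brute-force oracles used across the suite.  These deliberately
# re-derive everything from first principles (loops, pairwise Hamming
# distances, path-following descent) so that they share no code with the
# implementation they check.

# moments by naive loops over samples and channel pairs
naive_moments <- function(spins) {
  F_ <- nrow(spins); C <- ncol(spins)
  act <- numeric(C)
  for (m in 1:C) for (f in 1:F_) act[m] <- act[m] + spins[f, m] / F_
  cooc <- matrix(0, C, C)
  for (m in 1:C) for (n in 1:C) {
    s <- 0
    for (f in 1:F_) s <- s + spins[f, m] * spins[f, n]
    cooc[m, n] <- s / F_
  }
  list(act = act, cooc = cooc)
}

# Hamming distance between 0-based state codes
hamming <- function(a, b) {
  sum(as.integer(intToBits(bitwXor(as.integer(a), as.integer(b)))))
}

# neighbour sets by scanning all pairs
brute_neighbors <- function(code, C) {
  others <- setdiff(0:(2^C - 1), code)
  sort(others[vapply(others, function(o) hamming(code, o) == 1, logical(1))])
}

# strict local minima by exhaustive comparison
brute_minima <- function(E, C) {
  lms <- integer(0)
  for (i in 0:(2^C - 1)) {
    nb <- brute_neighbors(i, C)
    if (all(E[i + 1] < E[nb + 1])) lms <- c(lms, i + 1L)
  }
  lms
}

# basin assignment by explicit path-following steepest descent with
# lowest-code tie break
brute_basins <- function(E, C) {
  owner <- integer(2^C)
  for (i in 0:(2^C - 1)) {
    cur <- i
    repeat {
      nb <- brute_neighbors(cur, C)
      best <- min(E[nb + 1])
      if (best < E[cur + 1]) {
        cand <- nb[E[nb + 1] == best]
        cur <- min(cand)
      } else break
    }
    owner[i + 1] <- cur + 1L
  }
  owner
}

# random symmetric coupling matrix with zero diagonal
rand_J <- function(C, sd = 0.3) {
  J <- matrix(rnorm(C * C, sd = sd), C, C)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  J
}

# KL divergence in bits by direct summation (0 log 0 = 0)
naive_kl2 <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  s
}
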