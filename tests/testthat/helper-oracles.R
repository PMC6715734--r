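# Independent oracles used across the suite.

# Brute-force posterior for the 3-state background HMM: enumerate all
# 3^n state paths with the same emission/transition definitions as the
# fast implementation, written independently of it.
brute_force_posterior <- function(calls, pos, eps, r) {
  n <- length(calls)
  stopifnot(n <= 15)
  Tmat <- rbind(c(0, 1, 0), c(0.5, 0, 0.5), c(0, 1, 0))
  em <- function(call, s) {
    if (is.na(call)) return(1)
    if (call == s) 1 - eps else eps / 2
  }
  trans <- function(a, b, d) {
    q <- 1 - exp(-r * d)
    if (a == b) 1 - q * sum(Tmat[a + 1, -(a + 1)]) else q * Tmat[a + 1, b + 1]
  }
  paths <- as.matrix(expand.grid(rep(list(0:2), n)))
  w <- apply(paths, 1, function(st) {
    p <- (1 / 3) * em(calls[1], st[1])
    if (n > 1) for (i in 2:n)
      p <- p * trans(st[i - 1], st[i], pos[i] - pos[i - 1]) *
        em(calls[i], st[i])
    p
  })
  post <- matrix(0, n, 3)
  for (s in 0:2)
    post[, s + 1] <- colSums(w * (paths == s)) / sum(w)
  post
}

# Exhaustive two-sided binomial p at p0 = 0.5 by direct summation of
# outcomes no more likely than the observed one.
enum_binom_p <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] + 1e-12])
}

# Fisher exact two-sided p by hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood convention).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Continuous maximiser of the composite log-likelihood (independent of
# the grid-search code path).
optim_tract_mean <- function(pairs) {
  f <- function(mean_bp) {
    lam <- 1 / mean_bp
    p <- exp(-lam * pairs$d)
    -sum(pairs$x * log(p) + (1 - pairs$x) * log(pmax(1 - p, 1e-300)))
  }
  stats::optimize(f, c(1, 1000))$minimum
}
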