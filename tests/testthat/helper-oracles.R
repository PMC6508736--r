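# Independent brute-force oracles used to check the package's
# implementations. These deliberately re-derive each quantity from its
# definition by a different route than the package code.

# TMM: trimmed, precision-weighted mean of M-values against the sample
# whose upper-quartile count rate is closest to the mean upper quartile;
# factors renormalized to geometric mean 1.
brute_tmm <- function(counts, lib = colSums(counts),
                      trim_m = 0.3, trim_a = 0.05) {
  uq <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(j) {
    o <- counts[, j]; r <- counts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    k <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    f <- sum(M[k] / w[k]) / sum(1 / w[k])
    if (!is.finite(f) || abs(f) < 1e-6) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Conditional exact NB p-value by direct enumeration of the joint NB
# probabilities of every split of the total (normalized), rather than the
# closed-form beta-binomial pmf the implementation uses.
brute_nb_pvalue <- function(s1, total, n1, n2, phi) {
  if (total == 0) return(1)
  x <- 0:total
  if (phi == 0) {
    w <- dbinom(x, total, n1 / (n1 + n2))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    w <- dnbinom(x, size = r1, mu = r1) *
      dnbinom(total - x, size = r2, mu = r2)
    w <- w / sum(w)
  }
  sum(w[w <= w[s1 + 1] * (1 + 1e-8)])
}

# BH step-up from its definition: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ps >= ps[i])
    q[i] <- min(1, min(m * ps[j] / j))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Rat screen by a per-row filter written independently of the
# implementation's vectorized form.
brute_rat_screen <- function(expr, fold) {
  keep <- character(0)
  others <- setdiff(colnames(expr), "Sertoli")
  for (g in rownames(expr)) {
    s <- expr[g, "Sertoli"]
    mx <- max(expr[g, others])
    ok <- if (mx > 0) s >= fold * mx else s > 0
    if (ok) keep <- c(keep, g)
  }
  keep
}
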