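# Shared fixtures and small oracles used across test files.

softSubstrate <- function() ElasticSubstrate(1000, 0.45)

# relative L2 error between two traction-like component pairs
relL2 <- function(ax, ay, bx, by) {
  sqrt(sum((ax - bx)^2 + (ay - by)^2) / sum(bx^2 + by^2))
}

# textbook Pearson correlation, written out (independent of stats::cor)
pearsonByHand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# pooled-variance two-sided t test from the closed-form textbook formula
tTestByHand <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tstat,
       p = 2 * stats::pt(-abs(tstat), n1 + n2 - 2))
}

# brute-force optimal assignment cost over permutations (equal-size sets,
# pairs beyond maxDisp penalized like an unmatched pair on each side)
bruteForceLinkCost <- function(c1, c2, maxDisp) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  pen <- maxDisp^2
  best <- Inf
  for (p in perms(seq_len(nrow(c1)))) {
    d2 <- rowSums((c1 - c2[p, , drop = FALSE])^2)
    best <- min(best, sum(ifelse(d2 <= pen, d2, 2 * pen)))
  }
  best
}
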