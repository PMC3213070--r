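# Independent brute-force / closed-form oracles used to verify the package's
# statistics. These deliberately share no code with the implementation:
# medians are taken by sorting, ANOVA by explicit sums of squares, the
# Kruskal-Wallis statistic by the rank formula with tie correction, BH by the
# step-up recursion, and geNorm M by materializing every pairwise difference
# vector.

oracle_median <- function(v) {
  s <- sort(unname(v))
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

oracle_mad <- function(v) oracle_median(abs(v - oracle_median(v)))

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

oracle_kw <- function(groups) {
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ri <- r[idx == i]
      length(ri) * (mean(ri) - (n + 1) / 2)^2
    }, 0))
  ties <- table(all_v)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  list(H = h, p = stats::pchisq(h, length(groups) - 1L, lower.tail = FALSE))
}

oracle_genorm <- function(x, candidates) {
  sd_nminus1 <- function(d) sqrt(sum((d - mean(d))^2) / (length(d) - 1L))
  m <- numeric(length(candidates))
  names(m) <- candidates
  for (i in candidates) {
    sds <- c()
    for (j in setdiff(candidates, i))
      sds <- c(sds, sd_nminus1(x[i, ] - x[j, ]))
    m[i] <- mean(sds)
  }
  m
}
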