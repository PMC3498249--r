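# Independent brute-force oracles. These deliberately re-derive each
# statistic with plain loops (no shared code with the package internals) so
# that tests compare two independent routes to the same number.

bc_oracle <- function(x, y) {
  num <- 0
  for (i in seq_along(x)) num <- num + min(x[i], y[i])
  2 * num / (sum(x) + sum(y))
}

mh_oracle <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  cross <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    cross <- cross + x[i] * y[i]
    dx <- dx + x[i]^2
    dy <- dy + y[i]^2
  }
  2 * cross / ((dx / X^2 + dy / Y^2) * X * Y)
}

chao_uncorr_oracle <- function(x, y) {
  U <- 0; V <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0 && y[i] > 0) {
      U <- U + x[i] / sum(x)
      V <- V + y[i] / sum(y)
    }
  }
  if (U == 0 || V == 0) return(0)
  U * V / (U + V - U * V)
}

paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  se <- sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n)
  t <- mean(d) / se
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# E[S(n)] by exhaustive enumeration of every n-subset of individuals
rarefy_enum_oracle <- function(counts, n) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), n)
  s <- apply(subs, 2, function(idx) length(unique(pool[idx])))
  list(expected = mean(s), variance = mean((s - mean(s))^2))
}

# IndVal statistic recomputed from first principles for one labeling
indval_oracle_stat <- function(x, groups) {
  glev <- sort(unique(groups))
  sapply(seq_len(ncol(x)), function(s) {
    mns <- sapply(glev, function(g) mean(x[groups == g, s]))
    frq <- sapply(glev, function(g) mean(x[groups == g, s] > 0))
    if (sum(mns) == 0) return(0)
    max(mns / sum(mns) * frq)
  })
}

random_count_pair <- function(n_species = 12, lambda = 3) {
  x <- rpois(n_species, lambda)
  y <- rpois(n_species, lambda)
  if (sum(x) == 0) x[1] <- 1L
  if (sum(y) == 0) y[1] <- 1L
  list(x = x, y = y)
}
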