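# Independent brute-force oracles used to validate the package's statistics.
# These deliberately avoid the implementation's code paths.

# shortest arc by explicit minimisation over candidate windings
oracle_geodesic <- function(a, b) {
  k <- -10:10
  min(abs(a - b + 2 * pi * k))
}

# ART statistic by an explicit double loop
oracle_art <- function(s1, s2) {
  acc <- 0
  for (x in s1) for (y in s2) acc <- acc + oracle_geodesic(x, y)
  acc
}

# two-sample Watson U2 via an explicit scan of the pooled circular order;
# cross-sample ties broken by a literal infinitesimal offset on sample 2
oracle_wu2 <- function(s1, s2, eps = 1e-9) {
  m <- length(s1); n <- length(s2)
  pooled <- c(s1, s2 + eps)
  lab <- rep(c(1L, 2L), c(m, n))
  o <- order(pooled)
  lab <- lab[o]
  d <- numeric(m + n)
  c1 <- 0; c2 <- 0
  for (k in seq_along(lab)) {
    if (lab[k] == 1L) c1 <- c1 + 1 else c2 <- c2 + 1
    d[k] <- c1 / m - c2 / n
  }
  (m * n / (m + n)^2) * sum((d - mean(d))^2)
}

# Watson-Wheeler uniform-scores statistic via literal ranks -> scores ->
# resultant, with the exact permutation variance scaling
oracle_ww <- function(s1, s2) {
  m <- length(s1); n <- length(s2)
  T_ <- m + n
  r <- rank(c(s1, s2))
  beta <- 2 * pi * r / T_
  C1 <- sum(cos(beta[1:m])); S1 <- sum(sin(beta[1:m]))
  2 * (T_ - 1) * (C1^2 + S1^2) / (m * n)
}

# spacing frequencies by a literal per-arc membership count
oracle_rsf <- function(s1, s2) {
  m <- length(s1); n <- length(s2)
  a <- sort(s1)
  f <- integer(m)
  for (y in s2) {
    i <- max(which(a <= y), 0L)
    if (i == 0L) i <- m  # before the first order statistic: wrap-around arc
    f[i] <- f[i] + 1L
  }
  sum(abs(f - n / m))
}

# exact permutation p-value by full enumeration of all C(m+n, m) relabelings,
# counting assignments with statistic >= observed (the identity is included)
oracle_exhaustive_p <- function(stat, s1, s2) {
  m <- length(s1)
  pooled <- c(s1, s2)
  observed <- stat(s1, s2)
  threshold <- observed - 1e-9 * (abs(observed) + 1)  # ties count as hits
  subsets <- utils::combn(length(pooled), m)
  hits <- 0L
  for (j in seq_len(ncol(subsets))) {
    idx <- subsets[, j]
    if (stat(pooled[idx], pooled[-idx]) >= threshold) hits <- hits + 1L
  }
  hits / ncol(subsets)
}

# truncated alternating series for the asymptotic Watson U2 tail, high order
oracle_wu2_tail <- function(u2, terms = 50) {
  k <- seq_len(terms)
  sum(2 * (-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
}

circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))
resultant_length <- function(x) sqrt(mean(cos(x))^2 + mean(sin(x))^2)

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# closed-form skewness of the skew-normal with shape alpha
skew_normal_skewness <- function(alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  mu_z <- delta * sqrt(2 / pi)
  (4 - pi) / 2 * mu_z^3 / (1 - mu_z^2)^1.5
}
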