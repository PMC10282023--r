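TEST_NAMES <- c("ART", "WU2", "pWU2", "WW", "pWW", "Rsf")

#' ART statistic: summed cross-sample geodesic distances
#'
#' The Angular Randomisation Test statistic
#' \eqn{G = \sum_i \sum_j D(\phi_i, \psi_j)}: the sum of the shortest angular
#' (geodesic) distances from every point in one sample to every point in the
#' other. No scalar multiplier is applied. Symmetric in its two arguments.
#'
#' @param s1,s2 Numeric vectors of angles in radians (wrapped internally), or
#'   [angle_sample] objects.
#' @return A single non-negative number.
#' @examples
#' art_statistic(0, pi)                 # pi
#' art_statistic(0, c(pi / 2, pi))      # 3 * pi / 2
#' @export
art_statistic <- function(s1, s2) {
  a <- as_angles(s1)
  b <- as_angles(s2)
  sum(geodesic_distance(rep(a, times = length(b)), rep(b, each = length(a))))
}

#' Monte-Carlo permutation p-value for a two-sample statistic
#'
#' Computes the observed statistic, draws `n_permutations` independent uniform
#' random relabellings of the pooled values into groups of the original sizes,
#' counts the number `Q` of relabellings whose statistic is greater than or
#' equal to the observed value, and returns
#' \eqn{p = (Q + 1) / (N + 1)}. The weak inequality makes the test valid
#' (conservative) in the presence of tied statistic values. Upper-tail only:
#' the statistic must be large under the alternative.
#'
#' Uses R's global RNG; pass `seed` (or call `set.seed()` yourself) for
#' reproducibility.
#'
#' @param statistic A function of two numeric vectors of radians returning a
#'   single number.
#' @param s1,s2 Angle vectors (radians) or [angle_sample] objects.
#' @param n_permutations Number of random relabellings `N`, at least 1.
#' @param seed Optional integer seed applied before drawing relabellings.
#' @return A list with elements `p_value`, `observed`, `n_exceeding`,
#'   `n_permutations`.
#' @examples
#' set.seed(1)
#' a <- sample_von_mises(0, 2, 8)
#' b <- sample_von_mises(pi, 2, 8)
#' permutation_pvalue(art_statistic, a, b, n_permutations = 199, seed = 1)
#' @export
permutation_pvalue <- function(statistic, s1, s2, n_permutations = 10000,
                               seed = NULL) {
  stopifnot(is.function(statistic))
  a <- as_angles(s1)
  b <- as_angles(s2)
  if (!is.numeric(n_permutations) || length(n_permutations) != 1L ||
      is.na(n_permutations) || n_permutations < 1) {
    stop("`n_permutations` must be a positive integer", call. = FALSE)
  }
  n_permutations <- as.integer(n_permutations)
  if (!is.null(seed)) set.seed(seed)
  m <- length(a)
  pooled <- c(a, b)
  observed <- statistic(a, b)
  # ties within floating noise count as exceedances (conservative direction)
  threshold <- observed - 1e-9 * (abs(observed) + 1)
  q <- 0L
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(length(pooled), m)
    if (statistic(pooled[idx], pooled[-idx]) >= threshold) q <- q + 1L
  }
  list(p_value = (q + 1) / (n_permutations + 1),
       observed = observed, n_exceeding = q,
       n_permutations = n_permutations)
}

# Shared fast path: sorts the pooled sample once and runs the C++ engine for
# the requested permutation statistics. Ties across samples are resolved by
# stable ordering with sample 1 first (equivalent to an infinitesimal positive
# offset on sample-2 values).
perm_engine <- function(a, b, n_permutations, seed,
                        art = FALSE, wu2 = FALSE, ww = FALSE, rsf = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(a)
  pooled <- c(a, b)
  src <- rep(c(FALSE, TRUE), c(m, length(b)))  # TRUE = sample 2
  o <- order(pooled, src)                       # stable: ties put s1 first
  pos_of_orig <- integer(length(pooled))
  pos_of_orig[o] <- seq_along(pooled) - 1L
  perm_engine_cpp(pooled[o], !src[o], pos_of_orig,
                  as.integer(n_permutations), art, wu2, ww, rsf)
}

new_test_result <- function(test_name, statistic, p_value, method,
                            m, n, n_permutations = NULL, n_exceeding = NULL,
                            seed = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         p.value = p_value, method = method, m = m, n = n,
         n_permutations = n_permutations, n_exceeding = n_exceeding,
         seed = seed),
    class = "circart_test")
}

#' @export
print.circart_test <- function(x, ...) {
  cat("\n\t", x$test_name, " two-sample test for circular data\n\n", sep = "")
  cat("samples: m =", x$m, ", n =", x$n, "\n")
  cat(names(x$statistic), "=", format(unname(x$statistic), digits = 6),
      ", p-value =", format(x$p_value, digits = 6), "\n")
  if (identical(x$method, "permutation")) {
    cat("permutation inference: N =", x$n_permutations,
        ", Q =", x$n_exceeding,
        if (!is.null(x$seed)) paste0(", seed = ", x$seed) else "", "\n")
  } else {
    cat("asymptotic inference\n")
  }
  invisible(x)
}

#' Angular Randomisation Test (ART)
#'
#' Two-sample permutation test whose statistic sums the geodesic angular
#' distances over all cross-sample pairs (see [art_statistic]). Significance
#' is upper-tail by permutation: \eqn{p = (Q + 1)/(N + 1)} where `Q` counts
#' random relabellings with a statistic at least as large as observed.
#'
#' @param s1,s2 Angle vectors in radians (wrapped internally) or
#'   [angle_sample] objects.
#' @param n_permutations Number of permutations `N` (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `circart_test` object with the observed statistic, p-value,
#'   sample sizes and permutation metadata.
#' @examples
#' set.seed(7)
#' a <- sample_von_mises(0, 2, 10)
#' b <- sample_von_mises(pi, 2, 10)
#' art_test(a, b, n_permutations = 999, seed = 1)
#' @export
art_test <- function(s1, s2, n_permutations = 10000, seed = NULL) {
  a <- as_angles(s1); b <- as_angles(s2)
  check_nperm(n_permutations)
  r <- perm_engine(a, b, n_permutations, seed, art = TRUE)
  new_test_result("ART", c(G = unname(r$observed["ART"])),
                  (r$n_exceeding[["ART"]] + 1) / (n_permutations + 1),
                  "permutation", length(a), length(b),
                  as.integer(n_permutations), as.integer(r$n_exceeding[["ART"]]),
                  seed)
}

check_nperm <- function(n_permutations) {
  if (!is.numeric(n_permutations) || length(n_permutations) != 1L ||
      is.na(n_permutations) || n_permutations < 1) {
    stop("`n_permutations` must be a positive integer", call. = FALSE)
  }
}

#' Watson's two-sample U2 statistic
#'
#' The classical two-sample Watson \eqn{U^2} computed from the pooled circular
#' ordering: with pooled size \eqn{T = m + n} and
#' \eqn{d_k = F_1(k) - F_2(k)} the difference in the fractions of each sample
#' seen after the k-th pooled ordered point,
#' \eqn{U^2 = (mn / T^2) \sum_k (d_k - \bar d)^2}. Rotation of both samples by
#' a common angle leaves the cyclic ordering, and hence \eqn{U^2}, unchanged.
#'
#' Exact ties across the two samples are resolved by a deterministic
#' infinitesimal offset placing sample-1 values first (`ties = "s1_first"`),
#' or raise an error (`ties = "error"`).
#'
#' @param s1,s2 Angle vectors in radians or [angle_sample] objects.
#' @param ties Cross-sample tie handling: `"s1_first"` (default) or
#'   `"error"`.
#' @return A single non-negative number.
#' @examples
#' watson_u2_statistic(c(0.1, 0.2, 0.3), c(3.1, 3.2, 3.3))
#' @export
watson_u2_statistic <- function(s1, s2, ties = c("s1_first", "error")) {
  ties <- match.arg(ties)
  a <- as_angles(s1); b <- as_angles(s2)
  m <- length(a); n <- length(b)
  if (m + n < 3) stop("combined sample size must be at least 3", call. = FALSE)
  if (ties == "error" && any(a %in% b)) {
    stop("exact cross-sample ties present; see `ties` argument", call. = FALSE)
  }
  pooled <- c(a, b)
  src2 <- rep(c(FALSE, TRUE), c(m, n))
  o <- order(pooled, src2)
  is1 <- !src2[o]
  d <- cumsum(is1) / m - cumsum(!is1) / n
  (m * n / (m + n)^2) * sum((d - mean(d))^2)
}

#' Asymptotic tail probability for Watson's U2
#'
#' The standard large-sample upper tail
#' \eqn{p = 2 \sum_{k \ge 1} (-1)^{k-1} \exp(-2 k^2 \pi^2 U^2)}, summed until
#' terms fall below 1e-10 (at least one term), clamped into \eqn{(0, 1]}.
#'
#' @param u2 Observed \eqn{U^2} value, non-negative.
#' @return A p-value in \eqn{(0, 1]}.
#' @examples
#' watson_u2_pvalue_asymptotic(0.187)  # near the 5% critical value
#' @export
watson_u2_pvalue_asymptotic <- function(u2) {
  if (!is.numeric(u2) || length(u2) != 1L || is.na(u2) || u2 < 0) {
    stop("`u2` must be a single non-negative number", call. = FALSE)
  }
  # the alternating series is unusable as u2 -> 0+, where the tail tends to 1
  if (u2 < 1e-6) return(1)
  p <- 0
  k <- 1
  repeat {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2)
    p <- p + term
    if (abs(term) < 1e-10 && k >= 1) break
    k <- k + 1
    if (k > 1000) break
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Watson's two-sample U2 test
#'
#' Asymptotic version (`WU2`): [watson_u2_statistic] with
#' [watson_u2_pvalue_asymptotic]. Permutation version (`pWU2`): the same
#' statistic with p-value \eqn{(Q+1)/(N+1)} over random relabellings.
#'
#' @inheritParams art_test
#' @param method `"asymptotic"` or `"permutation"`.
#' @return A `circart_test` object.
#' @examples
#' set.seed(2)
#' a <- sample_von_mises(0, 2, 12)
#' b <- sample_von_mises(pi, 2, 12)
#' watson_u2_test(a, b)
#' watson_u2_test(a, b, method = "permutation", n_permutations = 999, seed = 1)
#' @export
watson_u2_test <- function(s1, s2, method = c("asymptotic", "permutation"),
                           n_permutations = 10000, seed = NULL) {
  method <- match.arg(method)
  a <- as_angles(s1); b <- as_angles(s2)
  if (method == "asymptotic") {
    u2 <- watson_u2_statistic(a, b)
    new_test_result("WU2", c(U2 = u2), watson_u2_pvalue_asymptotic(u2),
                    "asymptotic", length(a), length(b))
  } else {
    check_nperm(n_permutations)
    r <- perm_engine(a, b, n_permutations, seed, wu2 = TRUE)
    new_test_result("pWU2", c(U2 = unname(r$observed["WU2"])),
                    (r$n_exceeding[["WU2"]] + 1) / (n_permutations + 1),
                    "permutation", length(a), length(b),
                    as.integer(n_permutations),
                    as.integer(r$n_exceeding[["WU2"]]), seed)
  }
}

#' Watson-Wheeler uniform-scores statistic
#'
#' Pooled circular ranks \eqn{r} are replaced by uniform scores
#' \eqn{\beta = 2\pi r / T}; with \eqn{(C_1, S_1)} the resultant components of
#' sample 1's scores, the statistic is
#' \eqn{W = 2 (T - 1)(C_1^2 + S_1^2) / (m n)}, which is asymptotically
#' \eqn{\chi^2} with 2 degrees of freedom (the \eqn{T - 1} factor is the exact
#' permutation variance of \eqn{C_1} and \eqn{S_1}). Symmetric in the two
#' samples because the pooled scores sum to zero.
#'
#' Exact cross-sample ties are incompatible with unambiguous ranks and raise
#' an error by default; `ties = "jitter"` adds a seeded uniform jitter of
#' magnitude 1e-9 radians to break them.
#'
#' @inheritParams watson_u2_statistic
#' @param ties `"error"` (default) or `"jitter"`.
#' @param jitter_seed Seed for the tie-breaking jitter (only with
#'   `ties = "jitter"`).
#' @return A list with elements `statistic` (W) and `p_value` (upper
#'   \eqn{\chi^2_2} tail).
#' @examples
#' watson_wheeler_statistic(c(0.1, 0.2), c(3.0, 3.1))
#' @export
watson_wheeler_statistic <- function(s1, s2, ties = c("error", "jitter"),
                                     jitter_seed = 1L) {
  ties <- match.arg(ties)
  a <- as_angles(s1); b <- as_angles(s2)
  m <- length(a); n <- length(b)
  if (m + n < 3) stop("combined sample size must be at least 3", call. = FALSE)
  if (any(a %in% b)) {
    if (ties == "error") {
      stop("exact cross-sample ties; ranks are ambiguous (use ties = \"jitter\")",
           call. = FALSE)
    }
    set.seed(jitter_seed)
    a <- wrap_angle(a + runif(m, -1e-9, 1e-9))
    b <- wrap_angle(b + runif(n, -1e-9, 1e-9))
  }
  T_ <- m + n
  r <- rank(c(a, b))
  beta <- TWO_PI * r / T_
  C1 <- sum(cos(beta[seq_len(m)]))
  S1 <- sum(sin(beta[seq_len(m)]))
  W <- 2 * (T_ - 1) * (C1^2 + S1^2) / (m * n)
  list(statistic = W, p_value = pchisq(W, df = 2, lower.tail = FALSE))
}

#' Watson-Wheeler uniform-scores test
#'
#' Asymptotic version (`WW`): [watson_wheeler_statistic] with its
#' \eqn{\chi^2_2} p-value. Permutation version (`pWW`): the same statistic
#' with p-value \eqn{(Q+1)/(N+1)} over random relabellings.
#'
#' @inheritParams watson_u2_test
#' @return A `circart_test` object.
#' @examples
#' set.seed(3)
#' a <- sample_von_mises(0, 2, 12)
#' b <- sample_von_mises(pi, 2, 12)
#' watson_wheeler_test(a, b)
#' @export
watson_wheeler_test <- function(s1, s2, method = c("asymptotic", "permutation"),
                                n_permutations = 10000, seed = NULL) {
  method <- match.arg(method)
  a <- as_angles(s1); b <- as_angles(s2)
  if (method == "asymptotic") {
    w <- watson_wheeler_statistic(a, b)
    new_test_result("WW", c(W = w$statistic), w$p_value,
                    "asymptotic", length(a), length(b))
  } else {
    check_nperm(n_permutations)
    if (any(a %in% b)) {
      stop("exact cross-sample ties; ranks are ambiguous", call. = FALSE)
    }
    r <- perm_engine(a, b, n_permutations, seed, ww = TRUE)
    new_test_result("pWW", c(W = unname(r$observed["WW"])),
                    (r$n_exceeding[["WW"]] + 1) / (n_permutations + 1),
                    "permutation", length(a), length(b),
                    as.integer(n_permutations),
                    as.integer(r$n_exceeding[["WW"]]), seed)
  }
}

#' Rao spacing-frequencies discrepancy statistic
#'
#' The `m` circular arcs between consecutive circular order statistics of
#' `s1` receive spacing frequencies \eqn{f_1, \dots, f_m} of `s2` points
#' (\eqn{\sum f_i = n}); the statistic is the total absolute discrepancy from
#' perfect interleaving, \eqn{\sum_i |f_i - n/m|}.
#'
#' @inheritParams art_statistic
#' @return A single non-negative number.
#' @examples
#' rao_spacing_frequency_statistic(c(0, pi / 2, pi, 3 * pi / 2),
#'                                 c(0.1, 0.2, 0.3, 0.4))  # 6
#' @export
rao_spacing_frequency_statistic <- function(s1, s2) {
  a <- as_angles(s1); b <- as_angles(s2)
  m <- length(a); n <- length(b)
  if (m < 2) stop("the anchoring sample must contain at least 2 angles",
                  call. = FALSE)
  arcs <- sort(a)
  # arc i spans [arcs[i], arcs[i+1]); last arc wraps around 2*pi
  f <- tabulate(findInterval(b, arcs), nbins = m)
  f[m] <- f[m] + sum(findInterval(b, arcs) == 0L)  # before first point: wrap arc
  sum(abs(f - n / m))
}

#' Rao spacing-frequencies permutation test
#'
#' Permutation test on [rao_spacing_frequency_statistic]: under each random
#' relabelling of the pooled sample, the group of size `m` anchors the arcs
#' and the discrepancy of the other group's spacing frequencies is computed;
#' \eqn{p = (Q+1)/(N+1)} counts relabellings at least as discrepant as
#' observed. Sensitive to multimodal differences that cross-pair distance
#' statistics miss.
#'
#' @inheritParams art_test
#' @return A `circart_test` object.
#' @examples
#' set.seed(4)
#' a <- sample_axial_von_mises(0, 2, 12)
#' b <- sample_axial_von_mises(pi / 2, 2, 12)
#' rao_spacing_frequency_test(a, b, n_permutations = 999, seed = 1)
#' @export
rao_spacing_frequency_test <- function(s1, s2, n_permutations = 10000,
                                       seed = NULL) {
  a <- as_angles(s1); b <- as_angles(s2)
  if (length(a) < 2) {
    stop("the anchoring sample must contain at least 2 angles", call. = FALSE)
  }
  check_nperm(n_permutations)
  r <- perm_engine(a, b, n_permutations, seed, rsf = TRUE)
  new_test_result("Rsf", c(Rsf = unname(r$observed["Rsf"])),
                  (r$n_exceeding[["Rsf"]] + 1) / (n_permutations + 1),
                  "permutation", length(a), length(b),
                  as.integer(n_permutations),
                  as.integer(r$n_exceeding[["Rsf"]]), seed)
}

#' Run one of the six two-sample tests by name
#'
#' Dispatches to the test named by `name`: `"ART"` (geodesic-distance
#' permutation test), `"WU2"` / `"pWU2"` (Watson's U2, asymptotic /
#' permutation), `"WW"` / `"pWW"` (Watson-Wheeler, asymptotic / permutation),
#' `"Rsf"` (Rao spacing-frequencies permutation test).
#'
#' @param name One of `"ART"`, `"WU2"`, `"pWU2"`, `"WW"`, `"pWW"`, `"Rsf"`.
#' @inheritParams art_test
#' @return A `circart_test` object.
#' @examples
#' set.seed(5)
#' a <- sample_von_mises(0, 2, 10)
#' b <- sample_von_mises(pi, 2, 10)
#' run_test("ART", a, b, n_permutations = 999, seed = 1)
#' @export
run_test <- function(name, s1, s2, n_permutations = 10000, seed = NULL) {
  if (!is.character(name) || length(name) != 1L || !(name %in% TEST_NAMES)) {
    stop("unknown test `", paste(name, collapse = ","),
         "`; valid names: ", paste(TEST_NAMES, collapse = ", "), call. = FALSE)
  }
  switch(name,
    ART = art_test(s1, s2, n_permutations, seed),
    WU2 = watson_u2_test(s1, s2, method = "asymptotic"),
    pWU2 = watson_u2_test(s1, s2, method = "permutation",
                          n_permutations = n_permutations, seed = seed),
    WW = watson_wheeler_test(s1, s2, method = "asymptotic"),
    pWW = watson_wheeler_test(s1, s2, method = "permutation",
                              n_permutations = n_permutations, seed = seed),
    Rsf = rao_spacing_frequency_test(s1, s2, n_permutations, seed))
}
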