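# Exact test primitives. These are deliberately implemented from first
# principles (hypergeometric summation, permutation enumeration, labeling
# enumeration) so that small-sample p-values are exact and bit-reproducible;
# unit tests cross-check them against the independent base-R implementations
# and against brute-force oracles.

.perm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an (n! x n) integer matrix, cached per n.
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1L) matrix(1L) else {
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }))
  }
  storage.mode(p) <- "integer"
  .perm_cache[[key]] <- p
  p
}

# Exact two-sided permutation p-values for Spearman correlations, in batch.
# Xr: genes x n matrix of expression ranks; yr: fixed rank vector (stage
# ranks). For each row, p = fraction of the n! permutations of yr whose
# |rho| >= |rho_obs|. Ranks may contain ties (average ranks); rho is the
# Pearson correlation of ranks, which is linear in the permuted inner
# product, so the whole null distribution reduces to one matrix product.
spearman_exact_batch <- function(Xr, yr) {
  n <- length(yr)
  P <- all_permutations(n)
  Py <- matrix(yr[P], nrow(P), n)
  my <- mean(yr); sy <- stats::sd(yr)
  mx <- rowMeans(Xr)
  sx <- apply(Xr, 1L, stats::sd)
  p <- rep(NA_real_, nrow(Xr))
  ok <- which(sx > 0 & sy > 0)
  if (!length(ok)) return(p)
  chunk <- max(1L, floor(2e7 / nrow(P)))
  for (start in seq(1L, length(ok), by = chunk)) {
    idx <- ok[start:min(start + chunk - 1L, length(ok))]
    ip <- Py %*% t(Xr[idx, , drop = FALSE])          # n! x |idx|
    rho_perm <- sweep(sweep(ip, 2L, n * my * mx[idx], `-`),
                      2L, (n - 1) * sy * sx[idx], `/`)
    ip_obs <- as.vector(Xr[idx, , drop = FALSE] %*% yr)
    rho_obs <- (ip_obs - n * mx[idx] * my) / ((n - 1) * sx[idx] * sy)
    p[idx] <- vapply(seq_along(idx), function(j)
      mean(abs(rho_perm[, j]) >= abs(rho_obs[j]) - 1e-12), numeric(1L))
  }
  p
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of average ranks (ties handled). The
#' two-sided p-value is exact by full permutation enumeration for
#' n <= `exact_limit` observations and uses the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param exact_limit Largest n for exact enumeration (default 9).
#' @return A list: `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact_limit = 9L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  xr <- rank(x); yr <- rank(y)
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rho <- stats::cor(xr, yr)
  if (n <= exact_limit) {
    p <- spearman_exact_batch(matrix(xr, 1L), yr)[1L]
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tt <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = max(min(p, 1), .Machine$double.xmin), n = n,
       method = method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the conditional hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one; the conditional sample odds ratio is
#' (a d)/(b c), with a Haldane-corrected companion when a zero cell makes
#' the plain ratio degenerate.
#'
#' @param table 2x2 non-negative integer matrix (both margins positive).
#' @return A list: `odds_ratio`, `p`, `haldane` (logical, TRUE when a zero
#'   cell occurred), `odds_ratio_haldane`.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0), all(m == round(m)))
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  if (any(c(a + b, cc + d, a + cc, b + d) == 0))
    stop("both margins must be positive")
  k <- max(0, a + cc - (cc + d)):min(a + b, a + cc)
  probs <- stats::dhyper(k, a + b, cc + d, a + cc)
  p_obs <- stats::dhyper(a, a + b, cc + d, a + cc)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  zero <- any(m == 0)
  list(odds_ratio = (a * d) / (b * cc),
       p = min(p, 1),
       haldane = zero,
       odds_ratio_haldane = ((a + 0.5) * (d + 0.5)) /
         ((b + 0.5) * (cc + 0.5)))
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Exact two-sided p-value by full enumeration of the
#' choose(n1 + n2, n1) group labelings when the combined sample size is at
#' most `2 * exact_limit` (valid under ties, since the enumeration
#' conditions on the observed ranks); otherwise the normal approximation
#' with tie correction and continuity correction. The exact p is
#' min(1, 2 * min(P(W <= w), P(W >= w))) for the rank sum W of the first
#' sample.
#'
#' @param x,a Numeric samples.
#' @param exact_limit Half the largest combined sample size for exact
#'   enumeration (default 10: exact up to n1 + n2 = 20).
#' @return A list: `statistic` (Mann-Whitney U of `x`), `p`, `method`.
#' @export
ranksum_compare <- function(x, a, exact_limit = 10L) {
  stopifnot(length(x) >= 1L, length(a) >= 1L)
  n1 <- length(x); n2 <- length(a); n <- n1 + n2
  r <- rank(c(x, a))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (n <= 2L * exact_limit) {
    sums <- utils::combn(n, n1, FUN = function(idx) sum(r[idx]))
    p <- min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 == 0) return(list(statistic = u, p = 1, method = "degenerate"))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = u, p = p, method = method)
}
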