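#' Spearman rank correlation with exact permutation p-values
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (average
#' ranks for ties). The two-sided p-value is exact — computed by full
#' enumeration of all `n!` permutations of one rank vector — when
#' `n <= exact_limit`, and otherwise uses the t approximation with `n - 2`
#' degrees of freedom. A constant input gives an undefined rho; the result is
#' flagged (`method = "undefined"`, `rho = NA`) rather than raising, so batch
#' analyses over many proteins can proceed.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param exact_limit largest `n` at which the permutation null is fully
#'   enumerated (default 9).
#' @return one-row tibble with `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))
#' @export
spearman_test <- function(x, y, exact_limit = 9) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("spearman_test needs n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in spearman_test input", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    s <- as.vector(ryp %*% rx)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    method <- "t_approximation"
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}

# all n! permutations of 1..n as an n! x n integer matrix (row = permutation)
all_permutations <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1) out[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= ncol(out)) out[, pos:ncol(out), drop = FALSE]
      blocks[[pos]] <- cbind(left, matrix(k, nrow(out), 1), right)
    }
    out <- do.call(rbind, blocks)
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `after - before` are computed, zero differences dropped
#' (Wilcoxon's original treatment), absolute differences ranked with
#' mid-ranks for ties, and the statistic is the sum of ranks of positive
#' differences. The two-sided p-value (twice the smaller tail, capped at 1)
#' is exact for `n_effective <= exact_limit`, computed from the full
#' distribution over all `2^n` sign patterns (evaluated by convolution over
#' doubled ranks, which is integer-exact under ties); beyond that a normal
#' approximation with tie correction is used. If every difference is zero
#' the result is flagged degenerate.
#'
#' @param before,after paired numeric vectors.
#' @param exact_limit largest effective n for the exact distribution
#'   (default 25, so a 16-pair design is always exact).
#' @return one-row tibble with `statistic` (V, the positive-rank sum),
#'   `p_value`, `n_effective`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(6, 8, 9, 11, 12, 14))
#' @export
wilcoxon_signed_rank <- function(before, after, exact_limit = 25) {
  stopifnot(length(before) == length(after))
  d <- after - before
  if (any(!is.finite(d))) stop("non-finite paired differences", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = NA_real_, p_value = NA_real_, n_effective = 0L,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  tibble(statistic = v, p_value = p, n_effective = as.integer(n),
         method = method)
}

# exact two-sided p for the signed-rank statistic, mid-ranks allowed.
# Doubling the ranks makes them integers; the pmf over all 2^n sign patterns
# is built by convolution (each rank contributes 0 or its doubled value).
signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
    f <- g
  }
  f <- f / sum(f)
  v2 <- as.integer(round(2 * v))
  pl <- sum(f[seq_len(v2 + 1)])
  pg <- sum(f[(v2 + 1):(total + 1)])
  min(1, 2 * min(pl, pg))
}

#' Mann-Whitney U test for two independent groups
#'
#' Mid-rank U statistic for the first group. The two-sided p-value (twice
#' the smaller tail, capped at 1) is exact by enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings when `n_a + n_b <= exact_limit`,
#' otherwise a normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit largest combined n for exact enumeration (default 12).
#' @return one-row tibble with `statistic` (U for group `a`), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 20, 30))
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty (got ", length(a), " and ",
         length(b), ")", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) stop("non-finite values", call. = FALSE)
  na <- length(a)
  nb <- length(b)
  nn <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  u <- ra - na * (na + 1) / 2
  if (nn <= exact_limit) {
    idx <- combn(nn, na)
    rsums <- colSums(matrix(r[idx], nrow = na))
    pl <- mean(rsums <= ra + 1e-9)
    pg <- mean(rsums >= ra - 1e-9)
    p <- min(1, 2 * min(pl, pg))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      (nn + 1 - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  tibble(statistic = u, p_value = p, n_a = na, n_b = nb, method = method)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation of order statistics
#' (`stats::quantile()` type 7).
#'
#' @param values non-empty numeric vector.
#' @return one-row tibble with `median`, `q1`, `q3`, `iqr`.
#' @examples
#' median_iqr(c(51, 55, 59, 61, 62))
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}
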