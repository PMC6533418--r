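# Independent brute-force oracles for the exact nonparametric tests.
# These enumerate the null distributions directly from definitions and are
# deliberately written without reusing any package internals.

# two-sided exact signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- as.vector(signs %*% r)
  pl <- mean(v_all <= v_obs + 1e-9)
  pg <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# two-sided exact Mann-Whitney p by enumerating all group labelings;
# U computed by direct pairwise comparison of values, not via rank sums
oracle_mann_whitney_p <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  na <- length(a)
  u_of <- function(idx) {
    x <- v[idx]
    y <- v[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(na))
  u_all <- apply(combn(n, na), 2, u_of)
  pl <- mean(u_all <= u_obs + 1e-9)
  pg <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(pl, pg))
}

# full-permutation two-sided Spearman p; rho from base R
oracle_spearman_p <- function(x, y) {
  rho_obs <- cor(x, y, method = "spearman")
  perms <- permutations_of(length(y))
  rho_all <- apply(perms, 1, function(idx) cor(x, y[idx],
                                               method = "spearman"))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# iterative permutation generator (independent of the package's)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(smaller[, seq_len(pos - 1), drop = FALSE],
          n,
          if (pos <= n - 1) smaller[, pos:(n - 1), drop = FALSE])
  }))
}

# brute-force average-linkage agglomeration returning merge heights and the
# leaf sets of every internal node (order-free tree comparison)
oracle_average_linkage_sets <- function(dm) {
  labels <- rownames(dm)
  clusters <- as.list(labels)
  active <- rep(TRUE, length(clusters))
  sets <- list()
  heights <- numeric()
  dist_between <- function(c1, c2) mean(dm[c1, c2])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        d <- dist_between(clusters[[i]], clusters[[j]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    active[best[2]] <- FALSE
    sets[[length(sets) + 1]] <- merged
    heights <- c(heights, best_d)
  }
  list(sets = sets, heights = heights)
}

# plain numeric values of a staged matrix (class and stage stripped)
vals <- function(m) {
  m <- unclass(m)
  attr(m, "stage") <- NULL
  m
}
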