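# Independent brute-force oracles, deliberately written from first
# principles (not via the package's code paths).

# All permutations of 1..n by Heap's algorithm.
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  gen <- function(k) {
    if (k == 1L) {
      row <<- row + 1L
      out[row, ] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      gen(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  gen(n)
  out
}

# Exhaustive hypergeometric tails by enumerating every pair of presence
# sets (bitmask subsets of N samples), for N <= 10.
bruteforce_hypergeom <- function(N, a, b) {
  masks <- 0:(2^N - 1)
  pc <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(N - 1))) > 0),
               numeric(1))
  Ma <- masks[pc == a]
  Mb <- masks[pc == b]
  inter <- outer(Ma, Mb, bitwAnd)
  k_all <- matrix(pc[match(inter, masks)], nrow(inter))
  total <- length(k_all)
  function(k) c(p_co = sum(k_all >= k) / total,
                p_ex = sum(k_all <= k) / total)
}

# Exhaustive two-group ANOSIM by enumerating every assignment of group-A
# positions; recomputes R from its definition with fresh code.
bruteforce_anosim <- function(d, labels) {
  n <- nrow(d)
  stopifnot(length(unique(labels)) == 2)
  na <- sum(labels == unique(labels)[1])
  dv <- d[lower.tri(d)]
  rk <- rank(dv)
  M <- length(dv)
  pairs <- which(lower.tri(d), arr.ind = TRUE)
  stat <- function(is_a) {
    same <- is_a[pairs[, 1]] == is_a[pairs[, 2]]
    (mean(rk[!same]) - mean(rk[same])) / (M / 2)
  }
  obs <- stat(labels == unique(labels)[1])
  combos <- utils::combn(n, na)
  Rs <- apply(combos, 2, function(ix) {
    v <- rep(FALSE, n); v[ix] <- TRUE; stat(v)
  })
  list(R = obs, p = mean(Rs >= obs - 1e-12), null = Rs)
}

# Exhaustive two-sided Wilcoxon rank-sum p by enumerating every assignment
# of the pooled values to the two groups (no ties assumed).
bruteforce_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_of <- function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, u_of)
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Exhaustive two-sided permutation p for Spearman's rho over all n!
# shuffles of y.
bruteforce_spearman_perm <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  pearson <- function(u, v) {
    su <- (u - mean(u)) / stats::sd(u)
    sv <- (v - mean(v)) / stats::sd(v)
    sum(su * sv) / (length(u) - 1)
  }
  obs <- abs(pearson(rx, ry))
  perms <- heap_permutations(length(y))
  rho_all <- apply(perms, 1, function(p) abs(pearson(rx, ry[p])))
  mean(rho_all >= obs - 1e-12)
}

# Jaccard-network match helper: canonical unordered pair keys.
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")
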