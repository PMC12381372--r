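# Self-contained statistical primitives: exact/approximate Wilcoxon
# rank-sum, blocked permutation tests, and p-value adjustment.  These are
# implemented in the package (rather than wrapping stats::wilcox.test /
# stats::p.adjust) so that the permutation machinery, the exact small-n
# null, and the tie handling are a single auditable code path; the base-R
# routines serve as independent oracles in the test suite.

# Exact two-sided tail probability of the rank-sum statistic W (sum of the
# ranks of group x) under the null that the nx ranks are a uniformly random
# size-nx subset of 1..N.  Computed by dynamic programming over the count
# of subsets of each size and sum; two-sided by symmetry of the null:
# p = P(|W' - mu| >= |W - mu|).
ranksum_exact_p <- function(W, nx, N) {
  smax <- sum((N - nx + 1L):N)
  # dp[[j + 1]] is the count vector over sums (index s + 1) for subsets of
  # size j; doubles are exact well past any count reachable here relative
  # to the 1e-12 comparisons below.
  dp <- vector("list", nx + 1L)
  dp[[1L]] <- 1
  for (i in seq_len(N)) {
    for (j in seq(min(i, nx), 1L)) {
      prev <- dp[[j]]
      if (is.null(prev)) next
      shifted <- c(numeric(i), prev)
      cur <- dp[[j + 1L]] %||% numeric(0)
      n_out <- max(length(cur), length(shifted))
      out <- numeric(n_out)
      out[seq_along(cur)] <- cur
      out[seq_along(shifted)] <- out[seq_along(shifted)] + shifted
      dp[[j + 1L]] <- out
    }
  }
  counts <- dp[[nx + 1L]]
  s <- seq_along(counts) - 1
  mu <- nx * (N + 1) / 2
  sum(counts[abs(s - mu) >= abs(W - mu) - 1e-9]) / sum(counts)
}

#' Wilcoxon rank-sum test with exact small-sample null
#'
#' Two-sided rank-sum (Mann-Whitney) test. When the smaller group has at
#' most 10 observations and the pooled data contain no ties, the p-value is
#' computed by exact enumeration of the rank-sum null distribution;
#' otherwise a normal approximation with mid-ranks, the standard tie
#' correction and a continuity correction is used.
#'
#' @param x,y Numeric vectors of observations for the two groups.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact null;
#'   default `NULL` chooses exact when `min(n_x, n_y) <= 10` and there are
#'   no ties. Ties always fall back to the normal approximation.
#' @return A list of class `"rank_sum_test"` with elements `statistic`
#'   (the rank sum W of `x`), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_x` and `n_y`.
#' @examples
#' # complete separation of 4 vs 4 gives the smallest attainable p, 2/70
#' rank_sum_test(c(5, 6, 7, 8), c(1, 2, 3, 4))$p_value
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    abort_validation("rank_sum_test() requires at least one value per group")
  }
  if (anyNA(x) || anyNA(y)) {
    abort_validation("rank_sum_test() does not accept missing values")
  }
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- if (is.null(exact)) min(nx, ny) <= 10L && !ties else isTRUE(exact) && !ties

  if (use_exact) {
    p <- ranksum_exact_p(W, nx, N)
    method <- "exact"
  } else {
    mu <- nx * (N + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1 # all pooled values identical
    } else {
      z <- max(0, abs(W - mu) - 0.5) / sqrt(sigma2) # continuity-corrected
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal_approx"
  }
  structure(
    list(statistic = W, p_value = min(1, p), method = method,
         n_x = nx, n_y = ny),
    class = "rank_sum_test"
  )
}

# -- blocked permutation ---------------------------------------------------

# Keep only blocks that contain both groups (hence >= 2 units); returns the
# kept index vector, warning about what was dropped.
permutable_blocks <- function(groups, blocks) {
  keep_block <- tapply(groups, blocks, function(g) length(unique(g)) == 2L)
  dropped <- names(keep_block)[!keep_block]
  if (length(dropped)) {
    warn_mixo("dropping %d block(s) not spanning both groups: %s",
              length(dropped), paste(dropped, collapse = ", "))
  }
  which(as.character(blocks) %in% names(keep_block)[keep_block])
}

# Number of distinct within-block relabellings.
n_block_arrangements <- function(groups, blocks, level2) {
  sizes <- tapply(groups, blocks, length)
  k2 <- tapply(groups == level2, blocks, sum)
  prod(choose(as.numeric(sizes), as.numeric(k2)))
}

# Enumerate every within-block assignment of the level2 labels; returns a
# logical membership matrix (units x arrangements), TRUE = unit carries the
# level2 label in that arrangement.
enumerate_block_memberships <- function(groups, blocks, level2) {
  n <- length(groups)
  idx_by_block <- split(seq_len(n), blocks, drop = TRUE)
  choices <- lapply(idx_by_block, function(ix) {
    k2 <- sum(groups[ix] == level2)
    combn(length(ix), k2, function(sel) ix[sel], simplify = FALSE)
  })
  grid <- expand.grid(lapply(choices, seq_along), KEEP.OUT.ATTRS = FALSE)
  M <- matrix(FALSE, n, nrow(grid))
  for (a in seq_len(nrow(grid))) {
    sel <- unlist(mapply(function(ch, j) ch[[j]], choices, as.integer(grid[a, ]),
                         SIMPLIFY = FALSE), use.names = FALSE)
    M[sel, a] <- TRUE
  }
  M
}

# Monte Carlo membership matrix: each column is one random within-block
# relabelling (TRUE = level2).
sample_block_memberships <- function(groups, blocks, level2, n_perm) {
  n <- length(groups)
  idx_by_block <- split(seq_len(n), blocks, drop = TRUE)
  M <- matrix(FALSE, n, n_perm)
  for (ix in idx_by_block) {
    k2 <- sum(groups[ix] == level2)
    nb <- length(ix)
    if (k2 == 0L) next
    if (k2 == nb) {
      M[ix, ] <- TRUE
      next
    }
    u <- matrix(runif(nb * n_perm), nb, n_perm)
    sel <- apply(u, 2L, function(z) ix[order(z)[seq_len(k2)]])
    M[cbind(as.vector(sel), rep(seq_len(n_perm), each = k2))] <- TRUE
  }
  M
}

#' Blocked permutation test for a two-group mean difference
#'
#' Permutes group labels *within* blocks only, so block-level effects
#' (e.g. parent colony, tank) cannot masquerade as group effects. The test
#' statistic is the difference of group means, compared two-sided via its
#' absolute value. When the number of distinct within-block relabellings is
#' at most `exhaustive_limit` the null is enumerated exhaustively (the
#' seed is then ignored); otherwise `n_perm` Monte Carlo relabellings are
#' drawn and the add-one estimator `p = (1 + k) / (1 + n_perm)` is used,
#' so `p >= 1/(n_perm + 1)` and p can never be exactly zero.
#'
#' Blocks that do not contain both groups carry no information about the
#' contrast and are dropped with a warning.
#'
#' @param values Numeric response vector.
#' @param groups Two-level grouping vector/factor. The reported effect is
#'   `mean(second level) - mean(first level)`, with factor level order (or
#'   sort order for non-factors) defining which level is the reference.
#' @param blocks Blocking vector (e.g. colony, or colony x tank).
#' @param n_perm Number of Monte Carlo permutations (ignored when the null
#'   is enumerated exhaustively).
#' @param seed Optional integer seed for the Monte Carlo draw; the
#'   caller's RNG state is restored afterwards.
#' @param exhaustive_limit Enumerate exhaustively when the arrangement
#'   count is at most this value.
#' @return A list of class `"permutation_result"`: `observed_effect`,
#'   `p_value`, `n_permutations`, `exhaustive`, `seed`, `n_used`,
#'   `n_blocks_used`.
#' @export
blocked_permutation_test <- function(values, groups, blocks,
                                     n_perm = 9999L, seed = NULL,
                                     exhaustive_limit = 20000L) {
  res <- blocked_permutation_matrix(matrix(values, nrow = 1L), groups, blocks,
                                    n_perm = n_perm, seed = seed,
                                    exhaustive_limit = exhaustive_limit)
  structure(
    list(observed_effect = res$effects[[1L]],
         p_value = res$p_values[[1L]],
         n_permutations = res$n_permutations,
         exhaustive = res$exhaustive,
         seed = seed,
         n_used = res$n_used,
         n_blocks_used = res$n_blocks_used),
    class = "permutation_result"
  )
}

#' Blocked permutation tests for many variables sharing one design
#'
#' Vectorised form of [blocked_permutation_test()]: every row of `valmat`
#' is tested against the same group/block design, re-using a single set of
#' permutations. This is how per-fatty-acid treatment contrasts are
#' computed efficiently.
#'
#' @param valmat Numeric matrix, variables in rows, units in columns.
#' @inheritParams blocked_permutation_test
#' @return List with `effects` and `p_values` (one per row of `valmat`),
#'   plus `n_permutations`, `exhaustive`, `n_used`, `n_blocks_used`.
#' @export
blocked_permutation_matrix <- function(valmat, groups, blocks,
                                       n_perm = 9999L, seed = NULL,
                                       exhaustive_limit = 20000L) {
  valmat <- as.matrix(valmat)
  if (!is.numeric(valmat) || anyNA(valmat)) {
    abort_validation("`valmat` must be numeric with no missing values")
  }
  n <- ncol(valmat)
  if (length(groups) != n || length(blocks) != n) {
    abort_validation("`groups` and `blocks` must have one entry per unit")
  }
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2L) {
    abort_validation("`groups` must contain exactly two levels (got %d)",
                     nlevels(groups))
  }
  lv <- levels(groups)
  keep <- permutable_blocks(groups, blocks)
  if (!length(keep)) {
    abort_validation("no block spans both groups; nothing to permute")
  }
  g <- groups[keep]
  blk <- factor(blocks[keep])
  V <- valmat[, keep, drop = FALSE]

  n2 <- sum(g == lv[2L])
  n1 <- sum(g == lv[1L])
  rs <- rowSums(V)
  sum2 <- V %*% (g == lv[2L])
  obs <- as.vector(sum2 / n2 - (rs - sum2) / n1)

  total <- n_block_arrangements(g, blk, lv[2L])
  if (total <= exhaustive_limit) {
    M <- enumerate_block_memberships(g, blk, lv[2L])
    S2 <- V %*% M
    E <- S2 / n2 - (rs - S2) / n1
    exceed <- abs(E) >= abs(obs) - 1e-12
    p <- rowSums(exceed) / ncol(M)
    n_done <- ncol(M)
    exhaustive <- TRUE
  } else {
    M <- with_seed(seed, sample_block_memberships(g, blk, lv[2L], n_perm))
    S2 <- V %*% M
    E <- S2 / n2 - (rs - S2) / n1
    exceed <- abs(E) >= abs(obs) - 1e-12
    p <- (1 + rowSums(exceed)) / (1 + n_perm)
    n_done <- n_perm
    exhaustive <- FALSE
  }
  list(effects = obs, p_values = as.vector(p), n_permutations = n_done,
       exhaustive = exhaustive, n_used = length(keep),
       n_blocks_used = nlevels(blk))
}

#' Adjust p-values for multiple testing
#'
#' Step-down Holm and step-up Benjamini-Hochberg adjustments, implemented
#' directly (and oracle-tested against `stats::p.adjust`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"none"`, `"holm"`, `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_p <- function(p, method = c("none", "holm", "BH")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1] with no missing values")
  }
  n <- length(p)
  if (n == 0L || method == "none") return(p)
  out <- numeric(n)
  if (method == "holm") {
    o <- order(p)
    adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
    out[o] <- adj
  } else { # BH
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))
    out[o] <- adj
  }
  out
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s)\n", x$method))
  cat(sprintf("  W = %g (n = %d vs %d), two-sided p = %.5g\n",
              x$statistic, x$n_x, x$n_y, x$p_value))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Blocked permutation test (%s, %d permutations)\n",
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_permutations))
  cat(sprintf("  effect = %.4g, p = %.5g (n = %d in %d blocks)\n",
              x$observed_effect, x$p_value, x$n_used, x$n_blocks_used))
  invisible(x)
}
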