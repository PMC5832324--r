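## Cache of combination index matrices so repeated small exact tests
## (the common case: 4 vs 4) do not rebuild combn(N, n1) every call.
.combn_cache <- new.env(parent = emptyenv())
.get_combn <- function(N, n1) {
  key <- paste(N, n1, sep = "_")
  if (is.null(.combn_cache[[key]])) .combn_cache[[key]] <- combn(N, n1)
  .combn_cache[[key]]
}

## Distribution of the doubled rank-sum over size-n1 subsets of the doubled
## mid-rank scores, by the shift (convolution) recursion. Returns counts
## indexed by doubled sum 0..sum(s2).
.shift_distribution <- function(s2, n1) {
  maxs <- sum(s2)
  dp <- matrix(0, n1 + 1L, maxs + 1L)
  dp[1L, 1L] <- 1
  for (x in s2) {
    kmax <- n1  # shift rows top-down so each score is used at most once
    for (k in seq(kmax, 1L)) {
      if (x == 0L) dp[k + 1L, ] <- dp[k + 1L, ] + dp[k, ]
      else dp[k + 1L, (x + 1L):(maxs + 1L)] <-
          dp[k + 1L, (x + 1L):(maxs + 1L)] + dp[k, 1L:(maxs + 1L - x)]
    }
  }
  dp[n1 + 1L, ]
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided exact test on the conditional permutation distribution of the
#' rank-sum statistic given the observed mid-ranks (so ties are handled
#' exactly). The p-value is the probability that the rank sum deviates from
#' its null expectation at least as much as observed,
#' `P(|W - E0(W)| >= |w - E0(W)|)`. Full enumeration of all
#' `choose(n1+n2, n1)` group assignments is used when that count is at most
#' 200,000; otherwise the distribution is computed by the shift (recursive
#' convolution) algorithm on doubled mid-rank scores. Both routes give
#' identical p-values.
#'
#' @param x,y Numeric vectors (each of length >= 2, finite values).
#' @param method `"auto"` (default), or force `"enumeration"`/`"shift"`.
#' @return A list of class `pde_test` with elements `statistic` (rank sum of
#'   `x`), `p_two_sided`, `direction` (one of `first_greater`,
#'   `second_greater`, `none`; from mean ranks), and `method`.
#' @examples
#' wilcoxon_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))  # p = 2/70
#' @export
wilcoxon_exact <- function(x, y, method = c("auto", "enumeration", "shift")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 2L || n2 < 2L)
    stop("each group must have at least 2 values", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all values must be finite", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  dev <- abs(w - mu)
  if (method == "auto")
    method <- if (choose(N, n1) <= 2e5) "enumeration" else "shift"
  if (method == "enumeration") {
    idx <- .get_combn(N, n1)
    ws <- colSums(matrix(r[idx], nrow = n1))
    p <- sum(abs(ws - mu) >= dev - 1e-9) / ncol(idx)
  } else {
    s2 <- as.integer(round(2 * r))
    cnt <- .shift_distribution(s2, n1)
    sums <- (seq_along(cnt) - 1L) / 2  # back to rank-sum scale
    p <- sum(cnt[abs(sums - mu) >= dev - 1e-9]) / choose(N, n1)
  }
  mrx <- mean(r[seq_len(n1)]); mry <- mean(r[-seq_len(n1)])
  direction <- if (mrx == mry) "none" else
    if (mrx > mry) "first_greater" else "second_greater"
  structure(list(statistic = w, p_two_sided = p, direction = direction,
                 method = method), class = "pde_test")
}

#' @export
print.pde_test <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon rank-sum: W = %g, p = %.6g (%s), direction: %s\n",
              x$statistic, x$p_two_sided, x$method, x$direction))
  invisible(x)
}

#' Tie-corrected Kruskal-Wallis statistic
#'
#' `H = [12 / (N(N+1)) * sum(R_i^2 / n_i) - 3(N+1)] / (1 - sum(t^3 - t) /
#' (N^3 - N))` on mid-ranks, where `R_i` are group rank sums and `t` the tie
#' multiplicities. When every value is identical the statistic is defined
#' as 0.
#'
#' @param groups List of at least two numeric vectors (total N >= 3).
#' @return The H statistic (a single number).
#' @examples
#' kruskal_wallis_stat(list(c(1, 2), c(3, 4), c(5, 6)))  # 32/7
#' @export
kruskal_wallis_stat <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("each group needs at least 1 value", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(vals))) stop("all values must be finite", call. = FALSE)
  N <- length(vals)
  if (N < 3L) stop("need at least 3 values in total", call. = FALSE)
  r <- rank(vals)
  g <- rep(seq_along(groups), sizes)
  R <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  t <- table(vals)
  denom <- 1 - sum(t^3 - t) / (N^3 - N)
  if (denom <= 0) return(0)
  H / denom
}

## Number of ordered assignments of N values to groups of the given sizes.
.n_arrangements <- function(sizes) {
  round(exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))))
}

## All arrangements: recursively pick index sets per group; returns the
## count of arrangements with H >= h_obs (within tolerance).
.kw_enum_count <- function(vals, sizes, h_obs) {
  count <- 0
  rec <- function(remaining, gi, assigned) {
    if (gi > length(sizes)) {
      gl <- split(vals[unlist(assigned)],
                  rep(seq_along(sizes), sizes))
      if (kruskal_wallis_stat(gl) >= h_obs - 1e-9)
        count <<- count + 1
      return(invisible())
    }
    if (gi == length(sizes)) {
      rec(integer(0), gi + 1L, c(assigned, list(remaining)))
      return(invisible())
    }
    picks <- combn(length(remaining), sizes[gi])
    for (j in seq_len(ncol(picks))) {
      sel <- picks[, j]
      rec(remaining[-sel], gi + 1L, c(assigned, list(remaining[sel])))
    }
    invisible()
  }
  rec(seq_along(vals), 1L, list())
  count
}

#' Permutation p-value for the Kruskal-Wallis test
#'
#' Relabels values across groups (group sizes preserved). When the number of
#' distinct ordered arrangements is at most 100,000 the full enumeration is
#' used and the p-value is the exact proportion of arrangements with
#' `H >= H_obs`. Otherwise `B` Monte-Carlo permutations are drawn with the
#' add-one correction `p = (#{H* >= H_obs} + 1) / (B + 1)`, so the p-value
#' is never 0 (minimum `1/(B+1)`).
#'
#' @param groups List of numeric vectors.
#' @param B Number of Monte-Carlo permutations (>= 1).
#' @param seed Optional integer seed set before sampling.
#' @param method `"auto"` (default), or force `"enumeration"`/
#'   `"monte_carlo"`.
#' @return The p-value, with attributes `method` and (for Monte Carlo) `B`.
#' @examples
#' perm_pvalue(list(c(1, 2), c(3, 4), c(5, 6)), B = 1000)  # exact 6/90
#' @export
perm_pvalue <- function(groups, B = 1e6, seed = NULL,
                        method = c("auto", "enumeration", "monte_carlo")) {
  method <- match.arg(method)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  h_obs <- kruskal_wallis_stat(groups)
  sizes <- lengths(groups)
  vals <- unlist(groups, use.names = FALSE)
  if (method == "auto")
    method <- if (.n_arrangements(sizes) <= 1e5) "enumeration" else
      "monte_carlo"
  if (method == "enumeration") {
    cnt <- .kw_enum_count(vals, sizes, h_obs)
    p <- cnt / .n_arrangements(sizes)
    return(structure(p, method = "enumeration"))
  }
  if (!is.null(seed)) set.seed(seed)
  r <- rank(vals)
  g <- rep(seq_along(groups), sizes)
  t_obs <- sum(tapply(r, g, sum)^2 / sizes)  # monotone in H given the ranks
  cnt <- perm_kw_count(r, as.integer(sizes), as.integer(B), t_obs)
  structure((cnt + 1) / (B + 1), method = "monte_carlo", B = as.integer(B))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment (via [stats::p.adjust()]) and the rejection mask at
#' level `q`: reject iff the adjusted p-value is at most `q`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @return List with `adjusted` (BH-adjusted p-values, input order) and
#'   `reject` (logical mask). Empty input gives empty outputs.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)$reject
#' @export
bh_fdr <- function(pvals, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must be a single proportion in (0, 1)", call. = FALSE)
  if (length(pvals) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adjusted <- p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}
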