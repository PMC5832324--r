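#' Encode one pairwise comparison as a directional digit
#'
#' Runs the exact two-sided Wilcoxon rank-sum test between `a` and `b` and
#' encodes the outcome: `1` if the null `a = b` is not rejected
#' (`p > alpha`), `0` if rejected with `a`'s location above `b`'s
#' (downregulation when `a` is the reference), `2` if `b`'s location is
#' above `a`'s (upregulation). A rejection with exactly tied mean ranks is
#' impossible for the exact test (the p-value would be 1); this is asserted.
#'
#' @param a,b Numeric vectors of log2 expression values.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Integer digit 0, 1 or 2.
#' @examples
#' encode_comparison(c(1, 1.1, 0.9, 1.05), c(4, 4.2, 3.9, 4.1))  # 2
#' @export
encode_comparison <- function(a, b, alpha = 0.05) {
  tst <- wilcoxon_exact(a, b)
  if (tst$p_two_sided > alpha) return(1L)
  stopifnot(tst$direction != "none")
  if (tst$direction == "first_greater") 0L else 2L
}

#' Assign the three-digit response pattern for one gene
#'
#' The three comparisons are vehicle vs D3T (`vd`), vehicle vs 10 umol/kg
#' CDDO-Im (`vc`), and D3T vs CDDO-Im (`dc`). Each digit is 1 when the two
#' groups are not significantly different, 0 when the first exceeds the
#' second, and 2 when the second exceeds the first; e.g. `122` reads: D3T
#' equal to vehicle, CDDO-Im above vehicle and above D3T.
#'
#' @param groups Named list of numeric vectors with elements `V`, `D300`,
#'   and `C10`.
#' @param alpha Two-sided pairwise significance level.
#' @return List of class `pattern_code`: digits `vd`, `vc`, `dc`, the
#'   rendered `pattern` string, and `p` (the three exact p-values).
#' @export
assign_pattern <- function(groups, alpha = 0.05) {
  need <- c("V", "D300", "C10")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop(sprintf("missing group(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  t_vd <- wilcoxon_exact(groups$V, groups$D300)
  t_vc <- wilcoxon_exact(groups$V, groups$C10)
  t_dc <- wilcoxon_exact(groups$D300, groups$C10)
  dig <- function(tst) {
    if (tst$p_two_sided > alpha) return(1L)
    stopifnot(tst$direction != "none")
    if (tst$direction == "first_greater") 0L else 2L
  }
  vd <- dig(t_vd); vc <- dig(t_vc); dc <- dig(t_dc)
  structure(list(vd = vd, vc = vc, dc = dc,
                 pattern = paste0(vd, vc, dc),
                 p = c(vd = t_vd$p_two_sided, vc = t_vc$p_two_sided,
                       dc = t_dc$p_two_sided)),
            class = "pattern_code")
}

#' @export
print.pattern_code <- function(x, ...) {
  cat(sprintf("pattern %s (p: VD %.4g, VC %.4g, DC %.4g)\n",
              x$pattern, x$p["vd"], x$p["vc"], x$p["dc"]))
  invisible(x)
}

#' Collapse a pattern into its meta cluster
#'
#' Meta cluster 1 (common to both treatments) collects patterns `22x` and
#' `00x`; meta 2 (unique to D3T) `21x` and `01x`; meta 3 (unique to
#' CDDO-Im) `12x` and `10x`. Discordant responses (`20x`, `02x`) fall into
#' `opposite`, and `11x` into `concordant_only` (no response to either
#' treatment). The partition is exhaustive and disjoint over all 27 codes.
#'
#' @param pattern Character vector of three-digit codes (or a
#'   `pattern_code`).
#' @return Character vector over `"1"`, `"2"`, `"3"`, `"opposite"`,
#'   `"concordant_only"`.
#' @examples
#' meta_cluster(c("222", "210", "200", "111"))
#' @export
meta_cluster <- function(pattern) {
  if (inherits(pattern, "pattern_code")) pattern <- pattern$pattern
  vd <- substr(pattern, 1L, 1L)
  vc <- substr(pattern, 2L, 2L)
  key <- paste0(vd, vc)
  out <- rep(NA_character_, length(pattern))
  out[key %in% c("22", "00")] <- "1"
  out[key %in% c("21", "01")] <- "2"
  out[key %in% c("12", "10")] <- "3"
  out[key %in% c("20", "02")] <- "opposite"
  out[key == "11"] <- "concordant_only"
  if (anyNA(out))
    stop("invalid pattern code(s): ",
         paste(unique(pattern[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Resolve redundant probe sets of one gene
#'
#' When a gene is represented by several probe sets, the probe with the most
#' numbers of smallest pairwise-comparison p-values is retained: for each of
#' the three comparisons the probe(s) attaining the minimal p-value win that
#' comparison, and the probe with the most wins is kept. Ties are broken by
#' the smaller Kruskal-Wallis p-value, then by lexicographically smallest
#' probe id. The alternative reading of the selection rule - smallest sum of
#' the three p-values - is available as `rule = "min_sum"`.
#'
#' @param probe_ids Character vector of probe ids (>= 1).
#' @param pvals Numeric matrix, one row per probe, three columns of pairwise
#'   p-values (VD, VC, DC).
#' @param kw_p Optional numeric vector of Kruskal-Wallis p-values.
#' @param rule `"winner_count"` (default) or `"min_sum"`.
#' @return The retained probe id.
#' @export
resolve_redundant <- function(probe_ids, pvals, kw_p = NULL,
                              rule = c("winner_count", "min_sum")) {
  rule <- match.arg(rule)
  n <- length(probe_ids)
  if (n == 0L) stop("need at least one probe", call. = FALSE)
  if (n == 1L) return(probe_ids)
  pvals <- as.matrix(pvals)
  stopifnot(nrow(pvals) == n, ncol(pvals) == 3L)
  if (rule == "winner_count") {
    wins <- rowSums(vapply(seq_len(3L), function(j)
      pvals[, j] <= min(pvals[, j]) + 1e-12, logical(n)))
    cand <- which(wins == max(wins))
  } else {
    s <- rowSums(pvals)
    cand <- which(s <= min(s) + 1e-12)
  }
  if (length(cand) > 1L && !is.null(kw_p)) {
    k <- kw_p[cand]
    cand <- cand[k <= min(k) + 1e-12]
  }
  probe_ids[cand[order(probe_ids[cand])[1L]]]
}

#' Tabulate patterns into the cluster table
#'
#' Counts genes per three-digit pattern over all 27 possible codes
#' (unobserved codes count 0) and collapses the counts into the five meta
#' categories. Counts are conserved: the meta counts sum to the number of
#' genes.
#'
#' @param patterns Character vector of per-gene pattern codes (one per gene,
#'   after redundancy resolution).
#' @return An object of class `cluster_table`: a list with `counts` (data
#'   frame `pattern`, `n`, `meta` over all 27 codes) and `meta_counts`
#'   (named numeric over `1`, `2`, `3`, `opposite`, `concordant_only`).
#' @examples
#' tabulate_patterns(c("221", "221", "122", "111"))$meta_counts
#' @export
tabulate_patterns <- function(patterns) {
  digits <- c("0", "1", "2")
  all_codes <- as.vector(outer(outer(digits, digits, paste0), digits,
                               paste0))
  all_codes <- sort(all_codes)
  n <- as.integer(table(factor(patterns, levels = all_codes)))
  counts <- data.frame(pattern = all_codes, n = n,
                       meta = meta_cluster(all_codes),
                       stringsAsFactors = FALSE)
  meta_counts <- vapply(PDE_META_LEVELS, function(m)
    sum(counts$n[counts$meta == m]), numeric(1))
  structure(list(counts = counts, meta_counts = meta_counts),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  nz <- x$counts[x$counts$n > 0, ]
  cat(sprintf("Cluster table: %d genes in %d non-empty patterns\n",
              sum(x$counts$n), nrow(nz)))
  if (nrow(nz)) print(nz, row.names = FALSE)
  cat("Meta clusters:\n")
  print(x$meta_counts)
  invisible(x)
}
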