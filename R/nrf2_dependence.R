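#' Classify genotype (Nrf2) dependence of one gene's response
#'
#' A response is called Nrf2-dependent when either criterion holds:
#' \enumerate{
#'   \item significance: the exact two-sided Wilcoxon rank-sum p-value
#'     between the raw (log2) expression values of treated wild-type and
#'     treated knockout tissue is below `alpha`; or
#'   \item fold-change shift: the treatment fold change differs between the
#'     genotypes by at least `delta` (default 30%), read as a two-sided
#'     ratio criterion on linear fold changes: with
#'     `rho = 2^(log2FC_wt - log2FC_ko)`, dependent iff `rho >= 1 + delta`
#'     or `rho <= 1 / (1 + delta)`.
#' }
#' An absolute-difference reading of the shift criterion
#' (`|FC_wt - FC_ko| >= delta * |FC_wt|` on signed fold changes) is
#' available as `fc_rule = "absolute"`.
#'
#' @param wt_treated,ko_treated Numeric vectors of log2 expression in the
#'   matching treatment group of each genotype.
#' @param fc_wt,fc_ko Signed fold changes (treated vs vehicle) in each
#'   genotype, in the convention of [signed_fold_change()].
#' @param alpha Significance level for criterion 1.
#' @param delta Relative fold-change shift in (0, 1) for criterion 2.
#' @param fc_rule `"ratio"` (default) or `"absolute"`.
#' @return List of class `dependence_call`: `dependent`, `by_significance`,
#'   `by_fc_shift`, `p_wt_vs_ko`, `fc_wt`, `fc_ko`.
#' @examples
#' classify_dependence(c(10, 10.1, 9.9, 10), c(8, 8.1, 7.9, 8),
#'                     fc_wt = 4, fc_ko = 1)
#' @export
classify_dependence <- function(wt_treated, ko_treated, fc_wt, fc_ko,
                                alpha = 0.05, delta = 0.30,
                                fc_rule = c("ratio", "absolute")) {
  fc_rule <- match.arg(fc_rule)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    stop("'delta' must be a single proportion in (0, 1)", call. = FALSE)
  p <- wilcoxon_exact(wt_treated, ko_treated)$p_two_sided
  by_significance <- p < alpha
  if (fc_rule == "ratio") {
    rho <- 2^(.log2_from_signed(fc_wt) - .log2_from_signed(fc_ko))
    by_fc_shift <- rho >= 1 + delta || rho <= 1 / (1 + delta)
  } else {
    by_fc_shift <- abs(fc_wt - fc_ko) >= delta * abs(fc_wt)
  }
  structure(list(dependent = by_significance || by_fc_shift,
                 by_significance = by_significance,
                 by_fc_shift = by_fc_shift,
                 p_wt_vs_ko = p, fc_wt = fc_wt, fc_ko = fc_ko),
            class = "dependence_call")
}

#' @export
print.dependence_call <- function(x, ...) {
  cat(sprintf(
    "dependence: %s (significance: %s, fc shift: %s; p = %.4g, FC Wt %+.2f / KO %+.2f)\n",
    x$dependent, x$by_significance, x$by_fc_shift, x$p_wt_vs_ko,
    x$fc_wt, x$fc_ko))
  invisible(x)
}

#' Whole-percent dependence rate
#'
#' `round(100 * n_dependent / n_total)` to the nearest integer, half away
#' from zero - the rounding that reproduces every printed percentage of the
#' summary tables (e.g. 98/197 -> 50, 649/745 -> 87).
#'
#' @param n_dependent,n_total Counts with `0 <= n_dependent <= n_total`,
#'   `n_total > 0`.
#' @return Integer percent.
#' @export
dependence_rate <- function(n_dependent, n_total) {
  if (any(n_total <= 0)) stop("'n_total' must be positive", call. = FALSE)
  if (any(n_dependent < 0) || any(n_dependent > n_total))
    stop("'n_dependent' must lie in [0, n_total]", call. = FALSE)
  as.integer(floor(100 * n_dependent / n_total + 0.5))
}
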