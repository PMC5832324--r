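## signed linear fold change from a log2 difference: ratio r >= 1 maps to
## +r, r < 1 maps to -1/r, so |value| >= 1 always and equality gives +1.
.signed_from_log2 <- function(d) ifelse(d >= 0, 2^d, -(2^(-d)))

## inverse: log2 ratio from a signed fold change (+1 -> 0).
.log2_from_signed <- function(s) sign(s) * log2(abs(s))

#' Signed fold change between two groups
#'
#' Computes the linear expression ratio `r = 2^(mean(treat) - mean(ref))`
#' (a geometric-mean ratio, since values are log2) and renders it in the
#' signed display convention: `+r` for `r >= 1`, `-1/r` for `r < 1`. The
#' value is never inside the open interval (-1, 1) and equals +1 at exact
#' equality.
#'
#' @param treat,ref Non-empty numeric vectors of log2 expression values.
#' @return A single signed fold change.
#' @examples
#' signed_fold_change(c(9, 9), c(8, 8))   # +2
#' signed_fold_change(log2(0.7), 0)       # -1.43
#' @export
signed_fold_change <- function(treat, ref) {
  if (length(treat) == 0L || length(ref) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  .signed_from_log2(mean(treat) - mean(ref))
}

## Columns of the matrix belonging to one genotype x treatment group.
.group_cols <- function(ds, genotype, treatment) {
  ids <- ds$design$sample_id[ds$design$genotype == genotype &
                               ds$design$treatment == treatment]
  match(ids, colnames(ds$matrix))
}

#' Presence-call filter
#'
#' A probe set passes when at least `min_present` of its calls are `P`
#' within at least one wild-type treatment group. Significant-gene discovery
#' uses the wild-type arrays only; knockout data enter at the dependence
#' stage, so knockout calls never rescue a probe. Marginal (`M`) calls do
#' not count as present.
#'
#' @param ds An [expression_dataset()] with a calls grid.
#' @param min_present Minimum number of present calls (default 3).
#' @return Named logical vector over probes (`TRUE` = pass).
#' @export
presence_filter <- function(ds, min_present = 3L) {
  if (is.null(ds$calls))
    stop(paste("dataset has no presence calls; skip this filter explicitly",
               "if calls are unavailable"), call. = FALSE)
  pass <- rep(FALSE, nrow(ds$calls))
  for (tr in PDE_TREATMENTS) {
    cols <- .group_cols(ds, "Wt", tr)
    if (!length(cols)) next
    pass <- pass |
      rowSums(ds$calls[, cols, drop = FALSE] == "P") >= min_present
  }
  names(pass) <- rownames(ds$calls)
  pass
}

#' Fold-change filter
#'
#' A probe set passes when the absolute signed fold change of at least one
#' wild-type treated group (`D300`, `C3`, `C10`, `C30`) against the
#' wild-type vehicle reaches `threshold` (inclusive comparison), so
#' down-regulation counts through the absolute value.
#'
#' @param ds An [expression_dataset()].
#' @param threshold Linear fold-change threshold (default 1.5).
#' @return Named logical vector over probes (`TRUE` = pass).
#' @export
fc_filter <- function(ds, threshold = 1.5) {
  vcols <- .group_cols(ds, "Wt", "V")
  if (!length(vcols))
    stop("wild-type vehicle group missing", call. = FALSE)
  ref <- rowMeans(ds$matrix[, vcols, drop = FALSE])
  pass <- rep(FALSE, nrow(ds$matrix))
  for (tr in setdiff(PDE_TREATMENTS, "V")) {
    cols <- .group_cols(ds, "Wt", tr)
    if (!length(cols)) next
    d <- rowMeans(ds$matrix[, cols, drop = FALSE]) - ref
    pass <- pass | (2^abs(d) >= threshold)  # |signed FC| = 2^|log2 diff|
  }
  names(pass) <- rownames(ds$matrix)
  pass
}
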