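#' Pfaffl-method relative qPCR quantification
#'
#' Efficiency-corrected expression ratio
#' `E_target^dCt_target / E_ref^dCt_ref`, where each delta-Ct is oriented as
#' control minus sample so that induction gives a ratio above 1.
#' With both efficiencies equal to 2 this reduces to the familiar
#' 2^-ddCt value.
#'
#' @param e_target,e_ref Amplification efficiencies in `[1, 2]` (2 = perfect
#'   doubling per cycle).
#' @param dct_target,dct_ref Delta-Ct values (control - sample), in cycles.
#' @return Linear expression ratio(s); convert to the signed display
#'   convention with [signed_fold_change()] semantics if needed.
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)        # 2
#' pfaffl_ratio(1.9, 2, 2.0, 1)    # 1.805
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(e_target < 1 | e_target > 2) || any(e_ref < 1 | e_ref > 2))
    stop("amplification efficiencies must lie in [1, 2]", call. = FALSE)
  if (!all(is.finite(dct_target)) || !all(is.finite(dct_ref)))
    stop("delta-Ct values must be finite", call. = FALSE)
  e_target^dct_target / e_ref^dct_ref
}

#' Compute Pfaffl ratios from a qPCR table
#'
#' Reads a CSV with columns `gene`, `ct_control`, `ct_sample`,
#' `ref_ct_control`, `ref_ct_sample` and optional `e_target`, `e_ref`
#' (defaulting to 2 with a warning when absent, i.e. perfect efficiency)
#' and appends a `ratio` column.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the input columns plus `ratio`.
#' @export
read_qpcr_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "ct_control", "ct_sample", "ref_ct_control",
            "ref_ct_sample")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("'%s': missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(d$e_target) || is.null(d$e_ref)) {
    warning("amplification efficiencies absent; assuming perfect (E = 2)")
    if (is.null(d$e_target)) d$e_target <- 2
    if (is.null(d$e_ref)) d$e_ref <- 2
  }
  d$ratio <- pfaffl_ratio(d$e_target, d$ct_control - d$ct_sample,
                          d$e_ref, d$ref_ct_control - d$ref_ct_sample)
  d
}
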