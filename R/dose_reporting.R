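#' Dose of maximal response
#'
#' Returns the CDDO-Im dose (3, 10 or 30 umol/kg) at which the absolute
#' signed fold change is largest - induction and repression are compared on
#' magnitude. Exact ties resolve toward the lower dose.
#'
#' @param profile Numeric vector of three signed fold changes at doses C3,
#'   C10, C30 (in that order; names are ignored).
#' @return One of `"C3"`, `"C10"`, `"C30"`.
#' @examples
#' maximal_dose(c(-1.43, 12.84, 1.00))  # "C10"
#' @export
maximal_dose <- function(profile) {
  if (length(profile) != 3L || anyNA(profile))
    stop("profile must hold three signed fold changes (C3, C10, C30)",
         call. = FALSE)
  PDE_CDDO_DOSES[which.max(abs(profile))]
}

#' Count responders above a fold-change cutoff
#'
#' Counts values whose absolute signed fold change strictly exceeds
#' `cutoff` ("any level of response above the cutoff").
#'
#' @param fcs Numeric vector of signed fold changes.
#' @param cutoff Linear fold-change cutoff (>= 1; default 1.25).
#' @return Integer count.
#' @examples
#' responders_above(c(1.30, -1.26, 1.25, 1.10))  # 2
#' @export
responders_above <- function(fcs, cutoff = 1.25) {
  if (!is.numeric(cutoff) || cutoff < 1)
    stop("'cutoff' must be >= 1", call. = FALSE)
  sum(abs(fcs) > cutoff)
}

#' Summarize a pipeline run
#'
#' Renders the run's headline tables: the non-empty pattern clusters, the
#' meta-cluster table with whole-percent genotype-dependence rates (D3T
#' dependence for metas 1 and 2, CDDO-Im dependence for metas 1 and 3), and
#' the dose-maximal distribution of the CDDO-dependent meta-3 genes. All
#' percentages use the same rounding as [dependence_rate()]. An empty run
#' yields empty tables without division by zero.
#'
#' @param run A `pattern_run` from [run_pipeline()].
#' @return List of class `pattern_run_summary` with data frames `clusters`,
#'   `meta`, and `dose_maximal`.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pattern_run"))
  g <- run$genes
  ct <- run$cluster_table
  clusters <- ct$counts[ct$counts$n > 0, , drop = FALSE]

  meta <- data.frame(meta = PDE_META_LEVELS,
                     n = as.integer(ct$meta_counts),
                     pct_dependent_d3t = NA_integer_,
                     pct_dependent_cddo = NA_integer_,
                     stringsAsFactors = FALSE)
  if (nrow(g)) {
    for (m in c("1", "2")) {
      sel <- g$meta == m
      if (any(sel))
        meta$pct_dependent_d3t[meta$meta == m] <-
          dependence_rate(sum(g$dep_d3t[sel]), sum(sel))
    }
    for (m in c("1", "3")) {
      sel <- g$meta == m
      if (any(sel))
        meta$pct_dependent_cddo[meta$meta == m] <-
          dependence_rate(sum(g$dep_cddo[sel]), sum(sel))
    }
  }

  sel <- nrow(g) > 0 & g$meta == "3" & g$dep_cddo
  if (any(sel)) {
    tab <- table(factor(g$max_dose[sel], levels = PDE_CDDO_DOSES))
    dose_maximal <- data.frame(dose = PDE_CDDO_DOSES,
                               n = as.integer(tab),
                               pct = dependence_rate(as.integer(tab),
                                                     sum(tab)),
                               stringsAsFactors = FALSE)
  } else {
    dose_maximal <- data.frame(dose = character(0), n = integer(0),
                               pct = integer(0))
  }
  structure(list(clusters = clusters, meta = meta,
                 dose_maximal = dose_maximal),
            class = "pattern_run_summary")
}

#' @export
print.pattern_run_summary <- function(x, ...) {
  cat("Pattern clusters (non-empty):\n")
  print(x$clusters, row.names = FALSE)
  cat("\nMeta clusters (percent genotype-dependent):\n")
  print(x$meta, row.names = FALSE)
  cat("\nDose-maximal response of CDDO-dependent meta-3 genes:\n")
  if (nrow(x$dose_maximal)) print(x$dose_maximal, row.names = FALSE)
  else cat("  (none)\n")
  invisible(x)
}
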