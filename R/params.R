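#' Analysis parameters
#'
#' Bundles every threshold used by [run_pipeline()] with the conventional
#' defaults: a 1.5 linear fold-change screen, 5% FDR on the permutation
#' Kruskal-Wallis screen, two-sided pairwise alpha 0.05, a 30% fold-change
#' shift (and alpha 0.05) for the genotype-dependence call, a 1.25-fold
#' responder cutoff, at least three present calls in some wild-type
#' treatment group, and one million permutations.
#'
#' @param fc_threshold Linear fold-change threshold (>= 1) for the prefilter.
#' @param fdr_q FDR level for the Benjamini-Hochberg screen, in (0,1).
#' @param pairwise_alpha Two-sided alpha for the pairwise Wilcoxon encoding.
#' @param dependence_alpha Alpha for the Wt-vs-KO significance criterion.
#' @param dependence_delta Relative fold-change shift (in (0,1)) that calls a
#'   response genotype-dependent; 0.30 means a 30% increase or decrease.
#' @param responder_cutoff Linear fold change above which a gene counts as
#'   responding at all (strict comparison); >= 1.
#' @param min_present Minimum number of present ("P") calls required in at
#'   least one wild-type treatment group.
#' @param n_perm Number of Monte-Carlo permutations for the Kruskal-Wallis
#'   screen (full enumeration is used automatically when feasible).
#' @param seed Integer seed governing all randomness of a pipeline run.
#'
#' @return An object of class `analysis_params` (a validated list).
#' @examples
#' analysis_params(n_perm = 10000, seed = 1)
#' @export
analysis_params <- function(fc_threshold = 1.5,
                            fdr_q = 0.05,
                            pairwise_alpha = 0.05,
                            dependence_alpha = 0.05,
                            dependence_delta = 0.30,
                            responder_cutoff = 1.25,
                            min_present = 3,
                            n_perm = 1e6,
                            seed = 1L) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop(sprintf("'%s' must be a single proportion in (0, 1)", nm),
           call. = FALSE)
  }
  chk_prop(fdr_q, "fdr_q")
  chk_prop(pairwise_alpha, "pairwise_alpha")
  chk_prop(dependence_alpha, "dependence_alpha")
  chk_prop(dependence_delta, "dependence_delta")
  if (!is.numeric(fc_threshold) || fc_threshold < 1)
    stop("'fc_threshold' must be >= 1", call. = FALSE)
  if (!is.numeric(responder_cutoff) || responder_cutoff < 1)
    stop("'responder_cutoff' must be >= 1", call. = FALSE)
  if (!is.numeric(min_present) || min_present < 1)
    stop("'min_present' must be a positive count", call. = FALSE)
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("'n_perm' must be >= 1", call. = FALSE)
  structure(list(fc_threshold = as.numeric(fc_threshold),
                 fdr_q = as.numeric(fdr_q),
                 pairwise_alpha = as.numeric(pairwise_alpha),
                 dependence_alpha = as.numeric(dependence_alpha),
                 dependence_delta = as.numeric(dependence_delta),
                 responder_cutoff = as.numeric(responder_cutoff),
                 min_present = as.integer(min_present),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
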