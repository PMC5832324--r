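## Per-probe RNG substream seed: a deterministic mix of the run seed and the
## probe's row index in the full matrix, so results do not depend on the
## order (or partition) in which probes are evaluated. Kept below 2^31.
.probe_seed <- function(seed, idx) {
  as.integer((((as.double(seed) %% 65011) * 33029) + idx * 2411) %%
               2147483629) + 1L
}

#' Run the full pattern-clustering pipeline
#'
#' Stages, in fixed order, on the wild-type arrays: (1) presence-call filter
#' (at least `min_present` present calls in some treatment group; skipped
#' with a message when the dataset has no calls); (2) fold-change filter
#' against the vehicle; (3) permutation Kruskal-Wallis test across the five
#' treatment groups per surviving probe; (4) Benjamini-Hochberg FDR at
#' `fdr_q`; (5) three-digit pattern assignment (V, D300, C10) for the
#' FDR-significant probes; (6) extraction of the matching knockout values
#' and genotype-dependence classification per treatment (D3T at `D300`,
#' CDDO-Im at `C10`), plus the CDDO dose profile and dose-maximal class;
#' (7) redundancy resolution per annotated gene symbol (unannotated probes
#' are singleton genes); (8) tabulation into clusters and meta clusters.
#'
#' The run is deterministic given `params$seed`: each probe's Monte-Carlo
#' permutation stream is seeded from the run seed and the probe's row index.
#'
#' @param ds A valid [expression_dataset()] with both genotype arms.
#' @param params An [analysis_params()].
#' @return List of class `pattern_run`: `probes` (per-probe filter masks,
#'   Kruskal-Wallis statistics, permutation and adjusted p-values,
#'   significance), `genes` (per retained gene: digits, pattern, meta,
#'   fold changes, dependence calls, dose-maximal class), `cluster_table`,
#'   `summary` (see [summarize_run()]), and `params`.
#' @export
run_pipeline <- function(ds, params = analysis_params()) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(params, "analysis_params"))
  report <- validate_dataset(ds)
  if (length(report))
    stop("invalid dataset:\n  ", paste(report, collapse = "\n  "),
         call. = FALSE)

  m <- ds$matrix
  probe_ids <- rownames(m)
  cols <- lapply(PDE_GENOTYPES, function(g)
    lapply(setNames(PDE_TREATMENTS, PDE_TREATMENTS), function(tr)
      .group_cols(ds, g, tr)))
  names(cols) <- PDE_GENOTYPES

  ## stages 1-2: prefilters on Wt arrays
  if (!is.null(ds$calls)) {
    pass_presence <- presence_filter(ds, params$min_present)
  } else {
    message("no presence calls in dataset; presence filter skipped")
    pass_presence <- setNames(rep(TRUE, nrow(m)), probe_ids)
  }
  pass_fc <- fc_filter(ds, params$fc_threshold)
  tested <- pass_presence & pass_fc

  ## stages 3-4: permutation Kruskal-Wallis screen + FDR
  wt_groups <- function(i)
    lapply(cols$Wt, function(cc) m[i, cc])
  idx_tested <- which(tested)
  kw_stat <- kw_p <- rep(NA_real_, nrow(m))
  for (i in idx_tested) {
    gr <- wt_groups(i)
    kw_stat[i] <- kruskal_wallis_stat(gr)
    kw_p[i] <- perm_pvalue(gr, B = params$n_perm,
                           seed = .probe_seed(params$seed, i))
  }
  fdr_adj <- rep(NA_real_, nrow(m))
  significant <- rep(FALSE, nrow(m))
  if (length(idx_tested)) {
    bh <- bh_fdr(kw_p[idx_tested], params$fdr_q)
    fdr_adj[idx_tested] <- bh$adjusted
    significant[idx_tested] <- bh$reject
  }
  probes <- data.frame(probe_id = probe_ids,
                       pass_presence = unname(pass_presence),
                       pass_fc = unname(pass_fc),
                       tested = unname(tested),
                       kw_stat = kw_stat, kw_p = kw_p,
                       fdr_adj_p = fdr_adj,
                       significant = significant,
                       stringsAsFactors = FALSE)

  ## stages 5-6: patterns, fold changes, KO extraction, dependence, dose
  idx_sig <- which(significant)
  per_probe <- lapply(idx_sig, function(i) {
    wt <- lapply(cols$Wt, function(cc) m[i, cc])
    ko <- lapply(cols$KO, function(cc) m[i, cc])
    pat <- assign_pattern(wt[c("V", "D300", "C10")],
                          alpha = params$pairwise_alpha)
    fc_wt <- vapply(setdiff(PDE_TREATMENTS, "V"), function(tr)
      signed_fold_change(wt[[tr]], wt$V), numeric(1))
    fc_ko <- vapply(c("D300", "C10"), function(tr)
      signed_fold_change(ko[[tr]], ko$V), numeric(1))
    dep_d <- classify_dependence(wt$D300, ko$D300, fc_wt["D300"],
                                 fc_ko["D300"],
                                 alpha = params$dependence_alpha,
                                 delta = params$dependence_delta)
    dep_c <- classify_dependence(wt$C10, ko$C10, fc_wt["C10"],
                                 fc_ko["C10"],
                                 alpha = params$dependence_alpha,
                                 delta = params$dependence_delta)
    data.frame(probe_id = probe_ids[i],
               vd = pat$vd, vc = pat$vc, dc = pat$dc,
               pattern = pat$pattern,
               p_vd = pat$p["vd"], p_vc = pat$p["vc"], p_dc = pat$p["dc"],
               kw_p = kw_p[i],
               fc_d300 = fc_wt[["D300"]], fc_c3 = fc_wt[["C3"]],
               fc_c10 = fc_wt[["C10"]], fc_c30 = fc_wt[["C30"]],
               fc_ko_d300 = fc_ko[["D300"]], fc_ko_c10 = fc_ko[["C10"]],
               dep_d3t = dep_d$dependent, dep_cddo = dep_c$dependent,
               p_dep_d3t = dep_d$p_wt_vs_ko, p_dep_cddo = dep_c$p_wt_vs_ko,
               max_dose = maximal_dose(c(fc_wt[["C3"]], fc_wt[["C10"]],
                                         fc_wt[["C30"]])),
               stringsAsFactors = FALSE)
  })
  sig_tab <- if (length(per_probe)) do.call(rbind, per_probe) else
    data.frame()

  ## stage 7: redundancy resolution per gene symbol
  if (nrow(sig_tab)) {
    ann <- ds$annotation
    gene_of <- sig_tab$probe_id
    if (!is.null(ann)) {
      hit <- match(sig_tab$probe_id, ann$probe_id)
      gene_of <- ifelse(is.na(hit), sig_tab$probe_id, ann$gene_symbol[hit])
    }
    sig_tab$gene <- gene_of
    keep <- unlist(lapply(split(seq_len(nrow(sig_tab)), sig_tab$gene),
                          function(rows) {
      pid <- resolve_redundant(sig_tab$probe_id[rows],
                               as.matrix(sig_tab[rows, c("p_vd", "p_vc",
                                                         "p_dc")]),
                               kw_p = sig_tab$kw_p[rows])
      rows[sig_tab$probe_id[rows] == pid]
    }))
    genes <- sig_tab[sort(keep), , drop = FALSE]
    genes <- genes[c("gene", setdiff(names(genes), "gene"))]
    genes$meta <- meta_cluster(genes$pattern)
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene = character(0), probe_id = character(0),
                        pattern = character(0), meta = character(0),
                        dep_d3t = logical(0), dep_cddo = logical(0),
                        max_dose = character(0), stringsAsFactors = FALSE)
  }

  ## stage 8: tabulation
  cluster_table <- tabulate_patterns(genes$pattern)
  run <- structure(list(probes = probes, genes = genes,
                        cluster_table = cluster_table, params = params),
                   class = "pattern_run")
  run$summary <- summarize_run(run)
  run
}

#' @export
print.pattern_run <- function(x, ...) {
  cat(sprintf(
    "pattern_run: %d probes (%d tested, %d significant), %d genes retained\n\n",
    nrow(x$probes), sum(x$probes$tested), sum(x$probes$significant),
    nrow(x$genes)))
  print(x$summary)
  invisible(x)
}

#' Write a pipeline run to a directory
#'
#' Emits `probes.tsv`, `genes.tsv`, `cluster_table.tsv`, `meta_summary.tsv`,
#' `dose_maximal.tsv`, and a machine-readable `manifest.json` holding the
#' parameters and seed.
#'
#' @param run A `pattern_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pattern_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(run$probes, "probes.tsv")
  wt(run$genes, "genes.tsv")
  wt(run$cluster_table$counts, "cluster_table.tsv")
  wt(run$summary$meta, "meta_summary.tsv")
  wt(run$summary$dose_maximal, "dose_maximal.tsv")
  manifest <- c(unclass(run$params),
                list(package_version =
                       as.character(utils::packageVersion("patternDE"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
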