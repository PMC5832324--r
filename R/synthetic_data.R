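#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' 2 genotype x 5 treatment x 4 replicate design, planted response classes,
#' genotype-dependent effect attenuation, replicate noise on the log2 scale,
#' redundant probe sets per gene, and hard-threshold presence calls.
#'
#' Classes and their planted wild-type effects (log2 shifts from baseline):
#' \describe{
#'   \item{null}{no shift anywhere (pattern `111`).}
#'   \item{common_up / common_down}{`D300` and `C10` shifted by
#'     +/- `effect_log2` (patterns `221` / `001`).}
#'   \item{d3t_unique_up}{only `D300` shifted (+, pattern `210`).}
#'   \item{cddo_unique_up}{`C3`, `C10`, `C30` shifted by
#'     `effect_log2 * dose_profile` (pattern `122`).}
#'   \item{opposite}{`D300` up, `C10` down (pattern `200`).}
#' }
#' Genes flagged genotype-dependent carry zero planted effect in `KO`.
#'
#' @param n_genes Number of genes.
#' @param prob_second_probe Probability that a gene is represented by a
#'   second, redundant probe set (default 0.2; otherwise one probe).
#' @param class_fractions Named fractions over the six classes, summing to 1.
#' @param effect_log2 Planted log2 effect per responding treatment.
#' @param dose_profile Relative CDDO-Im effect at (C3, C10, C30); the
#'   default (0.3, 1.0, 0.6) peaks at the middle dose, mirroring the
#'   observed dose-maximal behaviour of most CDDO-responsive genes.
#' @param dependence_fraction Fraction of responding genes whose effect is
#'   abolished in the knockout.
#' @param sigma_log2 Replicate noise standard deviation (log2 scale).
#' @param baseline_log2_range Interval for uniform gene baselines.
#' @param presence_threshold_log2 Values at or above this level are called
#'   present (`P`), below it absent (`A`) - a deliberate simplification of
#'   MAS5 detection calls.
#' @param seed Integer seed; identical configs generate identical data.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              prob_second_probe = 0.2,
                              class_fractions = c(null = 0.50,
                                                  common_up = 0.15,
                                                  common_down = 0.10,
                                                  d3t_unique_up = 0.10,
                                                  cddo_unique_up = 0.10,
                                                  opposite = 0.05),
                              effect_log2 = 2.0,
                              dose_profile = c(C3 = 0.3, C10 = 1.0,
                                               C30 = 0.6),
                              dependence_fraction = 0.8,
                              sigma_log2 = 0.25,
                              baseline_log2_range = c(4, 12),
                              presence_threshold_log2 = 5.0,
                              seed = 1L) {
  fr <- rep(0, length(PDE_CLASSES))
  names(fr) <- PDE_CLASSES
  bad <- setdiff(names(class_fractions), PDE_CLASSES)
  if (length(bad))
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  fr[names(class_fractions)] <- class_fractions
  if (abs(sum(fr) - 1) > 1e-12)
    stop("class_fractions must sum to 1", call. = FALSE)
  if (any(fr < 0)) stop("class_fractions must be non-negative", call. = FALSE)
  if (sigma_log2 <= 0) stop("sigma_log2 must be > 0", call. = FALSE)
  if (any(dose_profile < 0)) stop("dose_profile must be >= 0", call. = FALSE)
  if (length(dose_profile) != 3L)
    stop("dose_profile must give relative effects at C3, C10, C30",
         call. = FALSE)
  names(dose_profile) <- PDE_CDDO_DOSES
  structure(list(n_genes = as.integer(n_genes),
                 prob_second_probe = prob_second_probe,
                 class_fractions = fr,
                 effect_log2 = effect_log2,
                 dose_profile = dose_profile,
                 dependence_fraction = dependence_fraction,
                 sigma_log2 = sigma_log2,
                 baseline_log2_range = baseline_log2_range,
                 presence_threshold_log2 = presence_threshold_log2,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Deterministic largest-remainder allocation so truth counts are exact.
.largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

## True pattern code per class under the planted effect directions.
.true_pattern <- function(class) {
  c(null = "111", common_up = "221", common_down = "001",
    d3t_unique_up = "210", cddo_unique_up = "122", opposite = "200")[class]
}

#' Planted group means for one gene
#'
#' Returns the genotype x treatment grid of planted log2 means for a gene of
#' the given class: vehicle equals the baseline in both genotypes; treated
#' groups carry the class-specific shifts in the wild type, and either the
#' same shifts (independent gene) or none (dependent gene) in the knockout.
#'
#' @param class One of the class labels of [simulation_config()].
#' @param baseline Baseline log2 expression.
#' @param cfg A `simulation_config`.
#' @param dependent Whether the gene's response requires the intact genotype
#'   (knockout means collapse to baseline).
#' @return Numeric matrix with rows `Wt`, `KO` and columns `V`, `D300`,
#'   `C3`, `C10`, `C30`.
#' @examples
#' cfg <- simulation_config()
#' planted_group_means("cddo_unique_up", 8, cfg)
#' @export
planted_group_means <- function(class, baseline, cfg, dependent = TRUE) {
  if (!class %in% PDE_CLASSES)
    stop(sprintf("unknown class '%s'", class), call. = FALSE)
  e <- cfg$effect_log2
  shift <- setNames(numeric(5L), PDE_TREATMENTS)
  if (class == "common_up") shift[c("D300", "C10")] <- e
  if (class == "common_down") shift[c("D300", "C10")] <- -e
  if (class == "d3t_unique_up") shift["D300"] <- e
  if (class == "cddo_unique_up")
    shift[PDE_CDDO_DOSES] <- e * cfg$dose_profile
  if (class == "opposite") shift[c("D300", "C10")] <- c(e, -e)
  wt <- baseline + shift
  ko <- if (dependent) rep(baseline, 5L) else wt
  m <- rbind(Wt = wt, KO = ko)
  colnames(m) <- PDE_TREATMENTS
  m
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws gene classes by deterministic largest-remainder allocation (then
#' shuffles their order), uniform baselines, genotype-dependence flags,
#' redundant probe sets, and i.i.d. Gaussian replicate noise on the log2
#' scale. Presence calls are `P` wherever the value reaches the configured
#' threshold. Identical `(cfg, seed)` give bit-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return A list with components `dataset` (an [expression_dataset()] with
#'   calls and annotation) and `truth` (data frame: `gene`, `class`,
#'   `pattern`, `dependent`, `meta`).
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 20, seed = 1))
#' table(sim$truth$class)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  counts <- .largest_remainder(cfg$class_fractions, n)
  classes <- sample(rep(PDE_CLASSES, counts))
  genes <- sprintf("GENE%05d", seq_len(n))
  baselines <- runif(n, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  dependent <- logical(n)
  responding <- classes != "null"
  dependent[responding] <-
    runif(sum(responding)) < cfg$dependence_fraction
  n_probes <- 1L + rbinom(n, 1L, cfg$prob_second_probe)

  design <- expand.grid(replicate = 1:4, treatment = PDE_TREATMENTS,
                        genotype = PDE_GENOTYPES, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%d", design$genotype, design$treatment,
                              design$replicate)
  design <- design[c("sample_id", "genotype", "treatment", "replicate")]

  ## per-gene 10-cell mean grid, expanded to samples then probes
  mean_rows <- t(vapply(seq_len(n), function(i) {
    g <- planted_group_means(classes[i], baselines[i], cfg, dependent[i])
    g[cbind(design$genotype, design$treatment)]
  }, numeric(nrow(design))))

  probe_gene <- rep(seq_len(n), n_probes)
  probe_ids <- sprintf("sp%05d_%s_at", probe_gene,
                       unlist(lapply(n_probes, function(k) letters[seq_len(k)])))
  mu <- mean_rows[probe_gene, , drop = FALSE]
  m <- mu + rnorm(length(mu), 0, cfg$sigma_log2)
  dimnames(m) <- list(probe_ids, design$sample_id)

  calls <- ifelse(m >= cfg$presence_threshold_log2, "P", "A")
  dimnames(calls) <- dimnames(m)

  annotation <- data.frame(probe_id = probe_ids,
                           gene_symbol = genes[probe_gene],
                           stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, class = classes,
                      pattern = unname(.true_pattern(classes)),
                      dependent = dependent,
                      meta = meta_cluster(unname(.true_pattern(classes))),
                      stringsAsFactors = FALSE)
  list(dataset = expression_dataset(m, design, calls, annotation),
       truth = truth)
}
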