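# Shared in-code fixtures for the test suite.

# A minimal valid dataset: `n` probes over the full 2 genotype x 5 treatment
# x 2 replicate grid, flat expression unless a shift matrix is supplied.
make_toy_dataset <- function(n = 3, reps = 2, seed = 1, calls = TRUE) {
  set.seed(seed)
  design <- expand.grid(replicate = seq_len(reps),
                        treatment = c("V", "D300", "C3", "C10", "C30"),
                        genotype = c("Wt", "KO"), stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_%d", design$genotype, design$treatment,
                              design$replicate)
  design <- design[c("sample_id", "genotype", "treatment", "replicate")]
  m <- matrix(rnorm(n * nrow(design), 8, 0.2), n, nrow(design),
              dimnames = list(sprintf("probe%02d", seq_len(n)),
                              design$sample_id))
  cl <- NULL
  if (calls) {
    cl <- matrix("P", n, nrow(design), dimnames = dimnames(m))
  }
  expression_dataset(m, design, cl)
}

# Per-gene group values with the study's 4 replicates, for pattern tests.
make_groups <- function(v = 8, d = 8, c = 8, sd = 0.1, seed = 1) {
  set.seed(seed)
  list(V = rnorm(4, v, sd), D300 = rnorm(4, d, sd), C10 = rnorm(4, c, sd))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "patternDE", mustWork = TRUE)
}
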