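#' Assemble an expression dataset
#'
#' The central data container: a log2 expression matrix (probe sets x
#' samples), a sample design table, and optionally a presence-call grid and
#' a probe-to-gene annotation. Genotypes are `Wt`/`KO`; treatments are the
#' vehicle and four treated groups `V`, `D300` (300 umol/kg D3T) and `C3`,
#' `C10`, `C30` (3/10/30 umol/kg CDDO-Im).
#'
#' @param matrix Numeric matrix of log2 expression values with probe-set row
#'   names and sample-id column names.
#' @param design Data frame with columns `sample_id`, `genotype`,
#'   `treatment`, `replicate` (see [read_design()]).
#' @param calls Optional character matrix over `P`/`M`/`A` with the same
#'   dimnames as `matrix`.
#' @param annotation Optional data frame with columns `probe_id`,
#'   `gene_symbol`.
#' @param validate If `TRUE` (default) the invariants are checked and any
#'   violation aborts; set `FALSE` to assemble a dataset for later
#'   inspection with [validate_dataset()].
#'
#' @return An object of class `ExpressionDataset`.
#' @seealso [validate_dataset()], [read_expression_matrix()], [read_design()]
#' @export
expression_dataset <- function(matrix, design, calls = NULL,
                               annotation = NULL, validate = TRUE) {
  ds <- structure(list(matrix = matrix, design = design, calls = calls,
                       annotation = annotation),
                  class = "ExpressionDataset")
  if (validate) {
    report <- validate_dataset(ds)
    if (length(report))
      stop("invalid ExpressionDataset:\n  ",
           paste(report, collapse = "\n  "), call. = FALSE)
  }
  ds
}

#' Validate an expression dataset
#'
#' Pure check of the container invariants: sample labels of the matrix and
#' design must match one-to-one, every genotype x treatment cell must hold at
#' least one replicate, expression values must be finite, and the call grid
#' (when present) must mirror the matrix exactly.
#'
#' @param ds An `ExpressionDataset` (possibly assembled with
#'   `validate = FALSE`).
#' @return Character vector of violations; `character(0)` iff valid.
#' @export
validate_dataset <- function(ds) {
  out <- character(0)
  m <- ds$matrix
  if (!is.matrix(m) || !is.numeric(m)) {
    return("'matrix' must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    out <- c(out, "'matrix' must carry probe row names and sample column names")
  if (anyDuplicated(rownames(m)))
    out <- c(out, sprintf("duplicate probe_id: %s",
                          paste(unique(rownames(m)[duplicated(rownames(m))]),
                                collapse = ", ")))
  if (!all(is.finite(m)))
    out <- c(out, "non-finite expression values present")

  d <- ds$design
  need <- c("sample_id", "genotype", "treatment", "replicate")
  if (!is.data.frame(d) || !all(need %in% names(d))) {
    out <- c(out, paste("'design' must contain columns",
                        paste(need, collapse = ", ")))
    return(out)
  }
  bad_g <- setdiff(unique(as.character(d$genotype)), PDE_GENOTYPES)
  if (length(bad_g))
    out <- c(out, sprintf("unknown genotype label(s): %s (allowed: %s)",
                          paste(bad_g, collapse = ", "),
                          paste(PDE_GENOTYPES, collapse = ", ")))
  bad_t <- setdiff(unique(as.character(d$treatment)), PDE_TREATMENTS)
  if (length(bad_t))
    out <- c(out, sprintf("unknown treatment label(s): %s (allowed: %s)",
                          paste(bad_t, collapse = ", "),
                          paste(PDE_TREATMENTS, collapse = ", ")))

  extra <- setdiff(colnames(m), d$sample_id)
  if (length(extra))
    out <- c(out, sprintf("matrix sample(s) absent from design: %s",
                          paste(extra, collapse = ", ")))
  missing <- setdiff(d$sample_id, colnames(m))
  if (length(missing))
    out <- c(out, sprintf("design sample(s) absent from matrix: %s",
                          paste(missing, collapse = ", ")))
  if (anyDuplicated(d$sample_id))
    out <- c(out, "duplicate sample_id in design")

  if (!length(bad_g) && !length(bad_t)) {
    cells <- table(factor(d$genotype, PDE_GENOTYPES),
                   factor(d$treatment, PDE_TREATMENTS))
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      out <- c(out, sprintf("empty design cell(s): %s",
                            paste(PDE_GENOTYPES[empty[, 1]],
                                  PDE_TREATMENTS[empty[, 2]],
                                  sep = ":", collapse = ", ")))
    }
  }

  if (!is.null(ds$calls)) {
    cl <- ds$calls
    if (!identical(dim(cl), dim(m)) ||
        !identical(dimnames(cl), dimnames(m))) {
      out <- c(out, "calls grid shape or labels differ from the matrix")
    } else if (!all(cl %in% PDE_CALLS)) {
      out <- c(out, "calls grid contains values outside {P, M, A}")
    }
  }
  if (!is.null(ds$annotation)) {
    a <- ds$annotation
    if (!is.data.frame(a) || !all(c("probe_id", "gene_symbol") %in% names(a)))
      out <- c(out, "'annotation' must contain columns probe_id, gene_symbol")
  }
  out
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d probe sets x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  presence calls: %s; annotation: %s\n",
              if (is.null(x$calls)) "absent" else "present",
              if (is.null(x$annotation)) "absent" else
                sprintf("%d probes", nrow(x$annotation))))
  invisible(x)
}

## Shared reader for tab-delimited probe x sample grids.
.read_grid <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 2L)
    stop(sprintf("'%s': no data rows", path), call. = FALSE)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("'%s': row %d has %d fields, expected %d",
                 path, bad[1L], nf[bad[1L]], nf[1L]), call. = FALSE)
  dat <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    comment.char = "")
  ids <- dat[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("'%s': duplicate probe_id: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  vals <- as.matrix(dat[, -1L, drop = FALSE])
  rownames(vals) <- ids
  vals
}

#' Read a tab-delimited expression matrix
#'
#' First column holds probe-set identifiers, the header row holds sample
#' ids; the remaining cells are expression values. Row and column order is
#' preserved. Ragged rows, non-numeric cells, and duplicate probe ids are
#' rejected with messages naming the offender.
#'
#' @param path Path to the TSV file.
#' @param log2_input If `TRUE` (default) values are taken to be on the log2
#'   scale already; if `FALSE`, positive linear intensities are log2
#'   transformed on ingestion.
#' @return Numeric matrix with probe row names and sample column names.
#' @export
read_expression_matrix <- function(path, log2_input = TRUE) {
  chr <- .read_grid(path)
  m <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr),
                               dimnames = dimnames(chr)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("'%s': non-numeric value '%s' at probe '%s', sample '%s'",
                 path, chr[bad[1L], bad[2L]], rownames(m)[bad[1L]],
                 colnames(m)[bad[2L]]), call. = FALSE)
  }
  if (!log2_input) {
    if (any(m <= 0))
      stop("linear-scale input must be strictly positive for log2 transform",
           call. = FALSE)
    m <- log2(m)
  }
  m
}

#' Read a presence-call grid
#'
#' Same layout as [read_expression_matrix()] but cells must be detection
#' calls `P` (present), `M` (marginal) or `A` (absent).
#'
#' @param path Path to the TSV file.
#' @return Character matrix of calls.
#' @export
read_presence_calls <- function(path) {
  cl <- .read_grid(path)
  bad <- !(cl %in% PDE_CALLS)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("'%s': invalid call '%s' (allowed: %s)", path, cl[i],
                 paste(PDE_CALLS, collapse = ", ")), call. = FALSE)
  }
  cl
}

#' Read a sample design table
#'
#' CSV with columns `sample_id`, `genotype`, `treatment`, `replicate`.
#' Genotype and treatment labels are validated against the controlled
#' vocabularies (`Wt`/`KO`; `V`, `D300`, `C3`, `C10`, `C30`).
#'
#' @param path Path to the CSV file.
#' @return Data frame with validated columns.
#' @export
read_design <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    stop(sprintf("'%s': no samples", path), call. = FALSE)
  need <- c("sample_id", "genotype", "treatment", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("'%s': missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad_g <- setdiff(unique(d$genotype), PDE_GENOTYPES)
  if (length(bad_g))
    stop(sprintf("unknown genotype label(s): %s (allowed: %s)",
                 paste(bad_g, collapse = ", "),
                 paste(PDE_GENOTYPES, collapse = ", ")), call. = FALSE)
  bad_t <- setdiff(unique(d$treatment), PDE_TREATMENTS)
  if (length(bad_t))
    stop(sprintf("unknown treatment label(s): %s (allowed: %s)",
                 paste(bad_t, collapse = ", "),
                 paste(PDE_TREATMENTS, collapse = ", ")), call. = FALSE)
  d$replicate <- as.integer(d$replicate)
  d[need]
}

#' Read a probe-to-gene annotation
#'
#' Two-column TSV (`probe_id`, `gene_symbol`). Probes absent from the
#' annotation are later treated as singleton genes.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `probe_id` and `gene_symbol`.
#' @export
read_annotation <- function(path) {
  a <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(a)))
    stop(sprintf("'%s': expected columns probe_id, gene_symbol", path),
         call. = FALSE)
  a[c("probe_id", "gene_symbol")]
}

#' Write the dataset components back to disk
#'
#' Inverse of the readers: matrix and calls as TSV, design as CSV,
#' annotation as TSV. Round-trips are lossless for labels and values to
#' full printed precision (values are written with 15 significant digits).
#'
#' @param x Matrix (expression or calls) or data frame (design/annotation).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
write_presence_calls <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
write_design <- function(x, path) {
  write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
write_annotation <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
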