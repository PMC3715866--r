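#' Construct a gene-by-sample expression matrix
#'
#' A numeric matrix with genes as rows and samples as columns, plus a
#' per-sample dataset label identifying the platform or cohort the sample
#' came from. The label is what downstream combination and batch-aware
#' analyses key on.
#'
#' @param values Numeric matrix with unique rownames (genes) and unique
#'   colnames (samples).
#' @param dataset A single label applied to every sample, or a per-sample
#'   character vector of length `ncol(values)`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, dataset = "dataset1") {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene symbols in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample identifiers in expression matrix")
  }
  if (length(dataset) == 1) dataset <- rep(dataset, ncol(values))
  if (length(dataset) != ncol(values)) {
    abort("dataset labels must match the number of samples")
  }
  structure(list(values = values,
                 dataset = setNames(as.character(dataset), colnames(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (datasets: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$dataset), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' First column is the gene symbol; remaining columns are samples.
#'
#' @param path Path to the TSV file.
#' @param dataset Dataset/platform label to attach to all samples.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, dataset = "dataset1") {
  x <- read_tsv_strict(path)
  genes <- as.character(x[[1]])
  values <- as.matrix(x[-1])
  rownames(values) <- genes
  expr_matrix(values, dataset)
}

#' Write an expression matrix as TSV
#' @param em An `expr_matrix`.
#' @param path Output TSV path.
#' @export
write_expression <- function(em, path) {
  stopifnot(is(em, "expr_matrix"))
  out <- as_tibble(em$values)
  out <- cbind(tibble(gene = rownames(em$values)), out)
  readr::write_tsv(as_tibble(out), path)
  invisible(path)
}
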