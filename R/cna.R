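#' Fraction genome altered
#'
#' For each sample, the ratio of the summed lengths of segments whose
#' absolute log2 copy ratio exceeds the threshold to the summed length of
#' all segments:
#' \deqn{FGA = \sum_i L(i)\,[\,|CN_i| > T\,] / \sum_i L(i)}
#' Both gains and losses count as alterations; the inequality is strict, so
#' a segment sitting exactly at the threshold is unaltered. Segment lengths
#' are base-pair lengths under the 1-based closed convention
#' (`end - start + 1`).
#'
#' The threshold is platform- and purity-dependent: 0.2 is appropriate for
#' tumour samples (signal attenuated by stromal contamination and
#' heterogeneity), 0.3 for pure cell lines.
#'
#' @param segments A `cn_segments` tibble (one or more samples).
#' @param threshold Positive log2-ratio threshold `T`.
#' @return A tibble with columns `sample` and `fga`.
#' @export
fraction_genome_altered <- function(segments, threshold) {
  segments <- cn_segments(segments)
  if (nrow(segments) == 0) abort("empty segment profile")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("threshold must be a single positive number")
  }
  len <- segments$end - segments$start + 1
  altered <- abs(segments$seg_mean) > threshold
  tibble(sample = segments$sample, len = len, altered = altered) |>
    group_by(.data$sample) |>
    summarise(fga = sum(.data$len[.data$altered]) / sum(.data$len),
              .groups = "drop")
}

#' Map segmented copy number to gene-level values
#'
#' For every gene and sample, the gene's copy-number value is the
#' segment-length-weighted mean of `seg_mean` over all segments overlapping
#' the gene interval (weights are the overlap widths), which is robust to
#' genes straddling breakpoints. An alternative rule assigns the value of
#' the single segment with the largest overlap. Genes overlapped by no
#' segment are `NA` for that sample.
#'
#' @param segments A `cn_segments` tibble covering one or more samples.
#' @param genes Gene model tibble with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @param rule `"weighted_mean"` (default) or `"largest_overlap"`.
#' @return Numeric matrix, genes x samples, with `NA` for unmapped genes.
#' @export
map_segments_to_genes <- function(segments, genes,
                                  rule = c("weighted_mean", "largest_overlap")) {
  rule <- match.arg(rule)
  segments <- cn_segments(segments)
  genes <- validate_gene_model(genes)
  if (nrow(genes) == 0) abort("gene model is empty")
  samples <- unique(segments$sample)

  lv <- union(unique(genes$chrom), unique(segments$chrom))
  gene_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lv),
    IRanges::IRanges(genes$start, genes$end))
  seg_gr <- GenomicRanges::GRanges(
    factor(segments$chrom, levels = lv),
    IRanges::IRanges(segments$start, segments$end))

  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(
    gene_gr[qh], seg_gr[sh]))

  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene, samples))
  sample_idx <- match(segments$sample[sh], samples)
  cell <- (sample_idx - 1) * nrow(genes) + qh
  val <- segments$seg_mean[sh]
  if (rule == "weighted_mean") {
    wsum <- tapply(ow * val, cell, sum)
    wtot <- tapply(ow, cell, sum)
    out[as.integer(names(wsum))] <- as.numeric(wsum / wtot)
  } else {
    ord <- order(cell, -ow)
    first <- !duplicated(cell[ord])
    out[cell[ord][first]] <- val[ord][first]
  }
  out
}

#' Mean copy-number profile of a cohort
#'
#' Per-gene arithmetic mean of the gene-level copy-number values over the
#' cohort samples that carry a value for the gene. Genes missing in every
#' cohort sample are dropped from the result. Averaging retains
#' amplifications and deletions consistently present across samples while
#' conflicting or noisy values cancel out.
#'
#' @param gene_cna Genes x samples matrix from [map_segments_to_genes()].
#' @param cohort Sample identifiers to average over; defaults to all
#'   columns.
#' @return Named numeric vector indexed by gene.
#' @export
mean_cna_profile <- function(gene_cna, cohort = colnames(gene_cna)) {
  if (length(cohort) == 0) abort("cohort is empty")
  missing_samples <- setdiff(cohort, colnames(gene_cna))
  if (length(missing_samples) > 0) {
    abort(paste0("cohort sample(s) absent from matrix: ",
                 paste(head(missing_samples, 5), collapse = ", ")))
  }
  sub <- gene_cna[, cohort, drop = FALSE]
  m <- rowMeans(sub, na.rm = TRUE)
  m[!is.nan(m)]
}

#' Copy-number similarity of a cell line to a tumour cohort
#'
#' Quantifies similarity in three related ways: the Pearson correlation of
#' the cell line's gene-level profile with (a) each single tumour, (b) the
#' median of those per-tumour correlations, and (c) the cohort mean
#' profile; the maximum single-tumour correlation is also reported. Each
#' correlation uses the pairwise-complete gene set of the two vectors
#' (pairs with any missing value dropped), so every comparison uses the
#' maximal shared information. A comparison with fewer than 3 complete
#' shared genes is an error; a zero-variance vector yields an undefined
#' correlation which propagates as `NA` (with a warning) and is excluded
#' from the median, never silently zero.
#'
#' @param cell_line_profile Named numeric vector of gene-level copy number.
#' @param tumour_matrix Genes x tumours matrix from
#'   [map_segments_to_genes()].
#' @param mean_profile Named vector from [mean_cna_profile()].
#' @param cell_line Identifier recorded in the result.
#' @return A `cna_similarity` list with fields `cell_line`,
#'   `corr_with_mean_profile`, `per_tumour_correlations`,
#'   `median_correlation`, `max_single_tumour_correlation`.
#' @export
cna_similarity <- function(cell_line_profile, tumour_matrix, mean_profile,
                           cell_line = "cell_line") {
  if (is.null(names(cell_line_profile))) {
    abort("cell_line_profile must be a named (gene-indexed) vector")
  }
  per_tumour <- vapply(colnames(tumour_matrix), function(s) {
    pairwise_pearson(cell_line_profile, setNames(tumour_matrix[, s],
                                                 rownames(tumour_matrix)),
                     label = paste0("tumour ", s))
  }, numeric(1))
  if (all(is.na(per_tumour))) {
    abort("no defined per-tumour correlation")
  }
  res <- list(
    cell_line = cell_line,
    corr_with_mean_profile = pairwise_pearson(cell_line_profile, mean_profile,
                                              label = "mean profile"),
    per_tumour_correlations = per_tumour,
    median_correlation = median(per_tumour, na.rm = TRUE),
    max_single_tumour_correlation = max(per_tumour, na.rm = TRUE)
  )
  class(res) <- "cna_similarity"
  res
}

#' @export
print.cna_similarity <- function(x, ...) {
  cat(sprintf(
    "<cna_similarity> %s: r(mean profile) = %.3f, median r = %.3f, max r = %.3f over %d tumours\n",
    x$cell_line, x$corr_with_mean_profile, x$median_correlation,
    x$max_single_tumour_correlation, length(x$per_tumour_correlations)))
  invisible(x)
}

# Pearson r over the pairwise-complete intersection of two named vectors.
# NA (with a warning) when a vector has zero variance on the shared set.
pairwise_pearson <- function(x, y, label = "vector") {
  shared <- intersect(names(x), names(y))
  xv <- x[shared]
  yv <- y[shared]
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3) {
    abort(paste0("fewer than 3 complete shared genes with ", label))
  }
  xv <- xv[ok]
  yv <- yv[ok]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warn(paste0("zero variance in comparison with ", label,
                "; correlation undefined, propagated as NA"))
    return(NA_real_)
  }
  cor(xv, yv)
}

#' Similarity of every cell line to the tumour cohort
#'
#' Convenience wrapper running [cna_similarity()] for each column of a
#' cell-line gene-level matrix.
#'
#' @param cell_matrix Genes x cell-lines matrix.
#' @param tumour_matrix Genes x tumours matrix.
#' @param mean_profile Named vector from [mean_cna_profile()].
#' @return Tibble with one row per cell line: `cell_line`,
#'   `corr_with_mean_profile`, `median_correlation`,
#'   `max_single_tumour_correlation`.
#' @export
cna_similarity_table <- function(cell_matrix, tumour_matrix, mean_profile) {
  rows <- lapply(colnames(cell_matrix), function(s) {
    sim <- cna_similarity(setNames(cell_matrix[, s], rownames(cell_matrix)),
                          tumour_matrix, mean_profile, cell_line = s)
    tibble(cell_line = s,
           corr_with_mean_profile = sim$corr_with_mean_profile,
           median_correlation = sim$median_correlation,
           max_single_tumour_correlation = sim$max_single_tumour_correlation)
  })
  bind_rows(rows)
}

#' Call a high-level amplification
#'
#' A gene-level log2 copy ratio strictly above the threshold is a
#' high-level amplification. The default threshold of 1.0 suits pure cell
#' lines; it is configurable per dataset.
#'
#' @param value Gene-level log2 copy ratio (vectorised).
#' @param threshold Log2-ratio cut-off (default 1.0).
#' @return Logical vector; `NA` where `value` is `NA`.
#' @export
call_high_level_amplification <- function(value, threshold = 1.0) {
  if (any(!is.finite(value) & !is.na(value))) {
    abort("copy-number value must be finite or NA")
  }
  value > threshold
}
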