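#' Construct and validate a table of copy-number segments
#'
#' Segments are stored as one tidy table covering one or more samples, with
#' columns `sample`, `chrom`, `start`, `end` and `seg_mean` (log2 copy
#' ratio). Coordinates are 1-based, fully closed intervals, the convention
#' of SEG tables exported by the major portals, so the length of a segment
#' is `end - start + 1`.
#'
#' @param x A data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean`.
#' @return A validated `cn_segments` tibble.
#' @export
cn_segments <- function(x) {
  x <- as_tibble(x)
  required <- c("sample", "chrom", "start", "end", "seg_mean")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x[required]
  x$sample <- as.character(x$sample)
  x$chrom <- normalise_chromosome(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$seg_mean <- as.numeric(x$seg_mean)
  bad <- which(!(x$end > x$start))
  if (length(bad) > 0) {
    abort(paste0("segment end must exceed start; offending row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(!is.finite(x$seg_mean))) {
    abort("seg_mean must be finite")
  }
  check_segment_overlaps(x)
  x <- x[order(x$sample, chromosome_order(x$chrom), x$start), ]
  class(x) <- c("cn_segments", class(tibble()))
  x
}

# numeric sort key for chromosome labels ("1".."22" before anything else)
chromosome_order <- function(chrom) {
  suppressWarnings(as.numeric(chrom))
}

check_segment_overlaps <- function(x) {
  key <- paste(x$sample, x$chrom, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- idx[order(x$start[idx])]
    if (length(o) > 1 && any(x$start[o][-1] <= x$end[o][-length(o)])) {
      j <- which(x$start[o][-1] <= x$end[o][-length(o)])[1]
      abort(sprintf(
        "overlapping segments for sample '%s' on chromosome %s: [%s-%s] and [%s-%s]",
        x$sample[o[j]], x$chrom[o[j]],
        format(x$start[o[j]], scientific = FALSE),
        format(x$end[o[j]], scientific = FALSE),
        format(x$start[o[j + 1]], scientific = FALSE),
        format(x$end[o[j + 1]], scientific = FALSE)))
    }
  }
  invisible(x)
}

#' Read a SEG-style table of segmented copy-number profiles
#'
#' Expects a tab-separated table with a header naming the sample,
#' chromosome, start, end and segment-mean columns. Common header spellings
#' (`ID`, `chrom`, `loc.start`, `loc.end`, `seg.mean`, ...) are recognised;
#' a probe-count column, if present, is ignored. Chromosome labels are
#' normalised (`"chr1"` to `"1"`), and sex chromosomes are dropped by
#' default so that downstream statistics run on chromosomes 1-22.
#'
#' @param path Path to a tab-separated SEG file.
#' @param drop_sex_chromosomes Drop segments outside chromosomes 1-22
#'   (default `TRUE`).
#' @return A `cn_segments` tibble covering all samples in the file.
#' @export
read_seg <- function(path, drop_sex_chromosomes = TRUE) {
  x <- read_tsv_strict(path)
  cols <- match_columns(x, list(
    sample   = c("sample", "id", "sampleid", "sample_id"),
    chrom    = c("chrom", "chromosome", "chr"),
    start    = c("start", "locstart", "loc_start"),
    end      = c("end", "locend", "loc_end"),
    seg_mean = c("segmean", "segmentmean", "seg_mean", "mean")
  ), context = "SEG file")
  seg <- tibble(
    sample = as.character(x[[cols["sample"]]]),
    chrom = normalise_chromosome(x[[cols["chrom"]]]),
    start = as.numeric(x[[cols["start"]]]),
    end = as.numeric(x[[cols["end"]]]),
    seg_mean = as.numeric(x[[cols["seg_mean"]]])
  )
  if (drop_sex_chromosomes) {
    seg <- seg[seg$chrom %in% autosome_labels(), , drop = FALSE]
  }
  cn_segments(seg)
}

#' Write segments as a SEG-style table
#'
#' @param segments A `cn_segments` tibble.
#' @param path Output path; tab-separated with a header.
#' @export
write_seg <- function(segments, path) {
  segments <- cn_segments(segments)
  out <- as_tibble(segments)
  names(out) <- c("sample", "chromosome", "start", "end", "seg.mean")
  # 17 significant digits so the log2 ratios round-trip bit-exactly
  out$`seg.mean` <- formatC(out$`seg.mean`, digits = 17, format = "g")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene model table
#'
#' A BED-style tab-separated table with columns `gene`, `chrom`, `start`,
#' `end` (1-based closed coordinates, one row per gene symbol).
#'
#' @param path Path to the gene model TSV.
#' @param drop_sex_chromosomes Drop genes outside chromosomes 1-22.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_model <- function(path, drop_sex_chromosomes = TRUE) {
  x <- read_tsv_strict(path)
  cols <- match_columns(x, list(
    gene  = c("gene", "symbol", "genesymbol", "hugosymbol"),
    chrom = c("chrom", "chromosome", "chr"),
    start = c("start"),
    end   = c("end")
  ), context = "gene model")
  g <- tibble(
    gene = as.character(x[[cols["gene"]]]),
    chrom = normalise_chromosome(x[[cols["chrom"]]]),
    start = as.numeric(x[[cols["start"]]]),
    end = as.numeric(x[[cols["end"]]])
  )
  if (drop_sex_chromosomes) g <- g[g$chrom %in% autosome_labels(), ]
  validate_gene_model(g)
}

validate_gene_model <- function(g) {
  g <- as_tibble(g)
  if (any(!(g$end > g$start))) abort("gene model: end must exceed start")
  if (anyDuplicated(g$gene)) {
    abort(paste0("gene model: duplicated gene symbol(s): ",
                 paste(head(unique(g$gene[duplicated(g$gene)]), 5),
                       collapse = ", ")))
  }
  g
}

#' Write a gene model table
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @param path Output TSV path.
#' @export
write_gene_model <- function(genes, path) {
  readr::write_tsv(validate_gene_model(genes), path)
  invisible(path)
}

# -- shared header helpers ----------------------------------------------------

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # base parser: correctly-rounded doubles, so printed values round-trip
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE))
}

squash_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# match required logical columns against a header; returns named vector of
# actual column names, erroring with the missing logical name
match_columns <- function(x, wanted, context) {
  have <- squash_name(names(x))
  out <- character(0)
  for (nm in names(wanted)) {
    hit <- which(have %in% squash_name(wanted[[nm]]))
    if (length(hit) == 0) {
      abort(sprintf("%s is missing required column '%s'", context, nm))
    }
    out[nm] <- names(x)[hit[1]]
  }
  out
}
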