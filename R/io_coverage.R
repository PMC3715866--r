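#' Construct a sequencing-coverage track
#'
#' A coverage track records, for one sample, which bases were callable.
#' Two dialects exist in the wild and both are supported: `per_base`
#' (positions with one or more reads, as produced by wig-format read-depth
#' tracks) and `per_exon` (exon length plus a coverage fraction in \[0, 1\],
#' as distributed with some tumour cohorts). Exactly one dialect is
#' populated per track.
#'
#' @param sample Sample identifier.
#' @param dialect `"per_base"` or `"per_exon"`.
#' @param positions For `per_base`: a `GRanges` of covered positions (any
#'   width; overlapping ranges are merged) or an integer vector of positions
#'   on a single unnamed sequence.
#' @param exons For `per_exon`: a data frame with columns `length` (bp,
#'   positive) and `fraction` (coverage fraction in \[0, 1\]).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(sample, dialect = c("per_base", "per_exon"),
                           positions = NULL, exons = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "per_base") {
    if (is.null(positions) || !is.null(exons)) {
      abort("per_base track must supply 'positions' and no 'exons'")
    }
    if (is.numeric(positions)) {
      positions <- GenomicRanges::GRanges(
        "un", IRanges::IRanges(start = as.integer(positions), width = 1L))
    }
    if (!is(positions, "GRanges")) {
      abort("'positions' must be a GRanges or an integer vector")
    }
    positions <- GenomicRanges::reduce(positions)
    exons <- NULL
  } else {
    if (is.null(exons) || !is.null(positions)) {
      abort("per_exon track must supply 'exons' and no 'positions'")
    }
    exons <- as_tibble(exons)
    missing_cols <- setdiff(c("length", "fraction"), names(exons))
    if (length(missing_cols) > 0) {
      abort(paste0("per_exon table is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    exons$length <- as.numeric(exons$length)
    exons$fraction <- as.numeric(exons$fraction)
    if (any(exons$length <= 0)) abort("exon_length must be positive")
    if (any(exons$fraction < 0 | exons$fraction > 1)) {
      abort("coverage_fraction must lie within [0, 1]")
    }
    positions <- NULL
  }
  structure(list(sample = as.character(sample), dialect = dialect,
                 positions = positions, exons = exons),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  if (x$dialect == "per_base") {
    cat(sprintf("<coverage_track> sample %s, per_base, %d covered bases\n",
                x$sample, bases_covered(x)))
  } else {
    cat(sprintf("<coverage_track> sample %s, per_exon, %d exons, %d effective bases\n",
                x$sample, nrow(x$exons), bases_covered(x)))
  }
  invisible(x)
}

#' Read a coverage track
#'
#' `per_base` inputs are wig-format read-depth tracks (fixedStep or
#' variableStep), parsed with \pkg{rtracklayer}; positions with a read count
#' of one or more are retained. `per_exon` inputs are tab-separated tables
#' of exon length and coverage fraction.
#'
#' @param path Input file.
#' @param dialect `"per_base"` or `"per_exon"`.
#' @param sample Sample identifier to attach to the track.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path, dialect = c("per_base", "per_exon"), sample) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "per_base") {
    gr <- rtracklayer::import(path, format = "wig")
    covered <- gr[gr$score >= 1]
    S4Vectors::mcols(covered) <- NULL
    coverage_track(sample, "per_base", positions = covered)
  } else {
    x <- read_tsv_strict(path)
    cols <- match_columns(x, list(
      length   = c("length", "exonlength", "exon_length"),
      fraction = c("fraction", "coverage", "coveragefraction")
    ), context = "per-exon coverage table")
    coverage_track(sample, "per_exon",
                   exons = tibble(length = as.numeric(x[[cols["length"]]]),
                                  fraction = as.numeric(x[[cols["fraction"]]])))
  }
}

#' Write a coverage track
#'
#' `per_base` tracks are written as wig fixedStep blocks, one block per
#' covered run (span = run length, value 1); `per_exon` tracks as TSV.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  stopifnot(is(track, "coverage_track"))
  if (track$dialect == "per_base") {
    gr <- track$positions
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=wiggle_0 name=%s", track$sample), con)
    if (length(gr) > 0) {
      blocks <- sprintf("fixedStep chrom=%s start=%d step=%d span=%d\n1",
                        as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr),
                        GenomicRanges::width(gr),
                        GenomicRanges::width(gr))
      writeLines(blocks, con)
    }
  } else {
    readr::write_tsv(track$exons, path)
  }
  invisible(path)
}
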