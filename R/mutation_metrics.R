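#' Filter a catalogue to likely-functional mutations
#'
#' Removes records in intronic, untranslated, flanking and intergenic
#' regions, and silent and RNA mutations ([excluded_classes()]); all other
#' classes, including splice-site and in-frame indels, are retained. The
#' operation is idempotent and stamps the catalogue so that burden
#' calculations can verify they received filtered input.
#'
#' @param catalog A `mutation_catalog`.
#' @return Filtered `mutation_catalog` with attribute
#'   `functional_filtered = TRUE`.
#' @export
filter_functional <- function(catalog) {
  catalog <- mutation_catalog(catalog)
  out <- catalog[!(catalog$class %in% excluded_classes()), , drop = FALSE]
  class(out) <- class(catalog)
  attr(out, "functional_filtered") <- TRUE
  out
}

is_functional_filtered <- function(catalog) {
  isTRUE(attr(catalog, "functional_filtered")) ||
    all(catalog$class %in% functional_classes())
}

#' Number of callable bases of a coverage track
#'
#' `per_base` dialect: the number of positions with one or more reads.
#' `per_exon` dialect: the effective number of covered bases, i.e. the sum
#' over exons of exon length times coverage fraction, accumulated in real
#' arithmetic and rounded once at the end (per-row rounding would bias the
#' sum).
#'
#' @param track A `coverage_track`.
#' @return Non-negative integer count of bases.
#' @export
bases_covered <- function(track) {
  stopifnot(is(track, "coverage_track"))
  if (track$dialect == "per_base") {
    if (length(track$positions) == 0) abort("empty coverage track")
    sum(GenomicRanges::width(track$positions))
  } else {
    if (nrow(track$exons) == 0) abort("empty coverage track")
    round(sum(track$exons$length * track$exons$fraction))
  }
}

#' Coverage-corrected mutation burden
#'
#' The mutation frequency of a sample is its functional mutation count
#' divided by the number of covered bases, reported per megabase:
#' `frequency_per_mb = count / bases_covered * 1e6`. The catalogue must
#' already have passed [filter_functional()]; passing an unfiltered
#' catalogue requires `acknowledge_unfiltered = TRUE` (the resulting burden
#' then includes non-functional records, which is rarely what you want).
#' Each record counts once; multiple mutations in the same gene are not
#' collapsed.
#'
#' @param catalog A functional-filtered `mutation_catalog` (may contain
#'   several samples; records are matched to the track's sample, and zero
#'   records for that sample is a valid burden of 0).
#' @param track The sample's `coverage_track`.
#' @param acknowledge_unfiltered Set `TRUE` to accept a catalogue that has
#'   not been through [filter_functional()].
#' @return Tibble row: `sample`, `n_functional`, `bases_covered`,
#'   `frequency_per_mb`.
#' @export
mutation_frequency <- function(catalog, track, acknowledge_unfiltered = FALSE) {
  catalog <- mutation_catalog(catalog)
  stopifnot(is(track, "coverage_track"))
  if (!acknowledge_unfiltered && !is_functional_filtered(catalog)) {
    abort(paste0("catalogue has not been functional-filtered; run ",
                 "filter_functional() first (or set acknowledge_unfiltered ",
                 "= TRUE)"))
  }
  samples_present <- unique(catalog$sample)
  if (length(samples_present) == 1 && samples_present != track$sample) {
    abort(sprintf("sample mismatch: catalogue has '%s', track has '%s'",
                  samples_present, track$sample))
  }
  bc <- bases_covered(track)
  if (bc <= 0) abort("zero covered bases")
  n <- sum(catalog$sample == track$sample)
  tibble(sample = track$sample, n_functional = n, bases_covered = bc,
         frequency_per_mb = n / bc * 1e6)
}

#' Burden table for a panel of samples
#'
#' @param catalog Functional-filtered `mutation_catalog`.
#' @param tracks Named list of `coverage_track`s (one per sample).
#' @param acknowledge_unfiltered Passed to [mutation_frequency()].
#' @return Tibble with one burden row per track.
#' @export
mutation_burden_table <- function(catalog, tracks,
                                  acknowledge_unfiltered = FALSE) {
  bind_rows(lapply(tracks, function(tr) {
    mutation_frequency(catalog, tr,
                       acknowledge_unfiltered = acknowledge_unfiltered)
  }))
}

#' Marker status for the suitability gene panels
#'
#' Derives per-sample boolean flags for the configured marker panels:
#' mutation flags (`mut_<gene>`) are true when the sample carries at least
#' one functional mutation in the gene; amplification flags (`amp_<gene>`)
#' when the gene-level copy number exceeds the amplification threshold
#' ([call_high_level_amplification()]); the RB1 deletion flag (`del_RB1`)
#' when its gene-level copy number falls below the deletion threshold. A
#' panel gene absent from both the mutation catalogue's gene universe and
#' the copy-number genes raises a warning and yields `NA` flags.
#'
#' @param catalog A `mutation_catalog` (functional filtering is applied
#'   internally so silent hits never set a flag).
#' @param gene_cna Genes x samples matrix of gene-level copy number (or a
#'   named vector for a single sample, in which case `samples` must name
#'   it).
#' @param panels Panel configuration as in [default_marker_panels()].
#' @param amp_threshold Log2-ratio amplification cut-off (default 1.0).
#' @param deletion_threshold Log2-ratio deletion cut-off for RB1
#'   (default -1.0).
#' @param samples Samples to report; defaults to the columns of `gene_cna`.
#' @param somatic_only If `TRUE` and the catalogue has an `origin` column,
#'   only somatic records set mutation flags.
#' @return Tibble with one row per sample and one logical column per flag.
#' @export
marker_status <- function(catalog, gene_cna, panels = default_marker_panels(),
                          amp_threshold = 1.0, deletion_threshold = -1.0,
                          samples = NULL, somatic_only = FALSE) {
  gene_universe <- unique(mutation_catalog(catalog)$gene)
  catalog <- filter_functional(catalog)
  if (somatic_only && "origin" %in% names(catalog)) {
    catalog <- catalog[catalog$origin %in% "somatic", , drop = FALSE]
  }
  if (is.null(dim(gene_cna))) {
    if (is.null(samples) || length(samples) != 1) {
      abort("with a vector gene_cna, supply the single sample name")
    }
    gene_cna <- matrix(gene_cna, ncol = 1,
                       dimnames = list(names(gene_cna), samples))
  }
  if (is.null(samples)) samples <- colnames(gene_cna)

  mut_genes <- unique(c(panels$hgsoc_mut, panels$rb1, panels$non_hgsoc))
  amp_genes <- panels$hgsoc_amp
  known <- unique(c(gene_universe, rownames(gene_cna)))
  absent <- setdiff(unique(c(mut_genes, amp_genes, panels$rb1)), known)
  if (length(absent) > 0) {
    warn(paste0("panel gene(s) absent from catalogue and CNA genes: ",
                paste(absent, collapse = ", "), "; flags set to NA"))
  }

  flag_mut <- function(g, s) {
    if (g %in% absent) return(NA)
    any(catalog$gene == g & catalog$sample == s)
  }
  cn_of <- function(g, s) {
    if (!g %in% rownames(gene_cna) || !s %in% colnames(gene_cna)) {
      return(NA_real_)
    }
    gene_cna[g, s]
  }

  rows <- lapply(samples, function(s) {
    row <- list(sample = s)
    for (g in mut_genes) row[[paste0("mut_", g)]] <- flag_mut(g, s)
    for (g in amp_genes) {
      row[[paste0("amp_", g)]] <-
        call_high_level_amplification(cn_of(g, s), amp_threshold)
    }
    for (g in panels$rb1) {
      cn <- cn_of(g, s)
      row[[paste0("del_", g)]] <- if (is.na(cn)) NA else cn < deletion_threshold
    }
    as_tibble(row)
  })
  bind_rows(rows)
}
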