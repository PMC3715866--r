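#' Controlled vocabulary of variant classifications
#'
#' The internal vocabulary every mutation record is validated against.
#' Input spellings (for example `"Missense_Mutation"` in MAF exports) are
#' translated into these labels by the class map used by [read_mutations()].
#'
#' @return Character vector of the canonical classification labels.
#' @export
mutation_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice_site", "in_frame_indel",
    "nonstop", "translation_start", "silent", "intron", "utr5", "utr3",
    "flank", "igr", "rna")
}

#' Classifications excluded by the likely-functional filter
#'
#' Intronic, untranslated-region, flanking and intergenic variants, together
#' with silent and RNA variants, are treated as unlikely to be functional and
#' are removed by [filter_functional()]. Everything else (missense, nonsense,
#' frameshift, splice-site, in-frame indel, nonstop, translation-start) is
#' retained.
#'
#' @return Character vector of excluded classification labels.
#' @export
excluded_classes <- function() {
  c("intron", "utr5", "utr3", "flank", "igr", "silent", "rna")
}

#' Classifications retained by the likely-functional filter
#' @return Character vector of functional classification labels.
#' @export
functional_classes <- function() {
  setdiff(mutation_classes(), excluded_classes())
}

#' Read a MAF classification map from a YAML file
#'
#' The map translates dataset-specific variant-classification spellings into
#' the canonical vocabulary of [mutation_classes()]. It is shipped as an
#' editable configuration file rather than hard-coded because classification
#' vocabularies drift across dataset versions.
#'
#' @param path Path to a YAML file of `input_label: canonical_label` pairs.
#'   Defaults to the map installed with the package.
#' @return Named character vector mapping input labels to canonical labels.
#' @export
read_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "maf_classes.yaml", package = "cellmodelr")
  }
  if (!file.exists(path)) {
    abort(paste0("classification map not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  map <- vapply(raw, as.character, character(1))
  bad <- setdiff(unique(map), mutation_classes())
  if (length(bad) > 0) {
    abort(paste0("class map targets outside the vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  map
}

#' Default marker gene panels
#'
#' The marker panels used for the suitability analysis of ovarian cancer
#' cell lines: genes recurrently altered in high-grade serous ovarian cancer
#' (mutation of TP53, BRCA1 or BRCA2; high-level amplification of C11orf30
#' (EMSY), CCNE1, KRAS or MYC; mutation or deletion of RB1), and the seven
#' "non-HGSOC" genes recurrently mutated only in the other ovarian cancer
#' subtypes (ARID1A, BRAF, CTNNB1, ERBB2, KRAS, PIK3CA, PTEN).
#'
#' @return A list with elements `hgsoc_mut`, `hgsoc_amp`, `rb1` and
#'   `non_hgsoc`, each a character vector of gene symbols.
#' @export
default_marker_panels <- function() {
  list(
    hgsoc_mut = c("TP53", "BRCA1", "BRCA2"),
    hgsoc_amp = c("C11orf30", "CCNE1", "KRAS", "MYC"),
    rb1       = "RB1",
    non_hgsoc = c("ARID1A", "BRAF", "CTNNB1", "ERBB2", "KRAS", "PIK3CA",
                  "PTEN")
  )
}

#' The seven non-HGSOC panel genes
#' @return Character vector of the seven gene symbols.
#' @export
non_hgsoc_genes <- function() default_marker_panels()$non_hgsoc

# chromosome labels accepted after normalisation (autosomes)
autosome_labels <- function() as.character(1:22)

# strip "chr" prefixes; idempotent
normalise_chromosome <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}
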