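#' Construct and validate a mutation catalogue
#'
#' A tidy table of per-sample mutation records with columns `sample`,
#' `gene`, `class` (a label from [mutation_classes()]) and optionally
#' `protein_change` and `origin` (`"somatic"`/`"germline"`, when the source
#' distinguishes them). Unknown classification labels are rejected, not
#' coerced.
#'
#' @param x A data frame with at least `sample`, `gene`, `class`.
#' @return A validated `mutation_catalog` tibble.
#' @export
mutation_catalog <- function(x) {
  x <- as_tibble(x)
  required <- c("sample", "gene", "class")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("mutation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$sample <- as.character(x$sample)
  x$gene <- as.character(x$gene)
  x$class <- as.character(x$class)
  if (!"protein_change" %in% names(x)) x$protein_change <- NA_character_
  bad <- setdiff(unique(x$class), mutation_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown variant classification label(s): ",
                 paste(bad, collapse = ", ")))
  }
  keep <- intersect(c("sample", "gene", "class", "protein_change", "origin"),
                    names(x))
  x <- x[keep]
  class(x) <- c("mutation_catalog", class(tibble()))
  x
}

#' Read a MAF-style mutation table
#'
#' Expects a tab-separated table with sample, gene and classification
#' columns (common MAF header spellings such as `Tumor_Sample_Barcode`,
#' `Hugo_Symbol` and `Variant_Classification` are recognised). The
#' classification column is translated into the canonical vocabulary via a
#' configurable class map; any label the map does not cover aborts with the
#' offending labels listed. An optional `origin` column (somatic/germline)
#' is carried through when present, since some cohorts mix germline records
#' (for example BRCA1/2 carriers) into the same file.
#'
#' @param path Path to the tab-separated mutation table.
#' @param class_map Named character vector translating input labels to
#'   canonical ones; defaults to the installed map ([read_class_map()]).
#' @return A `mutation_catalog` tibble.
#' @export
read_mutations <- function(path, class_map = read_class_map()) {
  x <- read_tsv_strict(path)
  cols <- match_columns(x, list(
    sample = c("sample", "tumorsamplebarcode", "sampleid", "sample_id"),
    gene   = c("gene", "hugosymbol", "genesymbol"),
    class  = c("classification", "variantclassification", "class")
  ), context = "mutation table")
  raw_class <- as.character(x[[cols["class"]]])
  unmapped <- setdiff(unique(raw_class), names(class_map))
  if (length(unmapped) > 0) {
    abort(paste0("unmapped variant classification label(s): ",
                 paste(unmapped, collapse = ", ")))
  }
  out <- tibble(
    sample = as.character(x[[cols["sample"]]]),
    gene = as.character(x[[cols["gene"]]]),
    class = unname(class_map[raw_class])
  )
  prot <- which(squash_name(names(x)) %in% c("proteinchange", "hgvspshort"))
  if (length(prot) > 0) out$protein_change <- as.character(x[[prot[1]]])
  orig <- which(squash_name(names(x)) %in% c("origin", "mutationstatus"))
  if (length(orig) > 0) out$origin <- tolower(as.character(x[[orig[1]]]))
  mutation_catalog(out)
}

#' Write a mutation catalogue as a MAF-style table
#' @param catalog A `mutation_catalog` tibble.
#' @param path Output TSV path.
#' @export
write_mutations <- function(catalog, path) {
  catalog <- mutation_catalog(catalog)
  out <- catalog
  names(out)[names(out) == "class"] <- "classification"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Per-sample record counts of a catalogue
#' @param catalog A `mutation_catalog` tibble.
#' @return Tibble with columns `sample`, `n_records`.
#' @export
count_mutations <- function(catalog) {
  catalog <- mutation_catalog(catalog)
  catalog |>
    group_by(.data$sample) |>
    summarise(n_records = n(), .groups = "drop")
}
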