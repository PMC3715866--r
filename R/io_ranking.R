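#' Write a suitability ranking table
#'
#' Serialises the ordered ranking as TSV: `sample`, the components `A`,
#' `B`, `C`, `D`, the score `S`, the `tier`, the tie-break note, and any
#' per-gene marker columns that were joined onto the ranking. Real values
#' are written at full precision so a read-back reproduces them exactly.
#' Row order equals ranking order.
#'
#' @param ranking A `suitability_ranking` (or compatible tibble with
#'   `cell_line`, `A`..`S`, `tier`).
#' @param path Output TSV path.
#' @export
write_ranking_table <- function(ranking, path) {
  if (is.null(ranking) || nrow(ranking) == 0) abort("empty ranking")
  out <- as_tibble(ranking)
  names(out)[names(out) == "cell_line"] <- "sample"
  lead <- intersect(c("sample", "A", "B", "C", "D", "S", "tier",
                      "tie_break_note"), names(out))
  out <- out[c(lead, setdiff(names(out), lead))]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    formatC(v, digits = 17, format = "g")
  })
  readr::write_tsv(out, path)
  w <- attr(ranking, "weights")
  if (!is.null(w)) {
    meta <- sub("\\.tsv$", "", path)
    yaml::write_yaml(list(score_weights = as.list(w)),
                     paste0(meta, "_weights.yaml"))
  }
  invisible(path)
}

#' Read a ranking table written by [write_ranking_table()]
#'
#' @param path Path to the ranking TSV.
#' @return Tibble in file order with numeric columns restored.
#' @export
read_ranking_table <- function(path) {
  x <- read_tsv_strict(path)
  names(x)[names(x) == "sample"] <- "cell_line"
  for (cc in intersect(c("A", "B", "C", "D", "S"), names(x))) {
    x[[cc]] <- as.numeric(x[[cc]])
  }
  x
}
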