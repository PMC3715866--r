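#' Flag hypermutator outliers
#'
#' Hypermutators combine a high mutation frequency with few copy-number
#' changes, a genotype that sets them clearly apart from high-CNA, low
#' mutation-rate tumours. A sample is flagged when its frequency exceeds
#' `freq_threshold` (default 10 per Mb) AND its fraction genome altered
#' falls below `fga_threshold` (default 0.25). The defaults separate
#' outliers at roughly three times the typical cell-line mutation rate
#' while requiring a visibly flat profile; both are configurable.
#'
#' @param burdens Tibble with columns `sample`, `frequency_per_mb`
#'   (from [mutation_burden_table()]).
#' @param fga Tibble with columns `sample`, `fga`
#'   (from [fraction_genome_altered()]).
#' @param freq_threshold Mutations per Mb above which a sample is
#'   hypermutation-suspect.
#' @param fga_threshold FGA below which the profile counts as flat.
#' @return Tibble with columns `sample`, `frequency_per_mb`, `fga`,
#'   `hypermutated`.
#' @export
classify_hypermutated <- function(burdens, fga, freq_threshold = 10,
                                  fga_threshold = 0.25) {
  need_b <- setdiff(c("sample", "frequency_per_mb"), names(burdens))
  need_f <- setdiff(c("sample", "fga"), names(fga))
  if (length(need_b) > 0 || length(need_f) > 0) {
    abort("burdens needs (sample, frequency_per_mb); fga needs (sample, fga)")
  }
  joined <- dplyr::full_join(as_tibble(burdens)[c("sample", "frequency_per_mb")],
                             as_tibble(fga)[c("sample", "fga")], by = "sample")
  incomplete <- joined$sample[is.na(joined$frequency_per_mb) | is.na(joined$fga)]
  if (length(incomplete) > 0) {
    abort(paste0("missing burden or FGA for sample(s): ",
                 paste(head(incomplete, 5), collapse = ", ")))
  }
  joined$hypermutated <- joined$frequency_per_mb > freq_threshold &
    joined$fga < fga_threshold
  joined
}

#' Assemble the suitability-score components for one cell line
#'
#' The components are: `A`, the Pearson correlation of the cell line's
#' copy-number profile with the tumour-cohort mean profile; `B`, 1 when the
#' line carries a TP53 mutation; `C`, 1 when the line is hypermutated; and
#' `D`, the number of mutated genes among the non-HGSOC panel. A missing
#' marker flag for any panel gene is an error rather than a silent zero.
#'
#' @param cell_line Cell-line identifier.
#' @param similarity A `cna_similarity` for the line (or a one-row tibble
#'   with a `corr_with_mean_profile` column).
#' @param markers One-row marker tibble for the line from
#'   [marker_status()].
#' @param hyper Logical hypermutation indicator for the line.
#' @param panel Character vector of non-HGSOC panel genes.
#' @return One-row tibble: `cell_line`, `A`, `B`, `C`, `D`.
#' @export
assemble_components <- function(cell_line, similarity, markers, hyper,
                                panel = non_hgsoc_genes()) {
  A <- if (is(similarity, "cna_similarity")) {
    similarity$corr_with_mean_profile
  } else {
    similarity$corr_with_mean_profile[1]
  }
  if (nrow(markers) != 1) abort("markers must be a single row")
  tp53 <- markers[["mut_TP53"]]
  if (is.null(tp53) || is.na(tp53)) abort("missing TP53 marker flag")
  panel_cols <- paste0("mut_", panel)
  missing_cols <- setdiff(panel_cols, names(markers))
  if (length(missing_cols) > 0) {
    abort(paste0("missing marker flag(s) for panel gene(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  flags <- vapply(panel_cols, function(cc) markers[[cc]], logical(1))
  if (any(is.na(flags))) {
    abort(paste0("NA marker flag(s) for panel gene(s): ",
                 paste(panel_cols[is.na(flags)], collapse = ", ")))
  }
  if (is.na(hyper)) abort("missing hypermutation indicator")
  tibble(cell_line = cell_line, A = A, B = as.integer(tp53),
         C = as.integer(hyper), D = sum(flags))
}

#' Component table for a panel of cell lines
#'
#' @param similarity Tibble from [cna_similarity_table()].
#' @param markers Tibble from [marker_status()].
#' @param hyper Tibble from [classify_hypermutated()].
#' @param panel Non-HGSOC panel genes.
#' @return Tibble with one component row per cell line.
#' @export
suitability_components <- function(similarity, markers, hyper,
                                   panel = non_hgsoc_genes()) {
  bind_rows(lapply(similarity$cell_line, function(s) {
    assemble_components(
      s,
      similarity[similarity$cell_line == s, , drop = FALSE],
      markers[markers$sample == s, , drop = FALSE],
      hyper$hypermutated[hyper$sample == s],
      panel = panel)
  }))
}

#' Default weights of the suitability score
#' @return Named numeric vector `(A, B, C, D)`.
#' @export
default_score_weights <- function() c(A = 1, B = 0.5, C = 0.5, D = 0.25)

#' Compute the suitability score
#'
#' The score combines the components affinely, with HGSOC features
#' weighted positively and features of other subtypes negatively:
#' \deqn{S = w_A A + w_B B - w_C C - w_D D}
#' The default weights `(1, 0.5, 0.5, 0.25)` put each component on a
#' comparable dynamic range (`A` spans about one unit; `D/4` spans at most
#' 1.75) and are fully configurable; the weights used are recorded as an
#' attribute of the result so they travel with the output.
#'
#' @param components Tibble with columns `A`, `B`, `C`, `D` (one or more
#'   rows).
#' @param weights Named positive weights, see [default_score_weights()].
#' @return The component tibble with an `S` column appended and a
#'   `"weights"` attribute.
#' @export
suitability_score <- function(components, weights = default_score_weights()) {
  need <- setdiff(c("A", "B", "C", "D"), names(components))
  if (length(need) > 0) {
    abort(paste0("components missing column(s): ", paste(need, collapse = ", ")))
  }
  if (!all(c("A", "B", "C", "D") %in% names(weights))) {
    abort("weights must name A, B, C and D")
  }
  if (any(weights[c("A", "B", "C", "D")] <= 0)) {
    abort("weights must be positive (signs are fixed by the score's form)")
  }
  out <- as_tibble(components)
  out$S <- weights["A"] * out$A + weights["B"] * out$B -
    weights["C"] * out$C - weights["D"] * out$D
  attr(out, "weights") <- weights[c("A", "B", "C", "D")]
  out
}

#' Order cell lines by score and assign good/moderate/poor tiers
#'
#' Sorts by `S` descending; ties are broken by `A` descending and then by
#' cell-line identifier (lexicographic), with a note recorded for rows
#' whose position was decided by a tie rule. Tiers are assigned either by
#' counts from the top/bottom (default: top 12 good, bottom 12 poor, rest
#' moderate) or by score cut points. The ordering distinguishes better and
#' poorer models; it is not meant as a finely graduated ranking.
#'
#' @param components Tibble from [suitability_score()] (must carry `S`).
#' @param mode `"count"` or `"cut"`.
#' @param n_good,n_poor Tier sizes for `mode = "count"`.
#' @param cuts For `mode = "cut"`: numeric `c(good = x, poor = y)`; `S >= x`
#'   is good, `S < y` is poor.
#' @return A `suitability_ranking` tibble with `tier` and `tie_break_note`
#'   columns, ordered best first; score weights (if present) are carried
#'   through as an attribute.
#' @export
rank_and_tier <- function(components, mode = c("count", "cut"),
                          n_good = 12, n_poor = 12, cuts = NULL) {
  mode <- match.arg(mode)
  if (nrow(components) == 0) abort("empty component table")
  if (!"S" %in% names(components)) abort("components must carry an S column")
  x <- as_tibble(components)
  ord <- order(-x$S, -x$A, x$cell_line)
  x <- x[ord, ]
  tie <- rep("", nrow(x))
  dup_s <- duplicated(x$S) | duplicated(x$S, fromLast = TRUE)
  if (any(dup_s)) {
    tie[dup_s] <- "tie on S broken by A, then cell line id"
  }
  x$tie_break_note <- tie

  n <- nrow(x)
  if (mode == "count") {
    n_good <- min(n_good, n)
    n_poor <- min(n_poor, max(0, n - n_good))
    tier <- rep("moderate", n)
    if (n_good > 0) tier[seq_len(n_good)] <- "good"
    if (n_poor > 0) tier[seq(n - n_poor + 1, n)] <- "poor"
  } else {
    if (is.null(cuts) || !all(c("good", "poor") %in% names(cuts))) {
      abort("mode = 'cut' needs cuts = c(good = ..., poor = ...)")
    }
    if (cuts["poor"] > cuts["good"]) abort("poor cut must not exceed good cut")
    tier <- ifelse(x$S >= cuts["good"], "good",
                   ifelse(x$S < cuts["poor"], "poor", "moderate"))
  }
  x$tier <- tier
  attr(x, "weights") <- attr(components, "weights")
  class(x) <- c("suitability_ranking", class(tibble()))
  x
}
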