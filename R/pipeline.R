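#' Build a run configuration
#'
#' Collects the input paths and analysis parameters of a full pipeline run.
#' Thresholds default to the platform-appropriate values: FGA threshold 0.2
#' for tumours and 0.3 for cell lines, high-level amplification above 1.0,
#' RB1 deletion below -1.0, hypermutator cut-offs 10 per Mb and FGA 0.25,
#' top 5,000 genes by IQR for the expression analyses.
#'
#' @param inputs Named list of paths: `tumour_seg`, `cell_seg`,
#'   `tumour_mutations`, `cell_mutations`, `gene_model`,
#'   `tumour_coverage_dir` (per-exon TSVs, `<sample>.tsv`),
#'   `cell_coverage_dir` (wig files, `<sample>.wig`), `tumour_expression`,
#'   `cell_expression`.
#' @param out_dir Output directory for stage artifacts.
#' @param thresholds Overrides for `t_tumour`, `t_cell_line`, `amp`,
#'   `deletion`.
#' @param score_weights Suitability weights, see [default_score_weights()].
#' @param hypermutator Overrides for `freq_threshold`, `fga_threshold`.
#' @param tiers Overrides for `mode`, `n_good`, `n_poor`, `cuts`.
#' @param expression Overrides for `n_top_genes`, `linkage`.
#' @param panels Marker panels, see [default_marker_panels()].
#' @param seed Seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters when inputs are simulated).
#' @return A validated `run_config` list.
#' @export
run_config <- function(inputs, out_dir, thresholds = list(),
                       score_weights = default_score_weights(),
                       hypermutator = list(), tiers = list(),
                       expression = list(),
                       panels = default_marker_panels(), seed = 1) {
  cfg <- list(
    inputs = inputs,
    out_dir = out_dir,
    thresholds = modifyList(
      list(t_tumour = 0.2, t_cell_line = 0.3, amp = 1.0, deletion = -1.0),
      thresholds),
    score_weights = score_weights,
    hypermutator = modifyList(list(freq_threshold = 10, fga_threshold = 0.25),
                              hypermutator),
    tiers = modifyList(list(mode = "count", n_good = 12, n_poor = 12,
                            cuts = NULL), tiers),
    expression = modifyList(list(n_top_genes = 5000, linkage = "complete"),
                            expression),
    panels = panels,
    seed = seed
  )
  required <- c("tumour_seg", "cell_seg", "tumour_mutations",
                "cell_mutations", "gene_model", "tumour_coverage_dir",
                "cell_coverage_dir", "tumour_expression", "cell_expression")
  missing_inputs <- setdiff(required, names(inputs))
  if (length(missing_inputs) > 0) {
    abort(paste0("run_config inputs missing: ",
                 paste(missing_inputs, collapse = ", ")))
  }
  for (nm in required) {
    if (!file.exists(inputs[[nm]])) {
      abort(paste0("input '", nm, "' not found: ", inputs[[nm]]))
    }
  }
  if (cfg$thresholds$t_tumour <= 0 || cfg$thresholds$t_cell_line <= 0) {
    abort("FGA thresholds must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]: an `inputs` block of
#' paths plus optional `thresholds`, `score_weights`, `hypermutator`,
#' `tiers`, `expression` and `seed` blocks. Relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param out_dir Output directory (overrides any `out_dir` in the file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  inputs <- lapply(y$inputs, function(p) {
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  weights <- if (is.null(y$score_weights)) default_score_weights() else {
    unlist(y$score_weights)
  }
  run_config(inputs,
             out_dir = if (is.null(out_dir)) y$out_dir else out_dir,
             thresholds = as.list(y$thresholds %||% list()),
             score_weights = weights,
             hypermutator = as.list(y$hypermutator %||% list()),
             tiers = as.list(y$tiers %||% list()),
             expression = as.list(y$expression %||% list()),
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, fmt, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

#' Copy-number stage: gene mapping, FGA, similarity
#'
#' Reads the tumour and cell-line SEG files and the gene model, maps both
#' cohorts to gene-level copy number, computes per-sample FGA at the
#' platform-appropriate thresholds, the tumour mean profile, and the three
#' copy-number similarity measures per cell line. Writes
#' `gene_cna_tumour.tsv`, `gene_cna_cell_line.tsv`, `fga.tsv` and
#' `similarity.tsv` into the output directory.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the similarity tibble.
#' @export
stage_cna <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_gene_model(cfg$inputs$gene_model)
  tum <- read_seg(cfg$inputs$tumour_seg)
  cell <- read_seg(cfg$inputs$cell_seg)
  stage_log("cna", "read %d tumour and %d cell-line samples, %d genes",
            length(unique(tum$sample)), length(unique(cell$sample)),
            nrow(genes))
  tum_cna <- map_segments_to_genes(tum, genes)
  cell_cna <- map_segments_to_genes(cell, genes)
  write_gene_matrix(tum_cna, stage_path(cfg, "gene_cna_tumour.tsv"))
  write_gene_matrix(cell_cna, stage_path(cfg, "gene_cna_cell_line.tsv"))

  fga <- bind_rows(
    mutate(fraction_genome_altered(tum, cfg$thresholds$t_tumour),
           cohort = "tumour"),
    mutate(fraction_genome_altered(cell, cfg$thresholds$t_cell_line),
           cohort = "cell_line"))
  readr::write_tsv(fga, stage_path(cfg, "fga.tsv"))

  mp <- mean_cna_profile(tum_cna)
  sim <- cna_similarity_table(cell_cna, tum_cna, mp)
  readr::write_tsv(sim, stage_path(cfg, "similarity.tsv"))
  stage_log("cna", "similarity computed for %d cell lines", nrow(sim))
  invisible(sim)
}

#' Burden stage: functional filter and coverage-corrected frequency
#'
#' Reads both mutation tables and the per-sample coverage inputs, applies
#' the likely-functional filter, and writes per-sample burdens
#' (`burden.tsv`). Coverage files are looked up per sample as
#' `<sample>.tsv` (per-exon, tumours) and `<sample>.wig` (per-base, cell
#' lines) in the configured directories.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the burden tibble.
#' @export
stage_burden <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tum_mut <- filter_functional(read_mutations(cfg$inputs$tumour_mutations))
  cell_mut <- filter_functional(read_mutations(cfg$inputs$cell_mutations))
  stage_log("burden", "functional records: %d tumour, %d cell line",
            nrow(tum_mut), nrow(cell_mut))
  tum_tracks <- read_coverage_dir(cfg$inputs$tumour_coverage_dir, "per_exon")
  cell_tracks <- read_coverage_dir(cfg$inputs$cell_coverage_dir, "per_base")
  burden <- bind_rows(
    mutate(mutation_burden_table(tum_mut, tum_tracks), cohort = "tumour"),
    mutate(mutation_burden_table(cell_mut, cell_tracks),
           cohort = "cell_line"))
  readr::write_tsv(burden, stage_path(cfg, "burden.tsv"))
  invisible(burden)
}

read_coverage_dir <- function(dir, dialect) {
  ext <- if (dialect == "per_base") "\\.wig$" else "\\.tsv$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  if (length(files) == 0) abort(paste0("no coverage files in ", dir))
  tracks <- lapply(files, function(f) {
    read_coverage(f, dialect, sample = sub("\\.[a-z]+$", "", basename(f)))
  })
  names(tracks) <- vapply(tracks, function(t) t$sample, character(1))
  tracks
}

#' Score stage: markers, hypermutators, components, ranking
#'
#' Consumes the artifacts of [stage_cna()] and [stage_burden()], derives
#' marker flags and the hypermutation indicator for each cell line,
#' assembles components, scores and tiers, and writes `markers.tsv`,
#' `components.tsv` and `ranking.tsv`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the `suitability_ranking`.
#' @export
stage_score <- function(cfg) {
  sim <- readr::read_tsv(stage_path(cfg, "similarity.tsv"),
                         show_col_types = FALSE)
  fga <- readr::read_tsv(stage_path(cfg, "fga.tsv"), show_col_types = FALSE)
  burden <- readr::read_tsv(stage_path(cfg, "burden.tsv"),
                            show_col_types = FALSE)
  cell_cna <- read_gene_matrix(stage_path(cfg, "gene_cna_cell_line.tsv"))
  cell_mut <- filter_functional(read_mutations(cfg$inputs$cell_mutations))

  markers <- marker_status(cell_mut, cell_cna, panels = cfg$panels,
                           amp_threshold = cfg$thresholds$amp,
                           deletion_threshold = cfg$thresholds$deletion)
  readr::write_tsv(markers, stage_path(cfg, "markers.tsv"))

  hyper <- classify_hypermutated(
    burden[burden$cohort == "cell_line", ],
    fga[fga$cohort == "cell_line", ],
    freq_threshold = cfg$hypermutator$freq_threshold,
    fga_threshold = cfg$hypermutator$fga_threshold)
  stage_log("score", "%d hypermutated cell line(s)", sum(hyper$hypermutated))

  comp <- suitability_components(sim, markers, hyper,
                                 panel = cfg$panels$non_hgsoc)
  comp <- suitability_score(comp, weights = cfg$score_weights)
  readr::write_tsv(comp, stage_path(cfg, "components.tsv"))

  ranking <- rank_and_tier(comp, mode = cfg$tiers$mode,
                           n_good = cfg$tiers$n_good,
                           n_poor = cfg$tiers$n_poor, cuts = cfg$tiers$cuts)
  ranking_out <- left_join(ranking, markers,
                           by = c(cell_line = "sample"))
  attr(ranking_out, "weights") <- attr(ranking, "weights")
  write_ranking_table(ranking_out, stage_path(cfg, "ranking.tsv"))
  invisible(ranking)
}

#' Expression stage: combine, cluster, embed, rank
#'
#' Combines the two expression datasets (separate robust z-scores, shared
#' genes), selects the most variable genes by IQR, clusters samples on the
#' correlation distance with the configured linkage, computes a 2-component
#' PCA embedding, and ranks cell lines by their average correlation with
#' the tumours. Writes `expression_rank.tsv`, `pca.tsv` and
#' `dendrogram.nwk`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the expression ranking tibble.
#' @export
stage_expression <- function(cfg) {
  tum <- read_expression(cfg$inputs$tumour_expression, dataset = "tumour")
  cell <- read_expression(cfg$inputs$cell_expression, dataset = "cell_line")
  comb <- combine_datasets(tum, cell)
  n_top <- min(cfg$expression$n_top_genes, nrow(comb$values))
  if (n_top < cfg$expression$n_top_genes) {
    stage_log("expression", "only %d shared genes; selecting all of them",
              n_top)
  }
  sel <- select_top_iqr(comb, n_top)
  dmat <- correlation_distance_matrix(sel)
  tree <- hierarchical_cluster(dmat, linkage = cfg$expression$linkage)
  write_dendrogram_newick(tree, stage_path(cfg, "dendrogram.nwk"))
  emb <- pca_embedding(sel, k = 2)
  readr::write_tsv(emb, stage_path(cfg, "pca.tsv"))
  er <- expression_rank(cell, tum)
  readr::write_tsv(er, stage_path(cfg, "expression_rank.tsv"))
  invisible(er)
}

#' Concordance stage: suitability versus expression ordering
#'
#' Compares the suitability ranking with the expression-based ranking via
#' Kendall's tau-b and writes `concordance.json`.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the concordance list.
#' @export
stage_concordance <- function(cfg) {
  ranking <- read_ranking_table(stage_path(cfg, "ranking.tsv"))
  er <- readr::read_tsv(stage_path(cfg, "expression_rank.tsv"),
                        show_col_types = FALSE)
  conc <- kendall_concordance(ranking$cell_line, er$cell_line)
  jsonlite::write_json(conc, stage_path(cfg, "concordance.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("concordance", "tau = %.3f, p = %.3g (%s)", conc$tau,
            conc$p_value, conc$method)
  invisible(conc)
}

#' Run the full pipeline
#'
#' Executes the stages in order (copy number, burden, score, expression,
#' concordance), emits the mutation-frequency versus FGA scatter, and
#' writes a manifest (`manifest.json`) recording the configuration hash,
#' seed and package version, so a run can be reproduced byte-identically
#' from the manifest and inputs. Stages communicate through TSV files in
#' the output directory, so each is independently re-runnable. Any stage
#' error aborts with the stage name attached.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the ranking, expression ranking and
#'   concordance.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, fn) {
    tryCatch(fn(cfg), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  run_stage("cna", stage_cna)
  burden <- run_stage("burden", stage_burden)
  ranking <- run_stage("score", stage_score)
  er <- run_stage("expression", stage_expression)
  conc <- run_stage("concordance", stage_concordance)

  fga <- readr::read_tsv(stage_path(cfg, "fga.tsv"), show_col_types = FALSE)
  hyper <- classify_hypermutated(
    burden[burden$cohort == "cell_line", ],
    fga[fga$cohort == "cell_line", ],
    freq_threshold = cfg$hypermutator$freq_threshold,
    fga_threshold = cfg$hypermutator$fga_threshold)
  report_scatter(burden, fga, hyper, stage_path(cfg, "scatter"))

  manifest <- list(
    package = "cellmodelr",
    version = as.character(utils::packageVersion("cellmodelr")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    inputs = cfg$inputs,
    thresholds = cfg$thresholds,
    score_weights = as.list(cfg$score_weights),
    hypermutator = cfg$hypermutator,
    tiers = cfg$tiers[c("mode", "n_good", "n_poor")],
    expression = cfg$expression
  )
  jsonlite::write_json(manifest, stage_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ranking = ranking, expression_rank = er,
                 concordance = conc))
}

#' Mutation frequency versus FGA scatter
#'
#' The outlier diagnostic: mutation frequency (per Mb, log scale) on the
#' horizontal axis against fraction genome altered on the vertical, with
#' hypermutators marked. The plotted table is also written as TSV so the
#' figure's content is testable numerically.
#'
#' @param burdens Burden tibble (with `cohort` column if mixed).
#' @param fga FGA tibble.
#' @param hyper Tibble from [classify_hypermutated()].
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.pdf`.
#' @return Invisibly, the emitted tibble.
#' @export
report_scatter <- function(burdens, fga, hyper, path_prefix) {
  if (nrow(burdens) == 0 || nrow(fga) == 0) abort("empty input")
  tab <- dplyr::inner_join(
    as_tibble(burdens)[intersect(c("sample", "frequency_per_mb", "cohort"),
                                 names(burdens))],
    as_tibble(fga)[intersect(c("sample", "fga"), names(fga))],
    by = "sample")
  if (nrow(tab) != length(unique(c(burdens$sample)))) {
    abort("sample sets of burdens and fga do not match")
  }
  tab <- left_join(tab, as_tibble(hyper)[c("sample", "hypermutated")],
                   by = "sample")
  tab$hypermutated[is.na(tab$hypermutated)] <- FALSE
  readr::write_tsv(tab, paste0(path_prefix, ".tsv"))
  p <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$frequency_per_mb, y = .data$fga,
    colour = if ("cohort" %in% names(tab)) .data$cohort else "sample",
    shape = .data$hypermutated)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutation frequency (per Mb)",
                  y = "fraction genome altered",
                  colour = "cohort", shape = "hypermutated") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paste0(path_prefix, ".pdf"), p, width = 6, height = 4)
  invisible(tab)
}

#' Write synthetic inputs to disk in the standard formats
#'
#' Generates a tumour cohort and cell-line panel and serialises every
#' artifact in the dialects the readers expect (SEG, MAF-style TSV, wig,
#' per-exon TSV, expression TSV, gene-model TSV), so a pipeline run on
#' synthetic data exercises the same input paths as a run on downloaded
#' exports. Truth labels are written alongside (`truth_*.tsv`).
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param cohort A `cohort_spec`.
#' @param panel A `panel_spec`.
#' @return The named list of paths needed by [run_config()].
#' @export
simulate_inputs <- function(dir, seed = 1, cohort = cohort_spec(),
                            panel = panel_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tum <- generate_tumour_cohort(cohort, seed = seed)
  mp <- mean_cna_profile(
    map_segments_to_genes(tum$segments, tum$gene_model))
  cl <- generate_cell_line_panel(panel, mp, seed = seed,
                                 gene_model = tum$gene_model,
                                 tumour_signature = tum$signature)
  paths <- list(
    tumour_seg = file.path(dir, "tumour_segments.seg"),
    cell_seg = file.path(dir, "cell_segments.seg"),
    tumour_mutations = file.path(dir, "tumour_mutations.tsv"),
    cell_mutations = file.path(dir, "cell_mutations.tsv"),
    gene_model = file.path(dir, "gene_model.tsv"),
    tumour_coverage_dir = file.path(dir, "coverage_tumour"),
    cell_coverage_dir = file.path(dir, "coverage_cell"),
    tumour_expression = file.path(dir, "expression_tumour.tsv"),
    cell_expression = file.path(dir, "expression_cell.tsv")
  )
  write_seg(tum$segments, paths$tumour_seg)
  write_seg(cl$segments, paths$cell_seg)
  write_mutations(tum$mutations, paths$tumour_mutations)
  write_mutations(cl$mutations, paths$cell_mutations)
  write_gene_model(tum$gene_model, paths$gene_model)
  dir.create(paths$tumour_coverage_dir, showWarnings = FALSE)
  dir.create(paths$cell_coverage_dir, showWarnings = FALSE)
  for (tr in tum$coverage) {
    write_coverage(tr, file.path(paths$tumour_coverage_dir,
                                 paste0(tr$sample, ".tsv")))
  }
  for (tr in cl$coverage) {
    write_coverage(tr, file.path(paths$cell_coverage_dir,
                                 paste0(tr$sample, ".wig")))
  }
  write_expression(tum$expression, paths$tumour_expression)
  write_expression(cl$expression, paths$cell_expression)
  readr::write_tsv(tum$truth, file.path(dir, "truth_tumour.tsv"))
  readr::write_tsv(cl$truth, file.path(dir, "truth_cell.tsv"))
  paths
}

# gene-by-sample matrix TSV helpers shared by the stages
write_gene_matrix <- function(m, path) {
  out <- as_tibble(m)
  out <- cbind(tibble(gene = rownames(m)), out)
  readr::write_tsv(as_tibble(out), path)
  invisible(path)
}

read_gene_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(x[-1])
  rownames(m) <- as.character(x[[1]])
  m
}
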