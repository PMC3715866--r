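#' Simulate a gene model along a synthetic genome
#'
#' Lays out `n_genes` genes of equal length on `n_chromosomes` autosome-like
#' chromosomes (round-robin block layout, fixed spacing). Fourteen marker
#' genes used by the suitability analysis (TP53, BRCA1/2, RB1, C11orf30,
#' CCNE1, KRAS, MYC and the seven non-HGSOC panel genes) are placed at
#' fixed, reproducible positions on chromosomes that carry no recurrent
#' copy-number event under the default cohort specification, so marker
#' calls are not confounded with the broad gains and losses.
#'
#' @param n_genes Total number of genes (at least 200).
#' @param n_chromosomes Number of chromosomes (default 22).
#' @param gene_length Gene length in bp.
#' @param spacing Start-to-start distance between adjacent genes in bp.
#' @return Gene model tibble (`gene`, `chrom`, `start`, `end`), plus
#'   attribute `"marker_index"` mapping marker symbols to row indices.
#' @export
simulate_gene_model <- function(n_genes = 2200, n_chromosomes = 22,
                                gene_length = 1e4, spacing = 1e5) {
  if (n_genes < 200) abort("n_genes must be at least 200")
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(n_chromosomes)), per_chrom)
  idx_in_chrom <- sequence(per_chrom)
  start <- (idx_in_chrom - 1) * spacing + 1
  g <- tibble(
    gene = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = chrom,
    start = start,
    end = start + gene_length - 1
  )
  # marker placement: gene -> (chromosome, fractional position within it)
  markers <- list(
    TP53 = c("17", 0.50), BRCA1 = c("17", 0.25), ERBB2 = c("17", 0.75),
    BRCA2 = c("13", 0.50), RB1 = c("13", 0.75), C11orf30 = c("11", 0.50),
    CCNE1 = c("19", 0.50), KRAS = c("12", 0.50), MYC = c("8", 0.50),
    ARID1A = c("1", 0.50), BRAF = c("7", 0.50), CTNNB1 = c("3", 0.25),
    PIK3CA = c("3", 0.75), PTEN = c("10", 0.50)
  )
  marker_index <- integer(0)
  for (nm in names(markers)) {
    cc <- markers[[nm]][1]
    frac <- as.numeric(markers[[nm]][2])
    rows <- which(g$chrom == cc)
    i <- rows[max(1, round(frac * length(rows)))]
    g$gene[i] <- nm
    marker_index[nm] <- i
  }
  g <- validate_gene_model(g)
  attr(g, "marker_index") <- marker_index
  g
}

#' Default recurrent copy-number events
#'
#' Six broad events covering whole chromosomes free of marker genes:
#' gains on chromosomes 2, 5 and 14 and losses on 4, 6 and 16, each with
#' amplitude 0.8 (log2) and prevalence 0.7. Together they span roughly a
#' quarter of the genome, giving carriers the extensive copy-number
#' alteration typical of high-grade serous tumours.
#'
#' @param gene_model A gene model from [simulate_gene_model()].
#' @return Tibble with columns `chrom`, `kind`, `amplitude`, `prevalence`,
#'   `from_gene`, `to_gene` (gene row indices).
#' @export
default_recurrent_events <- function(gene_model) {
  ev <- tibble(
    chrom = c("2", "5", "14", "4", "6", "16"),
    kind = c("gain", "gain", "gain", "loss", "loss", "loss"),
    amplitude = c(0.8, 0.8, 0.8, -0.8, -0.8, -0.8),
    prevalence = rep(0.7, 6)
  )
  ev$from_gene <- vapply(ev$chrom,
                         function(cc) min(which(gene_model$chrom == cc)),
                         numeric(1))
  ev$to_gene <- vapply(ev$chrom,
                       function(cc) max(which(gene_model$chrom == cc)),
                       numeric(1))
  ev
}

#' Specification of a synthetic tumour cohort
#'
#' Defaults emulate a high-grade serous ovarian cancer cohort: 316 tumours,
#' near-universal TP53 mutation (95% overall), a small flat-profile
#' TP53-wild-type subpopulation, broad recurrent gains and losses, a low
#' functional mutation rate (1.6 per Mb) over 30 Mb of covered exome, and
#' expression with a sparse tumour signature and no batch effect.
#'
#' @param n_tumours Cohort size.
#' @param n_genes,n_chromosomes Genome layout, see [simulate_gene_model()].
#' @param recurrent_events Event table; `NULL` for
#'   [default_recurrent_events()].
#' @param noise_sd Gaussian segment noise on the log2 scale.
#' @param tp53_mut_prob Overall probability that a tumour is TP53-mutant.
#' @param flat_tp53wt_fraction Target fraction of flat TP53-wild-type
#'   tumours; wild-type tumours are made flat first, so the realised flat
#'   fraction is at most `1 - tp53_mut_prob`.
#' @param background_mut_rate Functional mutations per Mb.
#' @param covered_mb Covered exome per sample, megabases.
#' @param class_mix Named probabilities over variant classes for background
#'   mutations (defaults: 70% missense, 10% silent, 10%
#'   frameshift/nonsense, 10% non-coding).
#' @param expr Expression parameters: `baseline_mean`, `baseline_sd`,
#'   `noise_sd`, `signature_fraction`, `signature_magnitude`, `spike_prob`.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumours = 316, n_genes = 2200, n_chromosomes = 22,
                        recurrent_events = NULL, noise_sd = 0.15,
                        tp53_mut_prob = 0.95, flat_tp53wt_fraction = 0.05,
                        background_mut_rate = 1.6, covered_mb = 30,
                        class_mix = default_class_mix(),
                        expr = list()) {
  expr <- modifyList(list(baseline_mean = 6, baseline_sd = 2, noise_sd = 1,
                          signature_fraction = 0.25, signature_magnitude = 6,
                          spike_prob = 0.3), expr)
  spec <- list(n_tumours = n_tumours, n_genes = n_genes,
               n_chromosomes = n_chromosomes,
               recurrent_events = recurrent_events, noise_sd = noise_sd,
               tp53_mut_prob = tp53_mut_prob,
               flat_tp53wt_fraction = flat_tp53wt_fraction,
               background_mut_rate = background_mut_rate,
               covered_mb = covered_mb, class_mix = class_mix, expr = expr)
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

default_class_mix <- function() {
  c(missense = 0.70, silent = 0.10, frameshift = 0.05, nonsense = 0.05,
    intron = 0.04, utr3 = 0.02, utr5 = 0.02, flank = 0.01, igr = 0.005,
    rna = 0.005)
}

functional_fraction <- function(class_mix) {
  sum(class_mix[names(class_mix) %in% functional_classes()]) / sum(class_mix)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_tumours < 1 || n_genes < 200 || n_chromosomes < 1) {
      abort("counts must be positive (n_genes at least 200)")
    }
    probs <- c(tp53_mut_prob, flat_tp53wt_fraction)
    if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
    if (noise_sd < 0 || background_mut_rate < 0 || covered_mb <= 0) {
      abort("noise_sd and background_mut_rate must be non-negative, covered_mb positive")
    }
    bad <- setdiff(names(class_mix), mutation_classes())
    if (length(bad) > 0) {
      abort(paste0("class_mix names outside the vocabulary: ",
                   paste(bad, collapse = ", ")))
    }
    if (!is.null(recurrent_events) &&
        any(!is.finite(recurrent_events$amplitude))) {
      abort("event amplitudes must be finite")
    }
  })
  invisible(spec)
}

#' Specification of a synthetic cell-line panel
#'
#' Defaults emulate a 47-line ovarian cancer panel as a mixture of three
#' archetypes: 12 HGSOC-like lines (copy-number profile equal to the
#' tumour-cohort mean plus noise, TP53-mutant, non-HGSOC panel clean), 30
#' non-HGSOC lines (flat profile, TP53 wild-type, 1-3 functional mutations
#' drawn from the seven-gene panel) and 5 hypermutators (flat profile,
#' functional mutation rate `lambda_high` per Mb). The expression batch
#' effect is a platform artefact applied to every cell line: sparse
#' positive activations (probability `spike_prob`) of a dedicated gene
#' subset, with magnitude `expression_batch_offset`; being sparse and
#' asymmetric it shifts per-gene means without moving per-gene medians,
#' which is what lets it survive robust z-scoring, as real platform
#' artefacts do.
#'
#' @param n_hgsoc,n_non_hgsoc,n_hypermutator Archetype counts.
#' @param lambda_background,lambda_high Functional mutations per Mb for
#'   ordinary lines and hypermutators (`lambda_high > lambda_background`).
#' @param expression_batch_offset Magnitude of the platform spike effect.
#' @param shared_programme_magnitude Magnitude with which HGSOC-like lines
#'   re-express the tumour signature (attenuated relative to tumours).
#' @param covered_mb Covered bases per line, megabases.
#' @param cna_noise_sd Per-gene noise of HGSOC-like profiles (log2).
#' @param flat_sd Segment noise of flat profiles (log2).
#' @param non_hgsoc_mut_range Range (min, max) of planted panel mutations
#'   per non-HGSOC line.
#' @param class_mix Background variant-class mixture.
#' @return A validated `panel_spec` list.
#' @export
panel_spec <- function(n_hgsoc = 12, n_non_hgsoc = 30, n_hypermutator = 5,
                       lambda_background = 4, lambda_high = 15,
                       expression_batch_offset = 12,
                       shared_programme_magnitude = 2,
                       covered_mb = 30, cna_noise_sd = 0.1, flat_sd = 0.05,
                       non_hgsoc_mut_range = c(1, 3),
                       class_mix = default_class_mix()) {
  spec <- list(n_hgsoc = n_hgsoc, n_non_hgsoc = n_non_hgsoc,
               n_hypermutator = n_hypermutator,
               lambda_background = lambda_background,
               lambda_high = lambda_high,
               expression_batch_offset = expression_batch_offset,
               shared_programme_magnitude = shared_programme_magnitude,
               covered_mb = covered_mb, cna_noise_sd = cna_noise_sd,
               flat_sd = flat_sd, non_hgsoc_mut_range = non_hgsoc_mut_range,
               class_mix = class_mix)
  if (any(c(n_hgsoc, n_non_hgsoc, n_hypermutator) < 0)) {
    abort("archetype counts must be non-negative")
  }
  if (n_hgsoc + n_non_hgsoc + n_hypermutator < 1) abort("empty panel")
  if (lambda_high <= lambda_background) {
    abort("lambda_high must exceed lambda_background")
  }
  if (covered_mb <= 0) abort("covered_mb must be positive")
  class(spec) <- "panel_spec"
  spec
}

# draw class labels for n background mutations
draw_classes <- function(n, class_mix) {
  sample(names(class_mix), n, replace = TRUE,
         prob = class_mix / sum(class_mix))
}

# draw a background catalogue for one sample over the allowed gene universe
draw_background_mutations <- function(sample_id, rate_per_mb, covered_bases,
                                      genes_allowed, class_mix) {
  total <- rpois(1, rate_per_mb * covered_bases / 1e6 /
                   functional_fraction(class_mix))
  if (total == 0) {
    return(data.frame(sample = character(0), gene = character(0),
                      class = character(0)))
  }
  data.frame(sample = sample_id,
             gene = sample(genes_allowed, total, replace = TRUE),
             class = draw_classes(total, class_mix))
}

# sparse positive activation ("spike") expression model shared by the
# tumour and cell-line generators
spike_expression <- function(x, gene_rows, magnitudes, magnitude, p) {
  sp <- matrix(rbinom(length(gene_rows) * ncol(x), 1, p),
               length(gene_rows), ncol(x))
  x[gene_rows, ] <- x[gene_rows, ] + magnitude * magnitudes * sp
  x
}

#' Generate a synthetic tumour cohort
#'
#' Realises segments, mutations, per-exon coverage, expression and truth
#' labels for a cohort under a [cohort_spec()]. Per tumour: recurrent
#' events are carried with their prevalence (Bernoulli), carried event
#' regions get the event amplitude plus Gaussian segment noise, and
#' baseline chromosomes are split into a few noisy segments. TP53 status
#' is Bernoulli(`tp53_mut_prob`) overall; wild-type tumours become flat
#' (no events, reduced noise) with probability
#' `flat_tp53wt_fraction / (1 - tp53_mut_prob)` capped at one, so the
#' wild-type subpopulation is predominantly flat while the overall mutant
#' fraction equals the configured probability. Background mutations are
#' Poisson with genes drawn uniformly (TP53 excluded: its status is
#' controlled by the explicit indicator). Coverage is per-exon with
#' fractions in \[0.7, 1\] and effective bases close to `covered_mb`.
#' Expression is a noisy baseline plus sparse positive activation of a
#' tumour signature gene subset; there is no batch effect within the
#' cohort.
#'
#' Identical `(spec, seed)` give bit-identical output; the generator uses
#' only its own local RNG state.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return List with `segments` (`cn_segments`), `mutations`
#'   (`mutation_catalog`), `coverage` (named list of per-exon
#'   `coverage_track`s), `expression` (`expr_matrix`, dataset label
#'   `"tumour"`), `gene_model`, `truth` (tibble: `sample`, `flat`,
#'   `tp53_mutant`), `signature` (list of signature gene symbols and
#'   per-gene magnitudes) and `events` (carrier matrix).
#' @export
generate_tumour_cohort <- function(spec = cohort_spec(), seed = 1) {
  validate_cohort_spec(spec)
  withr_seed(seed, {
    gm <- simulate_gene_model(spec$n_genes, spec$n_chromosomes)
    events <- spec$recurrent_events
    if (is.null(events)) events <- default_recurrent_events(gm)
    samples <- sprintf("TUM%03d", seq_len(spec$n_tumours))

    tp53 <- runif(spec$n_tumours) < spec$tp53_mut_prob
    p_flat_wt <- if (spec$tp53_mut_prob >= 1) 0 else {
      min(1, spec$flat_tp53wt_fraction / (1 - spec$tp53_mut_prob))
    }
    flat <- !tp53 & (runif(spec$n_tumours) < p_flat_wt)

    carriers <- matrix(runif(spec$n_tumours * nrow(events)) <
                         rep(events$prevalence, each = spec$n_tumours),
                       spec$n_tumours, nrow(events))
    carriers[flat, ] <- FALSE

    seg_list <- lapply(seq_len(spec$n_tumours), function(i) {
      simulate_tumour_segments(samples[i], gm, events, carriers[i, ],
                               if (flat[i]) spec$noise_sd * 0.3 else spec$noise_sd)
    })
    segments <- cn_segments(bind_rows(seg_list))

    coverage <- lapply(samples, function(s) {
      simulate_per_exon_track(s, spec$covered_mb)
    })
    names(coverage) <- samples

    genes_bg <- setdiff(gm$gene, "TP53")
    mut_list <- lapply(seq_len(spec$n_tumours), function(i) {
      bg <- draw_background_mutations(samples[i], spec$background_mut_rate,
                                      bases_covered(coverage[[samples[i]]]),
                                      genes_bg, spec$class_mix)
      if (tp53[i]) {
        bg <- bind_rows(bg, data.frame(sample = samples[i], gene = "TP53",
                                       class = sample(c("missense", "nonsense"),
                                                      1, prob = c(0.8, 0.2))))
      }
      bg
    })
    mutations <- mutation_catalog(bind_rows(mut_list))

    ex <- spec$expr
    n_sig <- round(ex$signature_fraction * spec$n_genes)
    sig_rows <- sort(sample(spec$n_genes, n_sig))
    sig_mag <- abs(rnorm(n_sig))
    baseline <- rnorm(spec$n_genes, ex$baseline_mean, ex$baseline_sd)
    values <- matrix(rnorm(spec$n_genes * spec$n_tumours, baseline,
                           ex$noise_sd),
                     spec$n_genes, spec$n_tumours,
                     dimnames = list(gm$gene, samples))
    values <- spike_expression(values, sig_rows, sig_mag,
                               ex$signature_magnitude, ex$spike_prob)
    expression <- expr_matrix(values, "tumour")

    list(segments = segments, mutations = mutations, coverage = coverage,
         expression = expression, gene_model = gm,
         truth = tibble(sample = samples, flat = flat, tp53_mutant = tp53),
         signature = list(genes = gm$gene[sig_rows], magnitudes = sig_mag),
         events = carriers)
  })
}

# run code with a local, restored RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# segments of one tumour: event chromosomes become one segment at the event
# amplitude (carriers) or baseline; other chromosomes are split into 1-3
# noisy baseline segments at random gene boundaries. Plain vectors for
# speed; the caller assembles one table for the whole cohort.
simulate_tumour_segments <- function(sample_id, gm, events, carried,
                                     noise_sd) {
  chroms <- unique(gm$chrom)
  chrom_v <- character(0); start_v <- numeric(0); end_v <- numeric(0)
  mean_v <- numeric(0)
  for (cc in chroms) {
    rows <- which(gm$chrom == cc)
    ev <- which(events$chrom == cc)
    if (length(ev) == 1 && carried[ev]) {
      chrom_v <- c(chrom_v, cc)
      start_v <- c(start_v, gm$start[rows[1]])
      end_v <- c(end_v, gm$end[rows[length(rows)]])
      mean_v <- c(mean_v, events$amplitude[ev] + rnorm(1, 0, noise_sd))
    } else {
      # contiguous tiling of the chromosome's gene span: each segment runs
      # up to one base before the next segment's start
      k <- sample(1:3, 1)
      cutpoints <- sort(sample(length(rows) - 1, k - 1))
      bounds <- c(0, cutpoints, length(rows))
      starts <- gm$start[rows[bounds[-length(bounds)] + 1]]
      ends <- c(starts[-1] - 1, gm$end[rows[length(rows)]])
      chrom_v <- c(chrom_v, rep(cc, k))
      start_v <- c(start_v, starts)
      end_v <- c(end_v, ends)
      mean_v <- c(mean_v, rnorm(k, 0, noise_sd))
    }
  }
  data.frame(sample = sample_id, chrom = chrom_v, start = start_v,
             end = end_v, seg_mean = mean_v)
}

# per-exon coverage with effective bases close to covered_mb
simulate_per_exon_track <- function(sample_id, covered_mb, n_exons = 200) {
  u <- runif(n_exons, 0.7, 1)
  len <- round(covered_mb * 1e6 / n_exons / u)
  coverage_track(sample_id, "per_exon",
                 exons = data.frame(length = len, fraction = u))
}

#' Generate a synthetic cell-line panel
#'
#' Realises the archetype mixture of a [panel_spec()] against a tumour
#' cohort: HGSOC-like lines carry per-gene segments equal to the cohort
#' mean profile plus noise, an explicit functional TP53 mutation, and
#' background mutations that avoid TP53 and the non-HGSOC panel;
#' non-HGSOC lines are flat, TP53 wild-type, with 1-3 planted functional
#' panel mutations plus background; hypermutators are flat with background
#' drawn over all genes at `lambda_high` per Mb. Coverage is per-base
#' (one covered run per chromosome summing to `covered_mb`). Expression
#' adds the platform spike effect to every line; HGSOC-like lines
#' additionally re-express the tumour signature at an attenuated
#' magnitude, other lines express their own signature gene set.
#'
#' @param spec A `panel_spec`.
#' @param tumour_mean_profile Named gene-level vector from
#'   [mean_cna_profile()] of the tumour cohort.
#' @param seed Integer seed.
#' @param gene_model Gene model shared with the cohort.
#' @param tumour_signature The cohort's `signature` element (genes and
#'   magnitudes); `NULL` for an independent signature.
#' @return List with `segments`, `mutations`, `coverage` (per-base
#'   tracks), `expression` (`expr_matrix`, dataset label `"cell_line"`),
#'   and `truth` (tibble: `sample`, `archetype`).
#' @export
generate_cell_line_panel <- function(spec = panel_spec(),
                                     tumour_mean_profile, seed = 1,
                                     gene_model,
                                     tumour_signature = NULL) {
  withr_seed(seed + 1000L, {
    gm <- gene_model
    n <- spec$n_hgsoc + spec$n_non_hgsoc + spec$n_hypermutator
    samples <- sprintf("CL%03d", seq_len(n))
    archetype <- rep(c("hgsoc_like", "non_hgsoc", "hypermutator"),
                     c(spec$n_hgsoc, spec$n_non_hgsoc, spec$n_hypermutator))

    seg_list <- lapply(seq_len(n), function(i) {
      if (archetype[i] == "hgsoc_like") {
        prof <- tumour_mean_profile[gm$gene]
        prof[is.na(prof)] <- 0
        data.frame(sample = samples[i], chrom = gm$chrom, start = gm$start,
                   end = gm$end,
                   seg_mean = as.numeric(prof) + rnorm(nrow(gm), 0,
                                                       spec$cna_noise_sd))
      } else {
        chroms <- unique(gm$chrom)
        data.frame(sample = samples[i], chrom = chroms,
                   start = vapply(chroms, function(cc)
                     min(gm$start[gm$chrom == cc]), numeric(1)),
                   end = vapply(chroms, function(cc)
                     max(gm$end[gm$chrom == cc]), numeric(1)),
                   seg_mean = rnorm(length(chroms), 0, spec$flat_sd))
      }
    })
    segments <- cn_segments(bind_rows(seg_list))

    coverage <- lapply(samples, function(s) {
      simulate_per_base_track(s, spec$covered_mb, unique(gm$chrom))
    })
    names(coverage) <- samples

    panel <- non_hgsoc_genes()
    mut_list <- lapply(seq_len(n), function(i) {
      bc <- bases_covered(coverage[[samples[i]]])
      if (archetype[i] == "hgsoc_like") {
        bg <- draw_background_mutations(
          samples[i], spec$lambda_background, bc,
          setdiff(gm$gene, c("TP53", panel)), spec$class_mix)
        bind_rows(bg, data.frame(sample = samples[i], gene = "TP53",
                                 class = sample(c("missense", "nonsense"), 1,
                                                prob = c(0.8, 0.2))))
      } else if (archetype[i] == "non_hgsoc") {
        bg <- draw_background_mutations(
          samples[i], spec$lambda_background, bc,
          setdiff(gm$gene, "TP53"), spec$class_mix)
        k <- sample(seq(spec$non_hgsoc_mut_range[1],
                        spec$non_hgsoc_mut_range[2]), 1)
        planted <- data.frame(sample = samples[i],
                              gene = sample(panel, k),
                              class = sample(functional_classes(), k,
                                             replace = TRUE))
        bind_rows(bg, planted)
      } else {
        draw_background_mutations(samples[i], spec$lambda_high, bc,
                                  gm$gene, spec$class_mix)
      }
    })
    mutations <- mutation_catalog(bind_rows(mut_list))

    n_genes <- nrow(gm)
    batch_rows <- sort(sample(n_genes, round(0.25 * n_genes)))
    batch_mag <- abs(rnorm(length(batch_rows)))
    if (is.null(tumour_signature)) {
      sig_rows <- sort(sample(setdiff(seq_len(n_genes), batch_rows),
                              round(0.25 * n_genes)))
      sig_mag <- abs(rnorm(length(sig_rows)))
    } else {
      sig_rows <- match(tumour_signature$genes, gm$gene)
      sig_mag <- tumour_signature$magnitudes
    }
    other_rows <- sort(sample(setdiff(seq_len(n_genes),
                                      c(batch_rows, sig_rows)),
                              min(round(0.25 * n_genes),
                                  n_genes - length(batch_rows) -
                                    length(sig_rows))))
    other_mag <- abs(rnorm(length(other_rows)))

    baseline <- rnorm(n_genes, 6, 2)
    values <- matrix(rnorm(n_genes * n, baseline, 1), n_genes, n,
                     dimnames = list(gm$gene, samples))
    is_hg <- archetype == "hgsoc_like"
    if (any(is_hg)) {
      values[, is_hg] <- spike_expression(
        values[, is_hg, drop = FALSE], sig_rows, sig_mag,
        spec$shared_programme_magnitude, 0.3)
    }
    if (any(!is_hg)) {
      values[, !is_hg] <- spike_expression(
        values[, !is_hg, drop = FALSE], other_rows, other_mag,
        spec$shared_programme_magnitude, 0.3)
    }
    values <- spike_expression(values, batch_rows, batch_mag,
                               spec$expression_batch_offset, 0.3)
    expression <- expr_matrix(values, "cell_line")

    list(segments = segments, mutations = mutations, coverage = coverage,
         expression = expression,
         truth = tibble(sample = samples, archetype = archetype))
  })
}

# one covered run per chromosome, total = covered_mb megabases
simulate_per_base_track <- function(sample_id, covered_mb, chroms) {
  per <- diff(round(seq(0, covered_mb * 1e6, length.out = length(chroms) + 1)))
  start <- sample(1e4, length(chroms))
  gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start = start, width = pmax(per, 1)))
  coverage_track(sample_id, "per_base", positions = gr)
}
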