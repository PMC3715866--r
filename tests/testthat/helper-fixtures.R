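# Small in-code fixtures shared across the test files.

# write a tab-separated file and return its path
write_tmp_tsv <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  readr::write_tsv(df, path)
  path
}

# a tiny two-sample segment table on chromosomes 1 and 2
tiny_segments <- function() {
  cn_segments(data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2"),
    chrom = c("1", "1", "2", "1", "2"),
    start = c(1, 201, 1, 1, 1),
    end = c(100, 300, 150, 300, 150),
    seg_mean = c(0.5, 0.1, -0.4, 0.0, 1.2)
  ))
}

# random non-overlapping segments for one sample; small coordinates so a
# per-base oracle stays cheap
random_segments <- function(sample_id, n, max_len = 200, chroms = 1:4) {
  chrom <- sort(sample(as.character(chroms), n, replace = TRUE))
  starts <- integer(n); ends <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    len <- sample(2:max_len, length(idx), replace = TRUE)
    gap <- sample(50, length(idx), replace = TRUE)
    ends_local <- cumsum(len + gap)
    starts[idx] <- ends_local - len + 1
    ends[idx] <- ends_local
  }
  cn_segments(data.frame(sample = sample_id, chrom = chrom, start = starts,
                         end = ends,
                         seg_mean = round(rnorm(n, 0, 0.5), 3)))
}

# per-base brute-force FGA: expand every segment to its bases
fga_per_base_oracle <- function(segments, threshold) {
  altered <- 0; total <- 0
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i] + 1
    total <- total + len
    if (abs(segments$seg_mean[i]) > threshold) altered <- altered + len
  }
  altered / total
}

# per-base brute-force gene mapping for one sample
gene_map_per_base_oracle <- function(segments, genes) {
  out <- rep(NA_real_, nrow(genes))
  for (g in seq_len(nrow(genes))) {
    vals <- numeric(0)
    for (i in which(segments$chrom == genes$chrom[g])) {
      lo <- max(segments$start[i], genes$start[g])
      hi <- min(segments$end[i], genes$end[g])
      if (lo <= hi) vals <- c(vals, rep(segments$seg_mean[i], hi - lo + 1))
    }
    if (length(vals) > 0) out[g] <- mean(vals)
  }
  names(out) <- genes$gene
  out
}

# small expression matrix with named genes/samples
tiny_expression <- function(n_genes = 20, n_samples = 6, dataset = "d1",
                            seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("%s_s%02d", dataset, seq_len(n_samples))))
  expr_matrix(m, dataset)
}

# a valid marker row with everything FALSE except the named flags
marker_row <- function(sample, true_flags = character(0)) {
  panels <- default_marker_panels()
  cols <- c(paste0("mut_", unique(c(panels$hgsoc_mut, panels$rb1,
                                    panels$non_hgsoc))),
            paste0("amp_", panels$hgsoc_amp), paste0("del_", panels$rb1))
  row <- as.list(setNames(rep(FALSE, length(cols)), cols))
  for (f in true_flags) row[[f]] <- TRUE
  tibble::as_tibble(c(list(sample = sample), row))
}

# list of all permutations of 1..n, by plain head-recursion (independent of
# any package code)
enumerate_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (tail in enumerate_permutations(n - 1)) {
      out[[length(out) + 1]] <- c(first, rest[tail])
    }
  }
  out
}

# shared 100-seed parameter-recovery run, computed once per test session
recovery_cache <- new.env(parent = emptyenv())

# the default-spec tumour cohort shared by the acceptance checks
recovery_cohort <- function() {
  if (is.null(recovery_cache$cohort)) {
    tum <- generate_tumour_cohort(cohort_spec(), seed = 20260926)
    mp <- mean_cna_profile(map_segments_to_genes(tum$segments,
                                                 tum$gene_model))
    recovery_cache$cohort <- list(tum = tum, mp = mp)
  }
  recovery_cache$cohort
}

recovery_results <- function(n_seeds = 100) {
  key <- paste0("seeds", n_seeds)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  co <- recovery_cohort()
  tum <- co$tum
  mp <- co$mp
  res <- lapply(seq_len(n_seeds), function(seed) {
    cl <- generate_cell_line_panel(panel_spec(), mp, seed = seed,
                                   gene_model = tum$gene_model,
                                   tumour_signature = tum$signature)
    cell_cna <- map_segments_to_genes(cl$segments, tum$gene_model)
    A <- cor(cell_cna, mp[rownames(cell_cna)],
             use = "pairwise.complete.obs")[, 1]
    burden <- mutation_burden_table(filter_functional(cl$mutations),
                                    cl$coverage)
    fga <- fraction_genome_altered(cl$segments, 0.3)
    hyper <- classify_hypermutated(burden, fga)
    markers <- suppressWarnings(marker_status(cl$mutations, cell_cna))
    sim <- tibble::tibble(cell_line = names(A), corr_with_mean_profile = A)
    comp <- suitability_score(suitability_components(sim, markers, hyper))
    rk <- rank_and_tier(comp)
    truth <- cl$truth
    ord_arch <- truth$archetype[match(rk$cell_line, truth$sample)]
    hg_pos <- which(ord_arch == "hgsoc_like")
    other_pos <- which(ord_arch != "hgsoc_like")
    hyper_truth <- truth$archetype == "hypermutator"
    hyper_call <- hyper$hypermutated[match(truth$sample, hyper$sample)]
    n_hyper_func <- vapply(truth$sample[hyper_truth], function(s) {
      sum(filter_functional(cl$mutations)$sample == s)
    }, numeric(1))
    list(separated = max(hg_pos) < min(other_pos),
         sensitivity_ok = all(hyper_call[hyper_truth]),
         specificity_ok = !any(hyper_call[!hyper_truth]),
         hyper_counts = n_hyper_func)
  })
  recovery_cache[[key]] <- res
  res
}
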