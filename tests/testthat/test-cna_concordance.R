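# fraction genome altered, gene mapping and copy-number similarity

test_that("FGA evaluates the length-weighted altered fraction", {
  seg <- cn_segments(data.frame(
    sample = "s1", chrom = "1", start = c(1, 201, 401),
    end = c(100, 300, 500), seg_mean = c(0.5, 0.1, -0.4)))
  expect_equal(fraction_genome_altered(seg, 0.2)$fga, 200 / 300)

  flat <- cn_segments(data.frame(sample = "s1", chrom = "1",
                                 start = c(1, 201), end = c(100, 300),
                                 seg_mean = c(0, 0)))
  expect_equal(fraction_genome_altered(flat, 0.2)$fga, 0)
  hot <- cn_segments(data.frame(sample = "s1", chrom = "1",
                                start = c(1, 201), end = c(100, 300),
                                seg_mean = c(0.9, -0.9)))
  expect_equal(fraction_genome_altered(hot, 0.2)$fga, 1)

  # a segment sitting exactly at the threshold is unaltered
  at <- cn_segments(data.frame(sample = "s1", chrom = "1", start = 1,
                               end = 100, seg_mean = 0.2))
  expect_equal(fraction_genome_altered(at, 0.2)$fga, 0)

  expect_error(fraction_genome_altered(seg, -1), "positive")
  expect_error(fraction_genome_altered(seg[0, ], 0.2), "missing|empty")
})

test_that("FGA matches a per-base oracle and is monotone in the threshold", {
  set.seed(21)
  seg <- random_segments("s1", 1000, chroms = 1:10)
  expect_equal(fraction_genome_altered(seg, 0.3)$fga,
               fga_per_base_oracle(seg, 0.3))
  grid <- seq(0.05, 1, by = 0.05)
  fgas <- vapply(grid, function(t) fraction_genome_altered(seg, t)$fga,
                 numeric(1))
  expect_true(all(fgas >= 0 & fgas <= 1))
  expect_true(all(diff(fgas) <= 0))
})

test_that("gene mapping weights segment means by overlap length", {
  genes <- data.frame(gene = c("gA", "gB"), chrom = "1",
                      start = c(10, 180), end = c(50, 260))
  seg <- cn_segments(data.frame(
    sample = "s1", chrom = "1", start = c(1, 201), end = c(200, 400),
    seg_mean = c(0.7, 0.4)))
  m <- map_segments_to_genes(seg, genes)
  # gA fully inside the first segment
  expect_equal(m["gA", "s1"], 0.7)
  # gB: 21 bases in segment 1 (cn 0.7 -> replaced by 0.0 below), rest in 2
  seg2 <- cn_segments(data.frame(
    sample = "s1", chrom = "1", start = c(1, 201), end = c(200, 400),
    seg_mean = c(0.0, 0.4)))
  genes2 <- data.frame(gene = "gC", chrom = "1", start = 181, end = 260)
  # 20 of 80 bases at 0.0, 60 of 80 at 0.4 -> weighted mean 0.3
  m2 <- map_segments_to_genes(seg2, genes2)
  expect_equal(m2["gC", "s1"], 0.3)
  # gene overlapping no segment is missing
  genes3 <- data.frame(gene = "gD", chrom = "2", start = 1, end = 100)
  expect_true(is.na(map_segments_to_genes(seg, genes3)["gD", "s1"]))
})

test_that("gene mapping agrees with a per-base oracle across samples", {
  set.seed(22)
  n_genes <- 200
  genes <- data.frame(gene = sprintf("g%03d", seq_len(n_genes)),
                      chrom = as.character(sample(1:4, n_genes,
                                                  replace = TRUE)),
                      start = sample(2000, n_genes))
  genes$end <- genes$start + sample(30:80, n_genes, replace = TRUE)
  genes <- genes[order(genes$chrom, genes$start), ]
  genes <- genes[!duplicated(genes$gene), ]
  segs <- dplyr::bind_rows(lapply(sprintf("s%02d", 1:10), function(s) {
    random_segments(s, 60, max_len = 150, chroms = 1:4)
  }))
  segs <- cn_segments(segs)
  m <- map_segments_to_genes(segs, genes)
  for (s in c("s01", "s05", "s10")) {
    oracle <- gene_map_per_base_oracle(segs[segs$sample == s, ], genes)
    expect_equal(unname(m[, s]), unname(oracle[rownames(m)]),
                 tolerance = 1e-12)
  }
  # largest-overlap rule picks the dominant segment's value
  m_lo <- map_segments_to_genes(segs, genes, rule = "largest_overlap")
  expect_true(all(is.na(m) == is.na(m_lo)))
})

test_that("mean profile averages present values and drops empty genes", {
  m <- rbind(g1 = c(0.2, 0.6), g2 = c(0.4, NA), g3 = c(NA, NA))
  colnames(m) <- c("t1", "t2")
  mp <- mean_cna_profile(m)
  expect_equal(mp[["g1"]], 0.4)
  expect_equal(mp[["g2"]], 0.4)   # mean equals the single present value
  expect_false("g3" %in% names(mp))
  expect_error(mean_cna_profile(m, cohort = character(0)), "empty")
  # brute-force check on a seeded matrix
  set.seed(23)
  big <- matrix(rnorm(500 * 8), 500, 8,
                dimnames = list(sprintf("g%03d", 1:500),
                                sprintf("t%d", 1:8)))
  big[sample(length(big), 300)] <- NA
  mp2 <- mean_cna_profile(big)
  for (g in sample(names(mp2), 20)) {
    expect_equal(mp2[[g]], mean(big[g, ], na.rm = TRUE))
  }
})

test_that("similarity reports the three correlation measures", {
  set.seed(24)
  genes <- sprintf("g%02d", 1:30)
  tum <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(genes, paste0("t", 1:5)))
  mp <- mean_cna_profile(tum)
  prof <- setNames(tum[, "t3"], genes)     # identical to one tumour
  sim <- cna_similarity(prof, tum, mp, cell_line = "cl1")
  expect_equal(sim$per_tumour_correlations[["t3"]], 1)
  expect_equal(sim$max_single_tumour_correlation, 1)
  expect_equal(sim$median_correlation,
               median(sim$per_tumour_correlations))
  expect_true(sim$median_correlation >=
                min(sim$per_tumour_correlations) &&
              sim$median_correlation <=
                max(sim$per_tumour_correlations))
  # anti-symmetric against the mean profile
  sim2 <- cna_similarity(-mp, tum, mp)
  expect_equal(sim2$corr_with_mean_profile, -1)
})

test_that("similarity median matches brute force over a cohort", {
  set.seed(25)
  genes <- sprintf("g%03d", 1:120)
  tum <- matrix(rnorm(120 * 100), 120, 100,
                dimnames = list(genes, sprintf("t%03d", 1:100)))
  cells <- matrix(rnorm(120 * 40), 120, 40,
                  dimnames = list(genes, sprintf("c%02d", 1:40)))
  tum[sample(length(tum), 400)] <- NA
  mp <- mean_cna_profile(tum)
  tab <- cna_similarity_table(cells, tum, mp)
  for (j in c(1, 17, 40)) {
    rs <- vapply(colnames(tum), function(t) {
      ok <- !is.na(tum[, t])
      cor(cells[ok, j], tum[ok, t])
    }, numeric(1))
    expect_equal(tab$median_correlation[j], median(rs), tolerance = 1e-12)
  }
})

test_that("similarity rejects degenerate inputs rather than guessing", {
  genes <- c("g1", "g2", "g3", "g4")
  tum <- matrix(rnorm(8), 4, 2, dimnames = list(genes, c("t1", "t2")))
  mp <- mean_cna_profile(tum)
  short <- setNames(c(1, 2), c("g1", "g2"))
  expect_error(cna_similarity(short, tum, mp), "fewer than 3")
  # a zero-variance tumour yields an undefined correlation, excluded from
  # the median rather than silently treated as 0
  tum2 <- tum
  tum2[, "t2"] <- 0.5
  prof <- setNames(rnorm(4), genes)
  expect_warning(sim <- cna_similarity(prof, tum2, mean_cna_profile(tum)),
                 "zero variance")
  expect_true(is.na(sim$per_tumour_correlations[["t2"]]))
  expect_equal(sim$median_correlation,
               sim$per_tumour_correlations[["t1"]])
})

test_that("high-level amplification uses a strict inequality", {
  expect_true(call_high_level_amplification(1.2, 1.0))
  expect_false(call_high_level_amplification(1.0, 1.0))
  expect_false(call_high_level_amplification(-2.0, 1.0))
  expect_equal(call_high_level_amplification(c(0.5, 1.5), 1.0),
               c(FALSE, TRUE))
})
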