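# functional filtering, coverage-corrected burden and marker flags

test_that("functional filter removes the excluded classes and is idempotent", {
  cat_ <- mutation_catalog(data.frame(
    sample = "s1", gene = paste0("G", 1:4),
    class = c("missense", "silent", "intron", "frameshift")))
  f <- filter_functional(cat_)
  expect_setequal(f$class, c("missense", "frameshift"))
  expect_equal(as.data.frame(filter_functional(f)), as.data.frame(f))

  all_silent <- mutation_catalog(data.frame(sample = "s1", gene = "G1",
                                            class = rep("silent", 3)))
  expect_equal(nrow(filter_functional(all_silent)), 0)
})

test_that("filtered counts match a brute-force tally on a seeded catalogue", {
  set.seed(31)
  classes <- sample(mutation_classes(), 500, replace = TRUE)
  cat_ <- mutation_catalog(data.frame(
    sample = sample(paste0("s", 1:6), 500, replace = TRUE),
    gene = sample(paste0("G", 1:50), 500, replace = TRUE),
    class = classes))
  f <- filter_functional(cat_)
  expect_equal(nrow(f), sum(!classes %in% c("intron", "utr5", "utr3",
                                            "flank", "igr", "silent",
                                            "rna")))
})

test_that("bases_covered handles both dialects", {
  pe <- coverage_track("s1", "per_exon",
                       exons = data.frame(length = c(1000, 500),
                                          fraction = c(0.8, 1.0)))
  expect_equal(bases_covered(pe), 1300)
  pb <- coverage_track("s1", "per_base", positions = c(2L, 3L, 5L))
  expect_equal(bases_covered(pb), 3)
  # full coverage reduces to the plain length sum
  full <- coverage_track("s1", "per_exon",
                         exons = data.frame(length = c(123, 456, 789),
                                            fraction = 1))
  expect_equal(bases_covered(full), 123 + 456 + 789)
  # rounding happens once, on the real-arithmetic sum
  pe2 <- coverage_track("s1", "per_exon",
                        exons = data.frame(length = rep(3, 3),
                                           fraction = rep(0.5, 3)))
  expect_equal(bases_covered(pe2), round(4.5))
})

test_that("mutation frequency is the coverage-corrected rate per Mb", {
  cat_ <- filter_functional(mutation_catalog(data.frame(
    sample = "s1", gene = paste0("G", 1:10), class = "missense")))
  tr <- coverage_track("s1", "per_exon",
                       exons = data.frame(length = 2e6, fraction = 1))
  b <- mutation_frequency(cat_, tr)
  expect_equal(b$frequency_per_mb, 5.0)
  expect_equal(b$n_functional, 10)

  empty <- filter_functional(mutation_catalog(
    data.frame(sample = character(0), gene = character(0),
               class = character(0))))
  expect_equal(mutation_frequency(empty, tr)$frequency_per_mb, 0)
})

test_that("mutation frequency refuses unfiltered input and bad pairs", {
  cat_ <- mutation_catalog(data.frame(sample = "s1", gene = "G1",
                                      class = "silent"))
  tr <- coverage_track("s1", "per_exon",
                       exons = data.frame(length = 1e6, fraction = 1))
  expect_error(mutation_frequency(cat_, tr), "functional-filtered")
  expect_equal(
    mutation_frequency(cat_, tr, acknowledge_unfiltered = TRUE)$n_functional,
    1)
  other <- filter_functional(mutation_catalog(
    data.frame(sample = "sX", gene = "G1", class = "missense")))
  expect_error(mutation_frequency(other, tr), "mismatch")
})

test_that("frequency is linear in count and halves when coverage doubles", {
  set.seed(32)
  tr1 <- coverage_track("s1", "per_exon",
                        exons = data.frame(length = rep(1e5, 10),
                                           fraction = runif(10, 0.4, 0.5)))
  tr2 <- coverage_track("s1", "per_exon",
                        exons = data.frame(length = tr1$exons$length,
                                           fraction = 2 * tr1$exons$fraction))
  make_cat <- function(n) filter_functional(mutation_catalog(
    data.frame(sample = "s1", gene = paste0("G", seq_len(n)),
               class = "missense")))
  f1 <- mutation_frequency(make_cat(40), tr1)$frequency_per_mb
  f2 <- mutation_frequency(make_cat(40), tr2)$frequency_per_mb
  expect_equal(f1 / f2, 2, tolerance = 1e-5)  # covered bases round once
  f3 <- mutation_frequency(make_cat(80), tr1)$frequency_per_mb
  expect_equal(f3, 2 * f1, tolerance = 1e-12)
})

test_that("marker flags reflect mutations, amplifications and deletions", {
  cat_ <- mutation_catalog(data.frame(
    sample = c("s1", "s1", "s2"),
    gene = c("TP53", "PTEN", "RB1"),
    class = c("missense", "silent", "frameshift")))
  cna <- matrix(c(1.4, -1.6, 0.2, 0.0), nrow = 2,
                dimnames = list(c("CCNE1", "RB1"), c("s1", "s2")))
  ms <- suppressWarnings(marker_status(cat_, cna))
  expect_true(ms$mut_TP53[ms$sample == "s1"])
  expect_false(ms$mut_PTEN[ms$sample == "s1"])   # silent does not count
  expect_true(ms$amp_CCNE1[ms$sample == "s1"])
  expect_false(ms$amp_CCNE1[ms$sample == "s2"])
  expect_true(ms$del_RB1[ms$sample == "s1"])
  expect_true(ms$mut_RB1[ms$sample == "s2"])
  # genes absent everywhere warn and yield NA
  expect_warning(marker_status(cat_, cna[1, , drop = FALSE]), "absent")
})

test_that("marker flags equal a brute-force recomputation on a seeded panel", {
  set.seed(33)
  genes <- c(unlist(default_marker_panels()), paste0("G", 1:20))
  samples <- sprintf("s%02d", 1:30)
  cat_ <- mutation_catalog(data.frame(
    sample = sample(samples, 400, replace = TRUE),
    gene = sample(genes, 400, replace = TRUE),
    class = sample(mutation_classes(), 400, replace = TRUE)))
  cna <- matrix(rnorm(length(genes) * 30, 0, 0.8), length(genes), 30,
                dimnames = list(genes, samples))
  ms <- marker_status(cat_, cna)
  f <- cat_[!(cat_$class %in% excluded_classes()), ]
  for (s in sample(samples, 6)) {
    for (g in c("TP53", "PTEN", "KRAS")) {
      expect_identical(ms[[paste0("mut_", g)]][ms$sample == s],
                       any(f$gene == g & f$sample == s))
    }
    expect_identical(ms$amp_MYC[ms$sample == s],
                     unname(cna["MYC", s] > 1))
    expect_identical(ms$del_RB1[ms$sample == s],
                     unname(cna["RB1", s] < -1))
  }
  # monotone: adding a qualifying record never unsets a flag
  extra <- mutation_catalog(rbind(as.data.frame(cat_)[1:3],
                                  data.frame(sample = "s01", gene = "BRAF",
                                             class = "missense")))
  ms2 <- marker_status(extra, cna)
  was_true <- which(as.matrix(ms[-1]) == TRUE)
  expect_true(all(as.matrix(ms2[-1])[was_true] == TRUE))
})
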