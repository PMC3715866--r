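# robust z-scores, variable-gene selection, clustering, PCA, expression
# ranking and the Kendall concordance test

test_that("robust z-scores centre on the median and scale by plain MAD", {
  em <- expr_matrix(matrix(c(1, 2, 4), 1, 3,
                           dimnames = list("g1", c("a", "b", "c"))))
  z <- robust_z(em)
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 2))

  m2 <- rbind(g1 = c(1, 2, 4), g2 = c(5, 5, 5))
  colnames(m2) <- c("a", "b", "c")
  two <- expr_matrix(m2, dataset = "d")
  expect_message(z2 <- robust_z(two), "1 gene")
  expect_false("g2" %in% rownames(z2$values))

  # the consistency-factor variant scales by 1.4826
  zc <- robust_z(em, mad_scale = "consistent")
  expect_equal(unname(zc$values["g1", ]), c(-1, 0, 2) / 1.4826)
})

test_that("retained genes have median 0 and MAD 1 after z-scoring", {
  z <- robust_z(tiny_expression(50, 9))
  meds <- apply(z$values, 1, median)
  mads <- apply(z$values, 1, function(v) median(abs(v - median(v))))
  expect_lt(max(abs(meds)), 1e-12)
  expect_lt(max(abs(mads - 1)), 1e-12)
})

test_that("IQR selection keeps the most variable genes deterministically", {
  m <- rbind(g1 = c(0, 5, 10, 15), g2 = c(0, 1, 1, 2), g3 = c(0, 3, 3, 6))
  colnames(m) <- paste0("s", 1:4)
  em <- expr_matrix(m)
  sel <- select_top_iqr(em, 2)
  expect_setequal(rownames(sel$values), c("g1", "g3"))
  expect_identical(rownames(select_top_iqr(em, 3)$values),
                   c("g1", "g3", "g2"))
  expect_error(select_top_iqr(em, 4), "exceeds")

  # brute-force oracle on a larger seeded matrix
  big <- tiny_expression(2000, 12, seed = 7)
  sel2 <- select_top_iqr(big, 500)
  iqr <- apply(big$values, 1, function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    q[2] - q[1]
  })
  expected <- rownames(big$values)[order(-iqr, rownames(big$values))][1:500]
  expect_identical(rownames(sel2$values), expected)
})

test_that("correlation distances are 1 - r with the expected geometry", {
  set.seed(51)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[, 2] <- m[, 1]          # duplicate
  m[, 3] <- -m[, 1]         # anti-correlated
  d <- correlation_distance_matrix(expr_matrix(m))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), colnames(m)))
  expect_true(all(d >= 0 & d <= 2))
  # brute force
  big <- tiny_expression(60, 20, seed = 8)
  db <- correlation_distance_matrix(big)
  for (i in 1:5) {
    for (j in 6:10) {
      expect_equal(db[i, j], 1 - cor(big$values[, i], big$values[, j]),
                   tolerance = 1e-12)
    }
  }
  flat <- m; flat[, 4] <- 3
  expect_error(correlation_distance_matrix(expr_matrix(flat)), "s4")
})

test_that("hierarchical clustering recovers planted structure", {
  # forced merge order: the close pair merges first under complete linkage
  d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- hierarchical_cluster(d, "complete")
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
  expect_equal(nrow(tree$merge), 2)
  expect_true(all(diff(tree$height) >= 0))

  # two well-separated planted groups are recovered exactly at k = 2
  set.seed(52)
  pattern_a <- c(rep(5, 30), rep(0, 30))
  pattern_b <- c(rep(0, 30), rep(5, 30))
  m <- sapply(1:12, function(i) {
    (if (i <= 6) pattern_a else pattern_b) + rnorm(60, 0, 0.2)
  })
  rownames(m) <- paste0("g", 1:60)
  colnames(m) <- paste0("s", 1:12)
  dm <- correlation_distance_matrix(expr_matrix(m))
  for (lk in c("ward", "complete")) {
    ct <- cut_clusters(hierarchical_cluster(dm, lk), 2)
    expect_equal(length(unique(ct[1:6])), 1)
    expect_equal(length(unique(ct[7:12])), 1)
    expect_false(ct[1] == ct[7])
  }
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("clustering is invariant to input sample order", {
  set.seed(53)
  em <- tiny_expression(40, 10, seed = 9)
  d <- correlation_distance_matrix(em)
  perm <- sample(10)
  d2 <- d[perm, perm]
  t1 <- hierarchical_cluster(d, "ward")
  t2 <- hierarchical_cluster(d2, "ward")
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
  c1 <- cut_clusters(t1, 3)
  c2 <- cut_clusters(t2, 3)[colnames(d)]
  # same partition up to label permutation
  expect_equal(length(unique(paste(c1, c2))), length(unique(c1)))
})

test_that("newick serialisation preserves the leaf set", {
  em <- tiny_expression(30, 8, seed = 10)
  tree <- hierarchical_cluster(correlation_distance_matrix(em), "ward")
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(em$values))
})

test_that("combining datasets z-scores separately and joins shared genes", {
  a <- tiny_expression(30, 5, dataset = "da", seed = 11)
  b <- tiny_expression(40, 6, dataset = "db", seed = 12)
  shared <- intersect(rownames(a$values), rownames(b$values))
  comb <- combine_datasets(a, b)
  expect_equal(nrow(comb$values), length(shared))
  expect_equal(ncol(comb$values), 11)
  expect_setequal(unique(comb$dataset), c("da", "db"))
  # within each dataset block the genes are robust-z-scored
  blk <- comb$values[, comb$dataset == "da", drop = FALSE]
  expect_lt(max(abs(apply(blk, 1, median))), 1e-12)

  # combining a dataset with itself doubles the samples (ids made unique)
  expect_warning(self_comb <- combine_datasets(a, a), "unique")
  expect_equal(ncol(self_comb$values), 2 * ncol(a$values))

  disj_a <- expr_matrix(matrix(rnorm(10), 5, 2,
                               dimnames = list(paste0("x", 1:5),
                                               c("a1", "a2"))), "da")
  disj_b <- expr_matrix(matrix(rnorm(10), 5, 2,
                               dimnames = list(paste0("y", 1:5),
                                               c("b1", "b2"))), "db")
  expect_error(combine_datasets(disj_a, disj_b), "shared gene")

  # known intersection size is preserved
  set.seed(54)
  g_all <- sprintf("g%03d", 1:200)
  ga <- sample(g_all, 120)
  gb <- sample(g_all, 120)
  ma <- expr_matrix(matrix(rnorm(120 * 4), 120, 4,
                           dimnames = list(ga, paste0("a", 1:4))), "da")
  mb <- expr_matrix(matrix(rnorm(120 * 4), 120, 4,
                           dimnames = list(gb, paste0("b", 1:4))), "db")
  expect_equal(nrow(combine_datasets(ma, mb)$values),
               length(intersect(ga, gb)))
})

test_that("PCA embedding is reproducible and captures planted structure", {
  set.seed(55)
  em <- tiny_expression(50, 8, seed = 13)
  emb <- pca_embedding(em, 2)
  expect_equal(names(emb), c("sample", "dataset", "PC1", "PC2"))
  # duplicated samples get identical coordinates
  m <- em$values
  m <- cbind(m, dup = m[, 1])
  emb2 <- pca_embedding(expr_matrix(m), 2)
  expect_equal(unlist(emb2[emb2$sample == "dup", c("PC1", "PC2")]),
               unlist(emb2[emb2$sample == colnames(em$values)[1],
                           c("PC1", "PC2")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # rank-1 matrix concentrates variance in the first component
  u <- rnorm(40); v <- rnorm(6)
  r1 <- outer(u, v)
  dimnames(r1) <- list(paste0("g", 1:40), paste0("s", 1:6))
  emb3 <- pca_embedding(expr_matrix(r1), 2)
  ve <- attr(emb3, "variance_explained")
  expect_lt(ve[2], 1e-8)
  expect_error(pca_embedding(em, 100), "k must lie")

  # planted two-batch offset: component 1 separates the batches
  set.seed(56)
  base <- matrix(rnorm(80 * 12), 80, 12,
                 dimnames = list(paste0("g", 1:80), paste0("s", 1:12)))
  base[1:40, 7:12] <- base[1:40, 7:12] + 6
  emb4 <- pca_embedding(expr_matrix(base, rep(c("t", "c"), each = 6)), 2)
  s_t <- emb4$PC1[emb4$dataset == "t"]
  s_c <- emb4$PC1[emb4$dataset == "c"]
  expect_true(max(s_t) < min(s_c) || min(s_t) > max(s_c))

  # invariance to sample order (up to the fixed sign convention)
  perm <- sample(12)
  emb5 <- pca_embedding(expr_matrix(base[, perm],
                                    rep(c("t", "c"), each = 6)[perm]), 2)
  expect_equal(emb5$PC1[match(emb4$sample, emb5$sample)], emb4$PC1,
               tolerance = 1e-9)
})

test_that("expression ranking orders lines by mean tumour correlation", {
  set.seed(57)
  genes <- paste0("g", 1:100)
  common <- rnorm(100)       # tumours share a programme, so a duplicated
  tum <- matrix(common + rnorm(100 * 50, 0, 0.7), 100, 50,
                dimnames = list(genes, sprintf("t%02d", 1:50)))
  cl <- matrix(rnorm(100 * 20), 100, 20,
               dimnames = list(genes, sprintf("c%02d", 1:20)))
  cl[, 5] <- tum[, 7]        # tumour profile correlates with all of them
  er <- expression_rank(expr_matrix(cl, "cell_line"),
                        expr_matrix(tum, "tumour"), combine = FALSE)
  expect_equal(er$cell_line[1], "c05")
  # brute-force oracle for the full ordering
  mean_r <- vapply(colnames(cl), function(cc) {
    mean(vapply(colnames(tum), function(t) cor(cl[, cc], tum[, t]),
                numeric(1)))
  }, numeric(1))
  expected <- names(sort(mean_r, decreasing = TRUE))
  expect_equal(er$cell_line, expected)

  # all-identical lines fall back to the identifier tie rule
  same <- cl; for (j in seq_len(ncol(same))) same[, j] <- cl[, 1]
  er2 <- expression_rank(expr_matrix(same, "cell_line"),
                         expr_matrix(tum, "tumour"), combine = FALSE)
  expect_equal(er2$cell_line, sort(colnames(same)))
})

test_that("kendall concordance handles the boundary orderings", {
  items <- paste0("i", 1:5)
  same <- kendall_concordance(items, items)
  expect_equal(same$tau, 1)
  rev_ <- kendall_concordance(items, rev(items))
  expect_equal(rev_$tau, -1)
  expect_error(kendall_concordance(items, paste0("j", 1:5)), "same item")
  expect_error(kendall_concordance(items[1:2], items[1:2]), "at least 3")
})

test_that("kendall tau and p agree with independent references", {
  set.seed(58)
  # untied data: cross-check against the classical exact test
  for (i in 1:5) {
    x <- sample(9)
    y <- sample(9)
    names(x) <- names(y) <- paste0("i", 1:9)
    res <- kendall_concordance(x, y)
    ref <- cor.test(x, y, method = "kendall", exact = FALSE,
                    continuity = TRUE)
    expect_equal(res$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
  # tied rankings: tau-b matches R's tie-aware correlation
  x <- setNames(c(1, 2, 2, 3, 4, 5, 6), paste0("i", 1:7))
  y <- setNames(c(2, 1, 3, 3, 5, 4, 6), paste0("i", 1:7))
  expect_equal(kendall_concordance(x, y)$tau,
               cor(x, y, method = "kendall"), tolerance = 1e-12)
})

test_that("small-n p-values come from exact enumeration", {
  set.seed(59)
  x <- setNames(sample(7), paste0("i", 1:7))
  y <- setNames(sample(7), paste0("i", 1:7))
  res <- kendall_concordance(x, y)
  expect_equal(res$method, "exact enumeration")
  # independent enumeration oracle over all 5040 permutations
  perms <- enumerate_permutations(7)
  taus <- vapply(perms, function(p) {
    cor(unname(x), unname(y)[p], method = "kendall")
  }, numeric(1))
  p_oracle <- mean(abs(taus) >= abs(res$tau) - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})
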