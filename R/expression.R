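#' Robust z-scores of an expression matrix
#'
#' Per gene, across samples: `(x - median) / MAD`, with the plain
#' (unscaled) median absolute deviation by default, i.e. without the 1.4826
#' consistency factor; set `mad_scale = "consistent"` for the scaled
#' variant. Genes with zero MAD have undefined z-scores and are dropped,
#' with the count reported via a message.
#'
#' @param em An `expr_matrix` with at least 2 samples.
#' @param mad_scale `"raw"` (default) or `"consistent"` (multiplies the MAD
#'   by 1.4826).
#' @return A z-scored `expr_matrix`; retained genes have median 0 and MAD 1.
#' @export
robust_z <- function(em, mad_scale = c("raw", "consistent")) {
  mad_scale <- match.arg(mad_scale)
  stopifnot(is(em, "expr_matrix"))
  x <- em$values
  if (ncol(x) < 2) abort("robust z-scoring needs at least 2 samples")
  if (nrow(x) == 0) abort("empty expression matrix")
  k <- if (mad_scale == "consistent") 1.4826 else 1
  med <- apply(x, 1, median)
  madv <- k * apply(x, 1, function(v) median(abs(v - median(v))))
  drop <- madv == 0
  if (any(drop)) {
    inform(sprintf("robust_z: dropped %d gene(s) with zero MAD", sum(drop)))
  }
  z <- sweep(sweep(x[!drop, , drop = FALSE], 1, med[!drop]), 1,
             madv[!drop], "/")
  expr_matrix(z, em$dataset)
}

#' Select the most variable genes by interquartile range
#'
#' Genes are ordered by IQR (75th minus 25th percentile across samples,
#' linear-interpolation type-7 quantiles) descending and the top `n`
#' retained. Ties at the boundary are broken by gene symbol
#' (lexicographic), so the selection is reproducible; the quantile
#' convention matters because it shifts boundary genes.
#'
#' @param em An `expr_matrix`.
#' @param n Number of genes to keep; must not exceed the gene count.
#' @return An `expr_matrix` restricted to the selected genes.
#' @export
select_top_iqr <- function(em, n) {
  stopifnot(is(em, "expr_matrix"))
  if (n > nrow(em$values)) {
    abort(sprintf("n = %d exceeds the %d available genes", n,
                  nrow(em$values)))
  }
  iqr <- apply(em$values, 1, function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] - q[1]
  })
  ord <- order(-iqr, rownames(em$values))
  keep <- ord[seq_len(n)]
  expr_matrix(em$values[keep, , drop = FALSE], em$dataset)
}

#' Sample-by-sample correlation distance matrix
#'
#' Distance between two samples is `1 - c`, with `c` the Pearson
#' correlation of their expression vectors across genes. The result is
#' symmetric with zero diagonal and entries in \[0, 2\]. A sample with zero
#' variance has no defined correlation and is an error naming the sample.
#'
#' @param em An `expr_matrix` with at least 2 genes.
#' @return Symmetric numeric matrix of `1 - r` distances.
#' @export
correlation_distance_matrix <- function(em) {
  stopifnot(is(em, "expr_matrix"))
  x <- em$values
  if (nrow(x) < 2) abort("need at least 2 genes for correlation distances")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance sample(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(x)
  diag(d) <- 0
  d
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Ward's method (`ward`, mapped to R's
#' `"ward.D2"`) or complete linkage. The merge tree is deterministic for a
#' given input; the leaf order follows the usual tight-cluster-first
#' convention of [stats::hclust()].
#'
#' @param distances Symmetric distance matrix or a `dist` object.
#' @param linkage `"ward"` or `"complete"`.
#' @return A `cluster_tree` list: `merge`, `height`, `order`, `labels`,
#'   `linkage` and the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(distances, linkage = c("ward", "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(distances)) {
    if (!isSymmetric(unname(distances), tol = 1e-8)) {
      abort("distance matrix must be symmetric")
    }
    distances <- as.dist(distances)
  }
  if (!inherits(distances, "dist")) {
    abort("distances must be a matrix or a dist object")
  }
  method <- c(ward = "ward.D2", complete = "complete")[[linkage]]
  hc <- hclust(distances, method = method)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, linkage = linkage, hclust = hc),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %s linkage\n",
              length(x$labels), x$linkage))
  invisible(x)
}

#' Flat cluster labels at a requested cut
#' @param tree A `cluster_tree`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(is(tree, "cluster_tree"))
  cutree(tree$hclust, k = k)
}

#' Serialise a cluster tree in Newick format
#' @param tree A `cluster_tree`.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(is(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Combine two expression datasets on their shared genes
#'
#' Each matrix is robust-z-scored independently (so platform-specific
#' location and scale per gene are removed within each dataset) and the two
#' are then joined on the intersection of their gene sets. Per-sample
#' dataset labels are preserved. Fewer than 3 shared genes is an error.
#'
#' @param a,b `expr_matrix` objects.
#' @param mad_scale Passed to [robust_z()].
#' @return A combined, z-scored `expr_matrix`.
#' @export
combine_datasets <- function(a, b, mad_scale = "raw") {
  stopifnot(is(a, "expr_matrix"), is(b, "expr_matrix"))
  za <- robust_z(a, mad_scale = mad_scale)
  zb <- robust_z(b, mad_scale = mad_scale)
  shared <- intersect(rownames(za$values), rownames(zb$values))
  if (length(shared) < 3) {
    abort(sprintf("only %d shared gene(s) after z-scoring; need at least 3",
                  length(shared)))
  }
  va <- za$values[shared, , drop = FALSE]
  vb <- zb$values[shared, , drop = FALSE]
  clash <- intersect(colnames(va), colnames(vb))
  if (length(clash) > 0) {
    warn(paste0("sample identifier(s) present in both datasets, made ",
                "unique: ", paste(head(clash, 5), collapse = ", ")))
    colnames(vb)[colnames(vb) %in% clash] <-
      paste0(colnames(vb)[colnames(vb) %in% clash], ".2")
  }
  expr_matrix(cbind(va, vb), c(unname(za$dataset), unname(zb$dataset)))
}

#' Principal-component embedding of samples
#'
#' PCA of the gene-centred matrix (genes as variables, samples as
#' observations). Component signs are fixed by making the
#' largest-magnitude gene loading of each component positive, so the
#' embedding is reproducible across runs and platforms.
#'
#' @param em An `expr_matrix`.
#' @param k Number of components; at most `min(genes, samples)`.
#' @return Tibble with columns `sample`, `dataset`, `PC1`..`PCk`; the
#'   per-component variance fractions are in attribute
#'   `"variance_explained"`.
#' @export
pca_embedding <- function(em, k = 2) {
  stopifnot(is(em, "expr_matrix"))
  p <- min(nrow(em$values), ncol(em$values))
  if (k < 1 || k > p) {
    abort(sprintf("k must lie in [1, %d]", p))
  }
  pc <- prcomp(t(em$values), center = TRUE, scale. = FALSE)
  k_avail <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k_avail), drop = FALSE]
  for (j in seq_len(k_avail)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble(sample = colnames(em$values),
                dataset = unname(em$dataset))
  for (j in seq_len(k_avail)) out[[paste0("PC", j)]] <- scores[, j]
  attr(out, "variance_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k_avail)]
  out
}

#' Rank cell lines by average expression correlation with tumours
#'
#' For every cell line, the Pearson correlation of its expression vector
#' with each tumour's is computed over the shared genes, and lines are
#' ranked by the mean of those correlations, descending (ties broken by
#' identifier). By default the two matrices are first combined via
#' [combine_datasets()], i.e. robust-z-scored per dataset and restricted to
#' shared genes.
#'
#' @param cell_lines,tumours `expr_matrix` objects.
#' @param combine If `TRUE` (default) run [combine_datasets()] first; set
#'   `FALSE` when the inputs are already on a common z-scored gene space.
#' @return Tibble ordered best-first with columns `cell_line`,
#'   `mean_correlation`, `rank`.
#' @export
expression_rank <- function(cell_lines, tumours, combine = TRUE) {
  stopifnot(is(cell_lines, "expr_matrix"), is(tumours, "expr_matrix"))
  if (combine) {
    comb <- combine_datasets(tumours, cell_lines)
    tum_ids <- colnames(tumours$values)
    cl_ids <- colnames(cell_lines$values)
    tm <- comb$values[, tum_ids, drop = FALSE]
    cm <- comb$values[, cl_ids, drop = FALSE]
  } else {
    shared <- intersect(rownames(cell_lines$values), rownames(tumours$values))
    if (length(shared) < 3) abort("fewer than 3 shared genes")
    tm <- tumours$values[shared, , drop = FALSE]
    cm <- cell_lines$values[shared, , drop = FALSE]
  }
  sds <- c(apply(tm, 2, stats::sd), apply(cm, 2, stats::sd))
  if (any(sds == 0)) {
    abort(paste0("zero-variance sample(s): ",
                 paste(names(sds)[sds == 0], collapse = ", ")))
  }
  r <- cor(cm, tm)
  out <- tibble(cell_line = rownames(r), mean_correlation = rowMeans(r))
  out <- out[order(-out$mean_correlation, out$cell_line), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Kendall rank concordance between two orderings
#'
#' Computes the tie-corrected Kendall tau-b between two orderings of the
#' same items and a two-sided p-value. Tau-b is used because tier-derived
#' rankings can contain ties. For `n <= 8` items the p-value is exact,
#' obtained by enumerating all `n!` permutations of one ranking; for larger
#' `n` a normal approximation with tie-corrected variance and continuity
#' correction is used. The method is recorded in the result.
#'
#' @param order1,order2 The two rankings over the same item set: character
#'   vectors of item identifiers in rank order, or named numeric rank
#'   vectors.
#' @return List with `tau`, `p_value`, `n`, `method`.
#' @export
kendall_concordance <- function(order1, order2) {
  r1 <- as_rank_vector(order1)
  r2 <- as_rank_vector(order2)
  if (!setequal(names(r1), names(r2))) {
    abort("the two orderings must cover the same item set")
  }
  n <- length(r1)
  if (n < 3) abort("need at least 3 items")
  r2 <- r2[names(r1)]
  tau <- kendall_tau_b(r1, r2)
  if (n <= 8) {
    perms <- all_permutations(n)
    taus <- apply(perms, 1, function(p) kendall_tau_b(r1, r2[p]))
    p_value <- mean(abs(taus) >= abs(tau) - 1e-12)
    method <- "exact enumeration"
  } else {
    p_value <- kendall_normal_p(r1, r2)
    method <- "normal approximation with continuity correction"
  }
  list(tau = tau, p_value = p_value, n = n, method = method)
}

as_rank_vector <- function(x) {
  if (is.character(x)) {
    if (anyDuplicated(x)) abort("ordering contains duplicated items")
    setNames(seq_along(x), x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    abort("ordering must be a character vector or a named numeric vector")
  }
}

# Kendall score (concordant minus discordant pairs) for two rank vectors
kendall_score <- function(x, y) {
  n <- length(x)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  sum(sign(x[i] - x[j]) * sign(y[i] - y[j]))
}

kendall_tau_b <- function(x, y) {
  n <- length(x)
  s <- kendall_score(x, y)
  n0 <- n * (n - 1) / 2
  t1 <- table(x); t2 <- table(y)
  n1 <- sum(t1 * (t1 - 1) / 2)
  n2 <- sum(t2 * (t2 - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) abort("tau-b undefined: a ranking is entirely tied")
  s / denom
}

# two-sided normal-approximation p with tie-corrected variance and
# continuity correction on the Kendall score
kendall_normal_p <- function(x, y) {
  n <- length(x)
  s <- kendall_score(x, y)
  t1 <- as.numeric(table(x)); t2 <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t1 * (t1 - 1) * (2 * t1 + 5))
  vu <- sum(t2 * (t2 - 1) * (2 * t2 + 5))
  v1 <- sum(t1 * (t1 - 1)) * sum(t2 * (t2 - 1)) / (2 * n * (n - 1))
  v2 <- sum(t1 * (t1 - 1) * (t1 - 2)) * sum(t2 * (t2 - 1) * (t2 - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  if (v <= 0) return(1)
  z <- (abs(s) - 1) / sqrt(v)   # continuity correction of 1 on the score
  min(1, 2 * pnorm(-max(z, 0)))
}

# all permutations of 1..n as a matrix (n! rows); n is small (<= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- as.matrix(block)
    row <- row + nrow(sub)
  }
  out
}
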