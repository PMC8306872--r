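#' Within-condition replicate Pearson correlations
#'
#' Sequencing-quality check: Pearson r between every pair of biological
#' replicates of the same genotype/treatment cell, computed on
#' log2(FPKM + 1). A zero-variance sample leaves its pairs undefined; they
#' are reported as `NA` with a warning.
#'
#' @param x an [expression_set()] with >= 2 replicates per condition.
#' @return list of class `correlation_report`: `pairs` (data frame
#'   `sample_a`, `sample_b`, `genotype`, `treatment`, `r`), `min_r`, `max_r`.
#' @export
replicate_correlation <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  lv <- log2(x$values + 1)
  cells <- unique(x$samples[, c("genotype", "treatment")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    ids <- x$samples$sample_id[x$samples$genotype == cells$genotype[i] &
                               x$samples$treatment == cells$treatment[i]]
    if (length(ids) < 2) {
      stop("condition ", cells$genotype[i], "/", cells$treatment[i],
           " has fewer than 2 replicates")
    }
    for (a in seq_len(length(ids) - 1)) for (b in seq(a + 1, length(ids))) {
      va <- lv[, ids[a]]; vb <- lv[, ids[b]]
      r <- if (sd(va) == 0 || sd(vb) == 0) {
        warning("zero-variance sample in pair ", ids[a], "/", ids[b],
                "; correlation undefined")
        NA_real_
      } else {
        cor(va, vb)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_a = ids[a], sample_b = ids[b],
        genotype = cells$genotype[i], treatment = cells$treatment[i],
        r = r, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 min_r = if (all(is.na(pairs$r))) NA_real_ else min(pairs$r, na.rm = TRUE),
                 max_r = if (all(is.na(pairs$r))) NA_real_ else max(pairs$r, na.rm = TRUE)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> ", nrow(x$pairs), " within-condition replicate pairs\n",
      sprintf("  Pearson r range: %.3f - %.3f\n", x$min_r, x$max_r), sep = "")
  invisible(x)
}

#' Unsupervised clustering behind the expression heatmap
#'
#' Genes are log2(FPKM + 1)-transformed, zero-variance genes are dropped,
#' and the rest are z-scored per gene. Columns (samples) are clustered on
#' Euclidean distance of the z-scores, rows (genes) on 1 - Pearson
#' correlation, both with average linkage. The testable artifact is the
#' permutations and merge trees, not a rendered image; when the main source
#' of variation is the treatment, cutting the column tree at k = 2 separates
#' control from cadmium-treated samples.
#'
#' @param x an [expression_set()] with >= 2 samples.
#' @return list of class `cluster_result`: `column_order` and `row_order`
#'   (ids in dendrogram order), `column_tree` and `row_tree`
#'   ([stats::hclust] objects), `dropped` (zero-variance contigs),
#'   `distance`, `linkage`.
#' @seealso [plot.cluster_result()] for the optional heatmap rendering.
#' @export
cluster_heatmap <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  if (ncol(x$values) < 2) stop("clustering needs at least 2 samples")
  lv <- log2(x$values + 1)
  v <- apply(lv, 1, sd)
  dropped <- rownames(lv)[v == 0]
  lv <- lv[v > 0, , drop = FALSE]
  if (!nrow(lv)) stop("no gene with non-zero variance to cluster")
  z <- (lv - rowMeans(lv)) / apply(lv, 1, sd)

  column_tree <- hclust(dist(t(z), method = "euclidean"), method = "average")
  row_tree <- if (nrow(z) >= 2) {
    hclust(as.dist(1 - cor(t(z))), method = "average")
  } else {
    NULL
  }
  structure(list(
    column_order = colnames(z)[column_tree$order],
    row_order = if (is.null(row_tree)) rownames(z) else rownames(z)[row_tree$order],
    column_tree = column_tree, row_tree = row_tree, dropped = dropped,
    distance = c(rows = "1-pearson", columns = "euclidean"),
    linkage = "average"
  ), class = "cluster_result")
}

#' Sample partition from the column dendrogram
#'
#' @param clust a `cluster_result` from [cluster_heatmap()].
#' @param k number of clusters.
#' @return named integer vector of cluster memberships per sample.
#' @export
column_clusters <- function(clust, k = 2) {
  stopifnot(inherits(clust, "cluster_result"))
  cutree(clust$column_tree, k = k)
}

#' Render the clustered expression heatmap
#'
#' Optional visual companion to [cluster_heatmap()]; requires the
#' `pheatmap` package.
#'
#' @param x a `cluster_result`.
#' @param expr the [expression_set()] the result was computed from.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot.cluster_result <- function(x, expr, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("package 'pheatmap' is required for heatmap rendering")
  }
  lv <- log2(expr$values[setdiff(rownames(expr$values), x$dropped), , drop = FALSE] + 1)
  z <- (lv - rowMeans(lv)) / apply(lv, 1, sd)
  p <- pheatmap::pheatmap(z, cluster_rows = x$row_tree, cluster_cols = x$column_tree,
                          show_rownames = nrow(z) <= 50, ...)
  invisible(p)
}
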