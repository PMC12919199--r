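#' Log-CPM normalization of a count matrix
#'
#' Scales each cell (column) to counts per million and applies a natural-log
#' `log1p` transform, the standard normalization for droplet/nucleus RNA-seq
#' counts prior to specificity scoring. The raw counts are left untouched;
#' the transformed matrix is returned as a new layer.
#'
#' @param counts gene x cell matrix of non-negative integer counts
#'   (dense or [Matrix::sparseMatrix]).
#' @return A matrix of the same shape with entries
#'   `log(1 + 1e6 * count / cell_total)`. Cells whose total count is zero are
#'   dropped with a warning (their CPM is undefined).
#' @export
normalize_log_cpm <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("excluding %d cell(s) with zero total count", sum(zero)))
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (length(totals) == 0L) stop("no cells with nonzero total count")
  out <- counts
  if (inherits(out, "sparseMatrix")) {
    out <- as(out, "CsparseMatrix")
    # scale within the nonzero slots; log1p(0) = 0 so sparsity is preserved
    j <- rep(seq_len(ncol(out)), diff(out@p))
    out@x <- log1p(1e6 * out@x / totals[j])
  } else {
    out <- log1p(sweep(out, 2, totals, "/") * 1e6)
  }
  out
}

#' Assign cells to cell-type x epoch clusters
#'
#' Clusters are the Cartesian combinations of annotated cell type and
#' developmental epoch actually observed. Combinations with fewer than
#' `min_cells` cells are excluded (their cells are dropped from downstream
#' specificity computation) to avoid unstable gene assignment.
#'
#' @param cells data.frame with one row per cell, containing columns
#'   `cell_type` and `epoch`; row order must match the columns of the
#'   count matrix.
#' @param min_cells minimum cluster size; smaller clusters are excluded.
#'   Default 50.
#' @return list with `cluster` (factor over retained cells, named by cell
#'   index), `keep` (logical vector over the input cells), and `excluded`
#'   (character vector of excluded cluster ids).
#' @export
label_clusters <- function(cells, min_cells = 50) {
  stopifnot(is.data.frame(cells), all(c("cell_type", "epoch") %in% names(cells)))
  cl <- paste(cells$cell_type, cells$epoch, sep = "|")
  sizes <- table(cl)
  excluded <- names(sizes)[sizes < min_cells]
  keep <- !(cl %in% excluded)
  if (!any(keep)) stop("no clusters with at least ", min_cells, " cells")
  structure(
    list(cluster = factor(cl[keep]), keep = keep, excluded = excluded,
         min_cells = min_cells),
    class = "cluster_labeling"
  )
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("Cluster labeling:", nlevels(x$cluster), "clusters over",
      length(x$cluster), "cells;", length(x$excluded),
      "cluster(s) excluded (<", x$min_cells, "cells)\n")
  invisible(x)
}

#' Detection sensitivity and specificity of one gene for one cluster
#'
#' Sensitivity is the fraction of cells inside the cluster with read count at
#' or above the threshold; specificity is the fraction of cells outside the
#' cluster below the threshold (not expressing at that level).
#'
#' @param counts gene x cell count matrix (raw counts).
#' @param labeling a [label_clusters()] result.
#' @param gene gene identifier (rowname) or row index.
#' @param cluster cluster id (a level of `labeling$cluster`).
#' @param threshold count threshold t; a cell "expresses" when count >= t.
#'   Default 1.
#' @return named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sensitivity_specificity <- function(counts, labeling, gene, cluster, threshold = 1) {
  v <- .gene_counts(counts, labeling, gene)
  inc <- labeling$cluster == cluster
  if (!any(inc)) stop("empty or unknown cluster: ", cluster)
  c(sensitivity = mean(v[inc] >= threshold),
    specificity = mean(v[!inc] < threshold))
}

.gene_counts <- function(counts, labeling, gene) {
  if (is.character(gene) && !(gene %in% rownames(counts)))
    stop("gene not found in matrix: ", gene)
  as.numeric(counts[gene, ])[labeling$keep]
}

# Area under the ROC curve for one score vector against in/out labels,
# swept over every observed value as a threshold (trapezoidal, so ties get
# half credit). Anchored at (0,0); the smallest observed value yields (1,1).
.auc_sweep <- function(v, inc) {
  n_in <- sum(inc); n_out <- sum(!inc)
  if (n_in == 0L || n_out == 0L) stop("need cells inside and outside the cluster")
  u <- sort(unique(v), decreasing = TRUE)
  f <- match(v, u)
  tpr <- cumsum(tabulate(f[inc], nbins = length(u))) / n_in
  fpr <- cumsum(tabulate(f[!inc], nbins = length(u))) / n_out
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Per-gene, per-cluster specificity profile with ROC AUC
#'
#' For every gene and every retained cluster, computes the detection
#' sensitivity and specificity at read count >= 1 and the area under the ROC
#' curve obtained by sweeping the expression threshold over all observed
#' count values (trapezoidal rule, so tied counts receive half credit; this
#' equals the normalized Mann-Whitney probability that a random in-cluster
#' cell has a higher count than a random out-cluster cell). An AUC of 1 means
#' the gene is expressed exclusively and ubiquitously in the cluster; 0.5
#' means no discriminatory power; genes with zero counts everywhere score
#' exactly 0.5.
#'
#' @inheritParams sensitivity_specificity
#' @return object of class `gene_specificity_profile`: a list with
#'   `by_cluster` (long data.frame gene/cluster/sensitivity/specificity/auc)
#'   and `summary` (per-gene `auc_max`, `sensitivity_max`, `specificity_max`,
#'   and `best_cluster`, the argmax-AUC cluster).
#' @export
compute_auc <- function(counts, labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  if (nlevels(labeling$cluster) == 0L) stop("empty labeling")
  genes <- rownames(counts)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(counts)))
  cls <- levels(labeling$cluster)
  m <- as.matrix(counts)[, labeling$keep, drop = FALSE]
  inc_list <- lapply(cls, function(cl) labeling$cluster == cl)
  res <- vector("list", nrow(m))
  for (g in seq_len(nrow(m))) {
    v <- m[g, ]
    sens <- spec <- auc <- numeric(length(cls))
    for (k in seq_along(cls)) {
      inc <- inc_list[[k]]
      sens[k] <- mean(v[inc] >= 1)
      spec[k] <- mean(v[!inc] < 1)
      auc[k] <- .auc_sweep(v, inc)
    }
    res[[g]] <- data.frame(gene = genes[g], cluster = cls,
                           sensitivity = sens, specificity = spec, auc = auc,
                           stringsAsFactors = FALSE)
  }
  by_cluster <- do.call(rbind, res)
  spl <- split(by_cluster, by_cluster$gene)[genes]
  summary <- data.frame(
    gene = genes,
    auc_max = vapply(spl, function(d) max(d$auc), 0),
    sensitivity_max = vapply(spl, function(d) max(d$sensitivity), 0),
    specificity_max = vapply(spl, function(d) max(d$specificity), 0),
    best_cluster = vapply(spl, function(d) d$cluster[which.max(d$auc)], ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(by_cluster = by_cluster, summary = summary),
            class = "gene_specificity_profile")
}

#' @export
print.gene_specificity_profile <- function(x, ...) {
  cat("Gene specificity profile:", nrow(x$summary), "genes x",
      length(unique(x$by_cluster$cluster)), "clusters\n")
  cat("median AUC_max:", round(stats::median(x$summary$auc_max), 3), "\n")
  invisible(x)
}

#' Remove genes with low best-case detection
#'
#' Genes detected (count >= 1) in fewer than `threshold` of the cells of even
#' their best cluster are too sparsely captured for reliable assignment and
#' are excluded from gene-set construction.
#'
#' @param profile a [compute_auc()] result.
#' @param threshold sensitivity_max cutoff; genes strictly below are removed.
#'   Default 0.10.
#' @return character vector of retained gene ids.
#' @export
filter_low_detection <- function(profile, threshold = 0.10) {
  stopifnot(inherits(profile, "gene_specificity_profile"))
  profile$summary$gene[profile$summary$sensitivity_max >= threshold]
}
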