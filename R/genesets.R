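# Gene-cluster specificity scores and fixed-size gene-set construction.
#
# Four scoring methods are supported: a z-score over per-cluster mean
# expression, a tie-corrected Wilcoxon rank-sum statistic on per-cell
# expression, the Expression Proportion (EP: the fraction of a gene's summed
# per-cluster mean expression falling in one cluster), and the Expression
# Enrichment (EE: EP divided by the cluster's share of total expression, so
# a uniformly expressed gene scores 1 everywhere).

.cluster_means <- function(exprs, labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  m <- as.matrix(exprs)[, labeling$keep, drop = FALSE]
  cls <- levels(labeling$cluster)
  out <- vapply(cls, function(cl) rowMeans(m[, labeling$cluster == cl, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(rownames(out))) rownames(out) <- as.character(seq_len(nrow(m)))
  out
}

#' Z-score specificity of per-cluster mean expression
#'
#' For each gene, the per-cluster mean log-CPM `x_i` is standardized against
#' the mean and (population) standard deviation of that gene's per-cluster
#' means: `z_i = (x_i - mu) / sigma`. Genes constant across clusters
#' (`sigma = 0`) score 0 in every cluster and are reported in the
#' `flagged_constant` attribute.
#'
#' @param exprs gene x cell expression matrix (log-CPM layer; see
#'   [normalize_log_cpm()]).
#' @param labeling a [label_clusters()] result (>= 2 clusters).
#' @return gene x cluster score matrix with attributes `method = "zscore"`
#'   and `flagged_constant`.
#' @export
score_zscore <- function(exprs, labeling) {
  xm <- .cluster_means(exprs, labeling)
  if (ncol(xm) < 2L) stop("z-score requires at least 2 clusters")
  mu <- rowMeans(xm)
  sigma <- sqrt(rowMeans((xm - mu)^2)) # population SD across clusters
  z <- (xm - mu) / ifelse(sigma == 0, Inf, sigma)
  structure(z, method = "zscore", flagged_constant = rownames(xm)[sigma == 0])
}

#' Expression Proportion (EP) specificity score
#'
#' `EP_i = x_i / sum_j x_j` over the per-cluster means of a gene; rows sum
#' to 1. Genes with zero expression in every cluster have an undefined EP
#' and are excluded (rows dropped, listed in the `excluded` attribute).
#'
#' @inheritParams score_zscore
#' @return gene x cluster score matrix, `method = "ep"`.
#' @export
score_ep <- function(exprs, labeling) {
  xm <- .cluster_means(exprs, labeling)
  tot <- rowSums(xm)
  zero <- tot == 0
  ep <- xm[!zero, , drop = FALSE] / tot[!zero]
  structure(ep, method = "ep", excluded = rownames(xm)[zero])
}

#' Expression Enrichment (EE) specificity score
#'
#' EP divided by the cluster's share of total expression:
#' `EE_i = EP_i * (sum_j s_j / s_i)` where `s_i` is the total expression of
#' cluster i (the sum of per-cluster mean expression over all genes). A gene
#' expressed uniformly scores 1 in every cluster, and the weighted sum
#' `sum_i (s_i / sum_j s_j) EE_i` equals 1 for every gene.
#'
#' @inheritParams score_zscore
#' @return gene x cluster score matrix, `method = "ee"`; attribute
#'   `cluster_share` carries `s_i / sum_j s_j`.
#' @export
score_ee <- function(exprs, labeling) {
  xm <- .cluster_means(exprs, labeling)
  s <- colSums(xm)
  if (any(s == 0)) stop("cluster with zero total expression")
  tot <- rowSums(xm)
  zero <- tot == 0
  ep <- xm[!zero, , drop = FALSE] / tot[!zero]
  ee <- sweep(ep, 2, sum(s) / s, "*")
  structure(ee, method = "ee", excluded = rownames(xm)[zero],
            cluster_share = s / sum(s))
}

#' Wilcoxon rank-sum specificity score
#'
#' Per gene and cluster, the tie-corrected normal approximation z-statistic
#' of the Wilcoxon rank-sum test comparing per-cell expression inside versus
#' outside the cluster. Higher z = more specific. Degenerate genes (all cells
#' tied) score 0.
#'
#' @inheritParams score_zscore
#' @return gene x cluster score matrix, `method = "wilcoxon"`.
#' @export
score_wilcoxon <- function(exprs, labeling) {
  m <- as.matrix(exprs)[, labeling$keep, drop = FALSE]
  cls <- levels(labeling$cluster)
  N <- ncol(m)
  out <- matrix(0, nrow(m), length(cls), dimnames = list(rownames(m), cls))
  for (g in seq_len(nrow(m))) {
    v <- m[g, ]
    r <- rank(v)
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    for (k in seq_along(cls)) {
      inc <- labeling$cluster == cls[k]
      n1 <- sum(inc); n2 <- N - n1
      if (n1 < 2L || n2 < 2L) stop("need >= 2 cells inside and outside each cluster")
      W <- sum(r[inc])
      EW <- n1 * (N + 1) / 2
      VW <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
      out[g, k] <- if (VW <= 0) 0 else (W - EW) / sqrt(VW)
    }
  }
  structure(out, method = "wilcoxon")
}

#' Build fixed-size cell-type gene sets from a score matrix
#'
#' Per cluster, takes the `n` retained genes with the highest specificity
#' score (ties broken by score descending, then gene id ascending, for
#' reproducibility). When a LOEUF table is supplied, genes not under genetic
#' constraint (LOEUF >= `loeuf_cutoff`) are then removed from each set, so
#' sets may shrink below `n`; genes with missing LOEUF are treated as
#' unconstrained and removed too (ids recorded in the `missing_loeuf`
#' attribute). A gene may belong to several sets.
#'
#' @param scores gene x cluster score matrix from one of the `score_*`
#'   functions.
#' @param n target set size. Default 600.
#' @param retained_genes optional character vector (e.g. from
#'   [filter_low_detection()]); scoring rows outside it are ignored.
#' @param loeuf optional named numeric vector of LOEUF values per gene;
#'   `NULL` disables the constraint filter.
#' @param loeuf_cutoff genes with LOEUF >= cutoff are excluded when the
#'   filter is on. Default 0.6.
#' @return object of class `gene_set_collection`: a named list of character
#'   vectors with attributes `method`, `n`, `loeuf_filtered`.
#' @export
assign_top_n <- function(scores, n = 600, retained_genes = NULL,
                         loeuf = NULL, loeuf_cutoff = 0.6) {
  stopifnot(is.matrix(scores) || inherits(scores, "Matrix"))
  method <- attr(scores, "method")
  g <- rownames(scores)
  if (!is.null(retained_genes)) {
    keep <- g %in% retained_genes
    scores <- scores[keep, , drop = FALSE]
    g <- g[keep]
  }
  missing_loeuf <- character(0)
  sets <- lapply(colnames(scores), function(cl) {
    s <- scores[, cl]
    ord <- order(-s, g) # score desc, gene id asc
    top <- g[ord][seq_len(min(n, length(g)))]
    if (!is.null(loeuf)) {
      lo <- loeuf[top]
      missing_loeuf <<- union(missing_loeuf, top[is.na(lo)])
      top <- top[!is.na(lo) & lo < loeuf_cutoff]
    }
    top
  })
  names(sets) <- colnames(scores)
  structure(sets, class = "gene_set_collection",
            method = method, n = n,
            loeuf_filtered = !is.null(loeuf), loeuf_cutoff = loeuf_cutoff,
            missing_loeuf = missing_loeuf)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x), "sets, sizes",
      paste(range(lengths(x)), collapse = "-"),
      "| method:", attr(x, "method") %||% "external",
      "| LOEUF filter:", attr(x, "loeuf_filtered") %||% FALSE, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrimination AUC of a gene window via its first principal component
#'
#' Projects all retained cells on the first principal component of the
#' expression of a window of genes (log-CPM, centered per gene, unscaled)
#' and computes the ROC AUC of that projection for in-cluster versus
#' out-cluster membership. The component sign is chosen so the AUC is
#' >= 0.5. Used to validate that ranked specificity windows (e.g. 15 ranges
#' of 100 genes) still discriminate their cell type.
#'
#' @param exprs gene x cell expression matrix (log-CPM).
#' @param labeling a [label_clusters()] result.
#' @param genes character vector of window genes (>= 2).
#' @param cluster cluster id to discriminate.
#' @return AUC in `[0.5, 1]`.
#' @export
validate_discrimination <- function(exprs, labeling, genes, cluster) {
  if (length(genes) < 2L) stop("window must contain at least 2 genes")
  if (!all(genes %in% rownames(exprs))) stop("window genes absent from matrix")
  m <- t(as.matrix(exprs[genes, labeling$keep, drop = FALSE]))
  pc1 <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
  inc <- labeling$cluster == cluster
  if (!any(inc)) stop("empty or unknown cluster: ", cluster)
  max(.auc_sweep(pc1, inc), .auc_sweep(-pc1, inc))
}

#' Pairwise Jaccard overlap of a gene-set collection
#'
#' `J(A, B) = |A intersect B| / |A union B|`; symmetric with unit diagonal.
#' A pair of empty sets is defined as 0 (flagged via warning).
#'
#' @param collection a [gene_set_collection][assign_top_n()] or named list
#'   of character vectors (>= 2 sets).
#' @return square symmetric matrix of Jaccard indices.
#' @export
overlap_matrix <- function(collection) {
  if (length(collection) < 2L) stop("need at least 2 gene sets")
  k <- length(collection)
  nm <- names(collection)
  J <- matrix(1, k, k, dimnames = list(nm, nm))
  flagged <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    u <- length(union(collection[[i]], collection[[j]]))
    if (u == 0) { J[i, j] <- J[j, i] <- 0; flagged <- TRUE }
    else J[i, j] <- J[j, i] <- length(intersect(collection[[i]], collection[[j]])) / u
  }
  if (flagged) warning("empty set pair(s): Jaccard defined as 0")
  J
}
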