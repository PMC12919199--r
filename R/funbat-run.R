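# Scanning a gene-set collection across variant classes, FDR bookkeeping,
# and cohort-downsampling stability.

#' Run FunBAT over a gene-set collection and variant classes
#'
#' Fits one conditional-logistic burden model per (gene set x variant
#' class). Copy-number classes (`deletion`, `duplication`) automatically use
#' the two-background-burden model when a LOEUF table is supplied: alongside
#' the set burden, the counts of disrupted genes outside the set that are
#' under (`LOEUF < background_cutoff`) and not under genetic constraint
#' enter as nuisance burdens, absorbing the cumulative effect of multigenic
#' CNVs. Benjamini-Hochberg FDR is applied over the declared family of tests
#' (all cells by default, or per class).
#'
#' @param collapsed a [collapse_by_gene()] result.
#' @param sets named list of gene sets (e.g. from [assign_top_n()] or
#'   [read_gmt()]).
#' @param phenotype cohort data.frame (see [funbat()]).
#' @param classes variant classes to test. Default: the five short-variant
#'   classes plus deletion and duplication.
#' @param covariates covariate column names passed to [funbat()].
#' @param loeuf named numeric vector of per-gene LOEUF values; required for
#'   the CNV background model, ignored otherwise.
#' @param cnv_classes classes that trigger the two-burden model.
#' @param background_cutoff LOEUF split for the background burdens.
#'   Default 1.
#' @param fdr_family `"all"` (one BH family over every cell) or
#'   `"per_class"`.
#' @return data.frame of class `funbat_scan`: one row per set x class with
#'   `beta`, `or`, `se`, `p`, `q`, stratum counts and flags. Cells with no
#'   estimable burden are kept as NA rows for bookkeeping.
#' @export
run_funbat <- function(collapsed, sets, phenotype,
                       classes = c("stop_gained", "frameshift", "missense",
                                   "splice", "synonymous", "deletion",
                                   "duplication"),
                       covariates = NULL, loeuf = NULL,
                       cnv_classes = c("deletion", "duplication"),
                       background_cutoff = 1, fdr_family = c("all", "per_class")) {
  fdr_family <- match.arg(fdr_family)
  individuals <- phenotype$individual_id
  rows <- list()
  for (set_id in names(sets)) {
    set_genes <- sets[[set_id]]
    for (cl in classes) {
      b <- compute_burden(collapsed, set_genes, cl, individuals)
      bg <- NULL
      if (cl %in% cnv_classes && !is.null(loeuf)) {
        other <- collapsed[collapsed$class == cl & !(collapsed$gene %in% set_genes), ]
        lo <- loeuf[other$gene]
        cons <- unique(other[!is.na(lo) & lo < background_cutoff,
                             c("individual_id", "gene")])
        uncons <- unique(other[!is.na(lo) & lo >= background_cutoff,
                               c("individual_id", "gene")])
        bg <- list(
          constrained = stats::setNames(as.integer(
            table(factor(cons$individual_id, levels = individuals))), individuals),
          unconstrained = stats::setNames(as.integer(
            table(factor(uncons$individual_id, levels = individuals))), individuals))
      }
      fit <- funbat(b, phenotype, covariates = covariates, background = bg)
      rows[[paste(set_id, cl)]] <- data.frame(
        set = set_id, class = cl, beta = fit$beta, or = fit$or, se = fit$se,
        p = fit$p, n_strata = fit$n_strata,
        n_dropped_strata = fit$n_dropped_strata,
        inestimable = fit$inestimable, diverged = fit$diverged,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  if (fdr_family == "all") {
    out$q <- stats::p.adjust(out$p, "BH")
  } else {
    for (cl in unique(out$class)) {
      i <- out$class == cl
      out$q[i] <- stats::p.adjust(out$p[i], "BH")
    }
  }
  class(out) <- c("funbat_scan", "data.frame")
  attr(out, "fdr_family") <- fdr_family
  out
}

#' @export
print.funbat_scan <- function(x, ...) {
  cat("FunBAT scan:", length(unique(x$set)), "gene sets x",
      length(unique(x$class)), "classes =", nrow(x), "tests;",
      sum(!is.na(x$q) & x$q < 0.05), "with FDR < 0.05\n")
  NextMethod()
}

#' Burden association across sliding windows of genetic constraint
#'
#' Sweeps a LOEUF-ordered gene universe with sliding windows and fits the
#' burden model on each window's genes, showing where along the constraint
#' spectrum the association signal lives. The binning is generic
#' (configurable width and step in genes, ordered by LOEUF).
#'
#' @inheritParams run_funbat
#' @param loeuf named numeric vector of per-gene LOEUF values; genes with
#'   missing values are dropped from the sweep.
#' @param class variant class to test.
#' @param window_size,step window width and stride, in genes.
#' @return data.frame: one row per window with its LOEUF range, `beta`,
#'   `se`, `p` and flags.
#' @export
loeuf_window_scan <- function(collapsed, phenotype, loeuf, class,
                              covariates = NULL, window_size = 100,
                              step = 50) {
  loeuf <- sort(loeuf[!is.na(loeuf)])
  if (length(loeuf) < window_size) stop("fewer genes than the window size")
  starts <- seq(1L, length(loeuf) - window_size + 1L, by = step)
  individuals <- phenotype$individual_id
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window_size - 1L)
    fit <- funbat(compute_burden(collapsed, names(loeuf)[idx], class,
                                 individuals),
                  phenotype, covariates = covariates)
    data.frame(loeuf_min = loeuf[idx[1]], loeuf_max = loeuf[idx[length(idx)]],
               beta = fit$beta, se = fit$se, p = fit$p,
               inestimable = fit$inestimable, diverged = fit$diverged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stability of burden estimates under cohort downsampling
#'
#' Repeatedly subsamples families (strata) without replacement at a grid of
#' fractions, recomputes the full scan, and correlates (Spearman) the
#' downsampled effect estimates against the full-cohort estimates. A
#' replicate whose subsample retains fewer than 2 informative strata is
#' skipped with a flag.
#'
#' @inheritParams run_funbat
#' @param fractions family-sampling fractions. Default 0.1 to 0.9 by 0.1.
#' @param reps replicates per fraction. Default 20.
#' @param seed integer seed for reproducible sampling.
#' @param ... further arguments to [run_funbat()].
#' @return data.frame `fraction`, `rep`, `spearman_r`, `n_strata`,
#'   `skipped`; the full-cohort scan is attached as attribute `full`.
#' @export
cohort_downsampling_stability <- function(collapsed, sets, phenotype,
                                          fractions = seq(0.1, 0.9, 0.1),
                                          reps = 20, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  full <- run_funbat(collapsed, sets, phenotype, ...)
  fams <- unique(phenotype$family_id)
  out <- list()
  for (f in fractions) for (r in seq_len(reps)) {
    sub_f <- sample(fams, max(1L, round(f * length(fams))))
    ph <- phenotype[phenotype$family_id %in% sub_f, , drop = FALSE]
    inf <- filter_strata(ph)
    if (length(unique(inf$family_id)) < 2L) {
      out[[length(out) + 1L]] <- data.frame(fraction = f, rep = r,
                                            spearman_r = NA_real_,
                                            n_strata = length(unique(inf$family_id)),
                                            skipped = TRUE)
      next
    }
    res <- run_funbat(collapsed, sets, ph, ...)
    rho <- suppressWarnings(
      stats::cor(res$beta, full$beta, method = "spearman",
                 use = "pairwise.complete.obs"))
    out[[length(out) + 1L]] <- data.frame(fraction = f, rep = r,
                                          spearman_r = rho,
                                          n_strata = length(unique(inf$family_id)),
                                          skipped = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "full") <- full
  res
}
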