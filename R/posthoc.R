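# Post-hoc analyses around the burden scan: gene prioritization by gene-set
# downsampling, Fisher-exact enrichments, size-matched effect
# normalization, and permutation tests for subgroup liability biases.

#' Prioritize genes by gene-set downsampling
#'
#' Draws `n_subsets` random sub-gene sets of `subset_size` genes from a
#' significant gene set, refits the burden model on each, flags subsets
#' significant at BH FDR < `fdr` (one family over the subsets), and then
#' asks per gene whether it is enriched among the significant subsets
#' (two-sided Fisher test of the 2x2 significant x contains-gene table,
#' second BH family over genes). A gene is prioritized when its enrichment
#' is FDR-significant with OR > 1.
#'
#' @param set_genes character vector, the gene set (longer than
#'   `subset_size`).
#' @param collapsed,phenotype,covariates as in [funbat()].
#' @param class variant class tested.
#' @param n_subsets number of random subsets. Default 1000.
#' @param subset_size genes per subset. Default 100.
#' @param fdr significance level for both BH families. Default 0.05.
#' @param seed integer seed.
#' @return data.frame of class `funbat_prioritization`: per gene the subset
#'   membership counts, enrichment OR, p, q and `prioritized`; subset-level
#'   results attached as attribute `subsets`.
#' @export
prioritize_genes <- function(set_genes, collapsed, phenotype, class,
                             covariates = NULL, n_subsets = 1000,
                             subset_size = 100, fdr = 0.05, seed = 1) {
  if (subset_size >= length(set_genes))
    stop("subset_size must be smaller than the gene set")
  set.seed(seed)
  individuals <- phenotype$individual_id
  membership <- matrix(FALSE, length(set_genes), n_subsets,
                       dimnames = list(set_genes, NULL))
  p <- numeric(n_subsets)
  for (s in seq_len(n_subsets)) {
    sub <- sample(set_genes, subset_size)
    membership[sub, s] <- TRUE
    fit <- funbat(compute_burden(collapsed, sub, class, individuals),
                  phenotype, covariates = covariates)
    p[s] <- fit$p
  }
  q_sub <- stats::p.adjust(p, "BH")
  sig <- !is.na(q_sub) & q_sub < fdr
  if (!any(sig)) warning("no significant subsets: empty prioritization")
  n_sig <- sum(sig)
  res <- data.frame(gene = set_genes,
                    n_significant_subsets = rowSums(membership[, sig, drop = FALSE]),
                    n_subsets_containing = rowSums(membership),
                    stringsAsFactors = FALSE)
  enr <- lapply(seq_len(nrow(res)), function(i) {
    a <- res$n_significant_subsets[i]
    b <- n_sig - a
    c <- res$n_subsets_containing[i] - a
    d <- n_subsets - n_sig - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "two.sided")
    c(or = .sample_or(a, b, c, d), p = ft$p.value)
  })
  res$or <- vapply(enr, `[[`, 0, "or")
  res$p <- vapply(enr, `[[`, 0, "p")
  res$q <- stats::p.adjust(res$p, "BH")
  res$prioritized <- !is.na(res$q) & res$q < fdr & res$or > 1
  attr(res, "subsets") <- data.frame(p = p, q = q_sub, significant = sig)
  class(res) <- c("funbat_prioritization", "data.frame")
  res
}

# sample odds ratio with Haldane-Anscombe 0.5 correction on zero cells
.sample_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a * d) / (b * c)
}

#' Fisher-exact enrichment of a gene list in a gene set
#'
#' Builds the 2x2 in/out-query by in/out-target table over a reference gene
#' universe and tests it with a two-sided Fisher exact test. The reported OR
#' is the sample odds ratio, with a Haldane 0.5 correction (flagged) when a
#' cell is zero.
#'
#' @param query,target character vectors, both subsets of `universe`.
#' @param universe reference gene universe (e.g. all autosomal
#'   protein-coding genes).
#' @return list `or`, `p`, `table`, `corrected`.
#' @export
fisher_enrichment <- function(query, target, universe) {
  if (length(query) == 0L) stop("empty query gene list")
  query <- intersect(query, universe)
  target <- intersect(target, universe)
  a <- length(intersect(query, target))
  b <- length(setdiff(query, target))
  c <- length(setdiff(target, query))
  d <- length(universe) - a - b - c
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"), target = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(or = .sample_or(a, b, c, d), p = ft$p.value, table = tab,
       corrected = any(tab == 0))
}

#' De novo versus inherited enrichment across gene sets
#'
#' Two contingency designs over called de novo variants. `vs_all_genes`:
#' per set, the 2x2 of (de novo, inherited) x (in set, in the rest of the
#' expressed-gene universe). `case_vs_sibling`: per set, restricted to set
#' genes, the 2x2 of (de novo, inherited) x (affected, unaffected sibling).
#' Two-sided Fisher tests with BH correction across sets.
#'
#' @param variants variant data.frame carrying a logical `de_novo` column
#'   (see [call_de_novo()]; NA-status variants are ignored).
#' @param sets named list of gene sets.
#' @param universe expressed-gene universe for the `vs_all_genes` design.
#' @param phenotype cohort table (needed for `case_vs_sibling`):
#'   `individual_id`, `affected`, and `role` where offspring are
#'   identifiable.
#' @param design contingency design.
#' @return data.frame per set: counts, `or`, `p`, `q`.
#' @export
de_novo_enrichment <- function(variants, sets, universe = NULL,
                               phenotype = NULL,
                               design = c("vs_all_genes", "case_vs_sibling")) {
  design <- match.arg(design)
  v <- variants[!is.na(variants$de_novo), , drop = FALSE]
  if (sum(v$de_novo) == 0) {
    warning("no de novo variants: enrichment undefined")
    return(data.frame(set = names(sets), or = NA_real_, p = NA_real_,
                      q = NA_real_))
  }
  if (design == "vs_all_genes") {
    stopifnot(!is.null(universe))
    v <- v[v$gene %in% universe, , drop = FALSE]
    rows <- lapply(names(sets), function(s) {
      ins <- v$gene %in% sets[[s]]
      a <- sum(v$de_novo & ins); b <- sum(!v$de_novo & ins)
      c <- sum(v$de_novo & !ins); d <- sum(!v$de_novo & !ins)
      ft <- stats::fisher.test(matrix(c(a, b, c, d), 2))
      data.frame(set = s, dn_in = a, inh_in = b, dn_out = c, inh_out = d,
                 or = .sample_or(a, b, c, d), p = ft$p.value)
    })
  } else {
    stopifnot(!is.null(phenotype))
    aff <- stats::setNames(phenotype$affected, phenotype$individual_id)
    sib <- phenotype$individual_id[phenotype$affected == 0 &
                                     phenotype$role == "child"]
    if (length(sib) == 0L) stop("no unaffected siblings in the cohort")
    case <- phenotype$individual_id[phenotype$affected == 1 &
                                      phenotype$role == "child"]
    rows <- lapply(names(sets), function(s) {
      u <- v[v$gene %in% sets[[s]], , drop = FALSE]
      inc <- u$individual_id %in% case
      ins <- u$individual_id %in% sib
      a <- sum(u$de_novo & inc); b <- sum(!u$de_novo & inc)
      c <- sum(u$de_novo & ins); d <- sum(!u$de_novo & ins)
      ft <- stats::fisher.test(matrix(c(a, b, c, d), 2))
      data.frame(set = s, dn_case = a, inh_case = b, dn_sib = c, inh_sib = d,
                 or = .sample_or(a, b, c, d), p = ft$p.value)
    })
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Null distribution of burden effects from random gene sets
#'
#' Draws random gene sets of a grid of sizes from the universe, fits the
#' burden model on each, and stores the per-size mean and SD of the effect
#' estimates. Used to normalize observed effects for gene-set size.
#'
#' @inheritParams prioritize_genes
#' @param universe gene universe to sample from.
#' @param sizes grid of set sizes. Default 50 to 950 by 50; sizes exceeding
#'   the universe are skipped with a warning.
#' @param reps_per_size random sets per size. Default 30.
#' @return object of class `funbat_null_dist`: data.frame `size`, `mean`,
#'   `sd`, `n`; raw estimates attached as attribute `estimates`.
#' @export
build_null_effect_distribution <- function(universe, collapsed, phenotype,
                                           class, covariates = NULL,
                                           sizes = seq(50, 950, 50),
                                           reps_per_size = 30, seed = 1) {
  set.seed(seed)
  feasible <- sizes[sizes <= length(universe)]
  if (length(feasible) < length(sizes))
    warning("skipping sizes larger than the gene universe")
  individuals <- phenotype$individual_id
  est <- lapply(feasible, function(sz) {
    vapply(seq_len(reps_per_size), function(r) {
      g <- sample(universe, sz)
      funbat(compute_burden(collapsed, g, class, individuals), phenotype,
             covariates = covariates)$beta
    }, 0)
  })
  out <- data.frame(size = feasible,
                    mean = vapply(est, mean, 0, na.rm = TRUE),
                    sd = vapply(est, stats::sd, 0, na.rm = TRUE),
                    n = vapply(est, function(e) sum(!is.na(e)), 0L))
  attr(out, "estimates") <- est
  class(out) <- c("funbat_null_dist", "data.frame")
  out
}

#' Size-normalize a burden effect against the random-set null
#'
#' `z = (estimate - mean_closest) / sd_closest`, where the closest null grid
#' size is chosen by absolute difference (ties to the smaller size).
#'
#' @param estimate observed effect (log-OR), e.g. `fit$beta`.
#' @param set_size size of the gene set behind the estimate.
#' @param null a [build_null_effect_distribution()] result.
#' @return normalized effect (NA with a warning if the matched SD is 0).
#' @export
normalize_effect_size <- function(estimate, set_size, null) {
  d <- abs(null$size - set_size)
  i <- which(d == min(d))[1] # grid sorted ascending: ties resolve to smaller
  if (is.na(null$sd[i]) || null$sd[i] == 0) {
    warning("null SD is 0 at matched size; returning NA")
    return(NA_real_)
  }
  (estimate - null$mean[i]) / null$sd[i]
}

#' Permutation test for subgroup differences in burden liability
#'
#' For each gene set and class, compares the burden effect estimated when
#' only subgroup-A cases are retained as cases against the estimate with
#' only subgroup-B cases (controls shared by both fits), and builds the null
#' by randomly re-splitting the cases `n_perm` times preserving the subgroup
#' proportion. The observed difference of log-ORs is significant when it
#' falls outside the 5th-95th percentile band of the null; a symmetric
#' rank-based two-tail empirical p is also reported and BH-corrected across
#' (set x class) cells.
#'
#' @inheritParams run_funbat
#' @param group named vector (by individual id) assigning each *case* to one
#'   of exactly two subgroups; controls are ignored.
#' @param n_perm number of permutations (> 0). Default 5000.
#' @param seed integer seed.
#' @param band percentile band for the significance call. Default
#'   `c(0.05, 0.95)`.
#' @return data.frame of class `funbat_subgroup`: per set x class the
#'   observed difference, percentile, empirical p, q and `significant`.
#' @export
subgroup_permutation_test <- function(collapsed, sets, phenotype, group,
                                      classes, covariates = NULL,
                                      n_perm = 5000, seed = 1,
                                      band = c(0.05, 0.95)) {
  if (n_perm < 1) stop("n_perm must be positive")
  set.seed(seed)
  cases <- phenotype$individual_id[phenotype$affected == 1]
  grp <- group[cases]
  if (anyNA(grp)) stop("every case needs a subgroup label")
  lev <- unique(grp)
  if (length(lev) != 2L) stop("group must define exactly two subgroups")
  individuals <- phenotype$individual_id

  # estimate with only one subgroup's cases kept as cases; the other
  # subgroup's cases are removed (controls are shared)
  est_for <- function(burden, keep_cases) {
    keep <- phenotype$affected == 0 | phenotype$individual_id %in% keep_cases
    fit <- funbat(burden[phenotype$individual_id[keep]],
                  phenotype[keep, , drop = FALSE], covariates = covariates)
    fit$beta
  }
  rows <- list()
  for (set_id in names(sets)) for (cl in classes) {
    burden <- compute_burden(collapsed, sets[[set_id]], cl, individuals)
    obs_a <- est_for(burden, cases[grp == lev[1]])
    obs_b <- est_for(burden, cases[grp == lev[2]])
    obs <- obs_a - obs_b
    null <- vapply(seq_len(n_perm), function(i) {
      pg <- sample(grp)
      est_for(burden, cases[pg == lev[1]]) - est_for(burden, cases[pg == lev[2]])
    }, 0)
    ok <- !is.na(null)
    pct <- 100 * mean(null[ok] < obs)
    lo <- stats::quantile(null[ok], band[1], na.rm = TRUE)
    hi <- stats::quantile(null[ok], band[2], na.rm = TRUE)
    p_emp <- 2 * min((1 + sum(null[ok] <= obs)) / (sum(ok) + 1),
                     (1 + sum(null[ok] >= obs)) / (sum(ok) + 1))
    rows[[paste(set_id, cl)]] <- data.frame(
      set = set_id, class = cl, observed_diff = obs, percentile = pct,
      p = min(p_emp, 1), significant = !is.na(obs) && (obs < lo || obs > hi),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, "BH")
  class(out) <- c("funbat_subgroup", "data.frame")
  out
}
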