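# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: the conditional likelihood is enumerated and
# maximized by grid search, and AUC is the brute-force pairwise
# win/tie/loss probability.

# exact conditional log-likelihood of a single burden coefficient:
# each stratum conditions on its observed number of cases, enumerating all
# case assignments of that size
oracle_condloglik <- function(beta, strata) {
  ll <- 0
  for (s in strata) {
    b <- s$burden
    y <- s$y
    m <- sum(y)
    if (m == 0 || m == length(y)) next
    num <- beta * sum(b[y == 1])
    subsets <- utils::combn(length(b), m)
    den <- log(sum(exp(beta * colSums(matrix(b[subsets], nrow = m)))))
    ll <- ll + num - den
  }
  ll
}

# grid search (step 1e-3 on [-8, 8]) refined by optimize on the best bracket
oracle_condlogit_mle <- function(strata) {
  grid <- seq(-8, 8, by = 1e-3)
  ll <- vapply(grid, oracle_condloglik, 0, strata = strata)
  i <- which.max(ll)
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  stats::optimize(oracle_condloglik, c(lo, hi), strata = strata,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# brute-force pairwise AUC: P(in > out) + 0.5 P(in == out) over all pairs
oracle_pairwise_auc <- function(v_in, v_out) {
  wins <- outer(v_in, v_out, ">")
  ties <- outer(v_in, v_out, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(v_in) * length(v_out))
}

# random small stratified instance for the conditional-logistic oracle
random_strata_instance <- function(n_strata = 3, max_size = 4) {
  strata <- list()
  for (s in seq_len(n_strata)) {
    size <- sample(2:max_size, 1)
    repeat {
      y <- rbinom(size, 1, 0.5)
      if (any(y == 1) && any(y == 0)) break
    }
    strata[[s]] <- list(burden = rpois(size, 1.2), y = y)
  }
  strata
}

# assemble a phenotype data.frame + burden vector from oracle strata
strata_to_cohort <- function(strata) {
  rows <- lapply(seq_along(strata), function(s) {
    k <- length(strata[[s]]$y)
    data.frame(individual_id = sprintf("f%d_i%d", s, seq_len(k)),
               family_id = sprintf("f%d", s),
               affected = strata[[s]]$y, stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, rows)
  list(phenotype = ph,
       burden = stats::setNames(unlist(lapply(strata, `[[`, "burden")),
                                ph$individual_id))
}

# compact null/planted cohort simulation used by several tests
sim_and_fit <- function(seed, n_families = 500, theta = NULL, class = "missense",
                        fit_class = class, covariates = "sex",
                        set_genes = sprintf("g%04d", 1:60),
                        rate_missense = 0.015) {
  sets <- list(S = set_genes)
  pe <- if (!is.null(theta))
    data.frame(set = "S", class = class, theta = theta)
  cfg <- cohort_sim_config(
    n_families = n_families, sets = sets, planted_effects = pe,
    per_gene_rate = c(stop_gained = 0.002, frameshift = 0.002,
                      missense = rate_missense, splice = 0.002,
                      synonymous = 0.02),
    seed = seed)
  ch <- simulate_cohort(cfg)
  qc <- qc_filter_short_variants(ch$variants)
  coll <- collapse_by_gene(qc$variants)
  b <- compute_burden(coll, set_genes, fit_class, ch$pedigree$individual_id)
  list(fit = funbat(b, ch$pedigree, covariates = covariates), cohort = ch,
       collapsed = coll, burden = b)
}
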