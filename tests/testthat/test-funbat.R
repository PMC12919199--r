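test_that("burden counts distinct disrupted set genes per individual", {
  coll <- collapse_by_gene(data.frame(
    individual_id = c("i1", "i1", "i1", "i2"),
    gene = c("gA", "gA", "gB", "gD"),
    class = c("missense", "missense", "missense", "missense")))
  b <- compute_burden(coll, c("gA", "gB", "gC"), "missense", c("i1", "i2", "i3"))
  expect_equal(b, c(i1 = 2L, i2 = 0L, i3 = 0L))
  # empty disruption table: all zero
  b0 <- compute_burden(collapse_by_gene(), c("gA"), "missense", c("i1"))
  expect_equal(b0, c(i1 = 0L))
  expect_error(compute_burden(coll, character(0), "missense", "i1"), "empty")
  # random instance equals a brute-force double loop
  set.seed(10)
  rv <- data.frame(individual_id = sample(sprintf("i%d", 1:6), 80, TRUE),
                   gene = sample(sprintf("g%d", 1:10), 80, TRUE),
                   class = "splice")
  coll2 <- collapse_by_gene(rv)
  set_g <- sprintf("g%d", 1:4); inds <- sprintf("i%d", 1:6)
  got <- compute_burden(coll2, set_g, "splice", inds)
  brute <- vapply(inds, function(i)
    length(unique(rv$gene[rv$individual_id == i & rv$gene %in% set_g])), 0L)
  expect_equal(got, brute)
})

test_that("strata filtering keeps only families with outcome diversity", {
  ph <- data.frame(
    individual_id = sprintf("i%d", 1:8),
    family_id = c("single", "trio", "trio", "trio", "allcase", "allcase",
                  "pair", "pair"),
    affected = c(1, 1, 0, 0, 1, 1, 0, 1))
  out <- filter_strata(ph)
  expect_setequal(unique(out$family_id), c("trio", "pair"))
  expect_equal(attr(out, "n_dropped_strata"), 2L)
  expect_equal(attr(out, "n_dropped_individuals"), 3L)
})

test_that("matched discordant pairs reproduce the closed-form log odds ratio", {
  # 6 pairs where only the case carries the exposure, 3 where only the
  # control does: conditional MLE is log(6/3)
  n10 <- 6; n01 <- 3
  ph <- data.frame(
    individual_id = sprintf("p%d_%d", rep(1:(n10 + n01), each = 2), 1:2),
    family_id = rep(sprintf("p%d", 1:(n10 + n01)), each = 2),
    affected = rep(c(1, 0), n10 + n01))
  burden <- stats::setNames(
    c(rep(c(1, 0), n10), rep(c(0, 1), n01)), ph$individual_id)
  fit <- funbat(burden, ph)
  expect_equal(fit$beta, log(2), tolerance = 1e-6)
})

test_that("the fit matches the brute-force conditional-likelihood oracle", {
  set.seed(21)
  for (rep in 1:12) {
    strata <- random_strata_instance()
    cohort <- strata_to_cohort(strata)
    fit <- funbat(cohort$burden, cohort$phenotype)
    if (fit$inestimable || fit$diverged) next
    expect_equal(fit$beta, oracle_condlogit_mle(strata), tolerance = 1e-4)
  }
})

test_that("degenerate designs are flagged instead of fit", {
  # burden identical within every stratum: conditioning removes it
  ph <- data.frame(individual_id = sprintf("i%d", 1:4),
                   family_id = c("f1", "f1", "f2", "f2"),
                   affected = c(1, 0, 1, 0))
  fit <- funbat(stats::setNames(c(2, 2, 5, 5), ph$individual_id), ph)
  expect_true(fit$inestimable)
  expect_true(is.na(fit$beta))
  # no informative strata at all is an error
  ph2 <- ph; ph2$affected <- 1
  expect_error(funbat(stats::setNames(1:4, ph$individual_id), ph2),
               "no informative strata")
})

test_that("the likelihood is invariant to adding non-diverse strata", {
  set.seed(33)
  strata <- random_strata_instance(n_strata = 5)
  cohort <- strata_to_cohort(strata)
  fit1 <- funbat(cohort$burden, cohort$phenotype)
  # append a singleton and an all-affected family
  extra <- data.frame(individual_id = c("x1", "x2", "x3"),
                      family_id = c("fx", "fy", "fy"),
                      affected = c(1, 1, 1))
  ph2 <- rbind(cohort$phenotype, extra)
  b2 <- c(cohort$burden, stats::setNames(c(3, 1, 2), extra$individual_id))
  fit2 <- funbat(b2, ph2)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit2$n_dropped_strata, fit1$n_dropped_strata + 2L)
})

test_that("scan over sets and classes applies BH within the declared family", {
  set.seed(44)
  res <- sim_and_fit(3, n_families = 200)
  sets <- list(S1 = sprintf("g%04d", 1:40), S2 = sprintf("g%04d", 41:80))
  scan <- run_funbat(res$collapsed, sets, res$cohort$pedigree,
                     classes = c("missense", "synonymous"))
  expect_s3_class(scan, "funbat_scan")
  expect_equal(nrow(scan), 4L)
  ok <- !is.na(scan$p)
  expect_equal(scan$q[ok], stats::p.adjust(scan$p[ok], "BH"))
  # single set, single class: FDR equals p
  scan1 <- run_funbat(res$collapsed, sets["S1"], res$cohort$pedigree,
                      classes = "missense")
  expect_equal(scan1$q, scan1$p)
})

test_that("the CNV model corrects the set estimate for multigenic background", {
  res <- sim_and_fit(17, n_families = 300)
  ch <- res$cohort
  fc <- filter_cnvs(ch$cnvs)
  cg <- annotate_cnv_genes(fc, ch$genes)
  coll <- collapse_by_gene(res$collapsed, cg)
  loeuf <- stats::setNames(ch$genes$loeuf, ch$genes$gene)
  scan <- run_funbat(coll, list(S = sprintf("g%04d", 1:60)), ch$pedigree,
                     classes = c("deletion", "missense"), loeuf = loeuf)
  expect_equal(nrow(scan), 2L)
  # the deletion row used the two-burden model: coefficients are present
  b <- compute_burden(coll, sprintf("g%04d", 1:60), "deletion",
                      ch$pedigree$individual_id)
  other <- coll[coll$class == "deletion" &
                  !(coll$gene %in% sprintf("g%04d", 1:60)), ]
  lo <- loeuf[other$gene]
  ids <- ch$pedigree$individual_id
  bg <- list(
    constrained = stats::setNames(as.integer(table(factor(
      unique(other[lo < 1, 1:2])$individual_id, levels = ids))), ids),
    unconstrained = stats::setNames(as.integer(table(factor(
      unique(other[lo >= 1, 1:2])$individual_id, levels = ids))), ids))
  fit <- funbat(b, ch$pedigree, background = bg)
  expect_true(all(c(".burden", ".bg_constrained", ".bg_unconstrained") %in%
                    names(coef(fit))))
  expect_equal(fit$beta, scan$beta[scan$class == "deletion"], tolerance = 1e-8)
})

test_that("downsampling stability returns full correlation at fraction 1", {
  res <- sim_and_fit(5, n_families = 150, theta = 0.8)
  sets <- list(S1 = sprintf("g%04d", 1:30), S2 = sprintf("g%04d", 31:60),
               S3 = sprintf("g%04d", 61:90))
  st <- cohort_downsampling_stability(res$collapsed, sets, res$cohort$pedigree,
                                      fractions = 1, reps = 2, seed = 1,
                                      classes = c("missense", "synonymous"))
  expect_true(all(st$spearman_r == 1))
  # tiny fractions on a tiny cohort exercise the skip guard
  tiny <- res$cohort$pedigree[res$cohort$pedigree$family_id %in%
                                unique(res$cohort$pedigree$family_id)[1:8], ]
  st2 <- cohort_downsampling_stability(res$collapsed, sets, tiny,
                                       fractions = 0.1, reps = 3, seed = 2,
                                       classes = "missense")
  expect_true(all(st2$skipped | !is.na(st2$spearman_r)))
})

test_that("the constraint-window sweep localizes signal in constrained genes", {
  res <- sim_and_fit(61, n_families = 600, theta = 1,
                     set_genes = sprintf("g%04d", 1:60), rate_missense = 0.02)
  ch <- res$cohort
  # planted set genes g0001..g0060 get low LOEUF, the rest high
  lo <- stats::setNames(ch$genes$loeuf, ch$genes$gene)
  lo[sprintf("g%04d", 1:60)] <- seq(0.05, 0.55, length.out = 60)
  lo[setdiff(names(lo), sprintf("g%04d", 1:60))] <-
    seq(0.7, 1.9, length.out = sum(!(names(lo) %in% sprintf("g%04d", 1:60))))
  sw <- loeuf_window_scan(res$collapsed, ch$pedigree, lo, "missense",
                          window_size = 60, step = 70)
  expect_equal(nrow(sw), 3L)
  expect_true(all(diff(sw$loeuf_min) > 0))
  # the most constrained window contains the planted genes: largest beta
  expect_equal(which.max(sw$beta), 1L)
  expect_error(loeuf_window_scan(res$collapsed, ch$pedigree, lo[1:10],
                                 "missense", window_size = 60), "fewer genes")
})

test_that("model object methods expose the fit", {
  res <- sim_and_fit(2, n_families = 200)
  fit <- res$fit
  expect_s3_class(fit, "funbat")
  expect_output(print(fit), "informative strata")
  expect_equal(unname(exp(coef(fit)[".burden"])), fit$or)
  expect_equal(nrow(vcov(fit)), length(coef(fit)))
  ci <- confint(fit)
  expect_true(ci[1] < fit$beta && fit$beta < ci[2])
  expect_equal(nobs(fit), fit$n_individuals)
})
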