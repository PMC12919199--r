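toy_variants <- function() {
  utils::read.delim(system.file("extdata", "toy_variants.tsv", package = "funbat"),
                    stringsAsFactors = FALSE)
}

test_that("QC cascade retains exactly the engineered survivor with matching attrition", {
  tv <- toy_variants()
  qc <- qc_filter_short_variants(tv)
  expect_equal(qc$n_retained, 1L)
  expect_equal(qc$variants$individual_id, "ind6")
  expect_equal(qc$attrition,
               c(depth = 1, genotype_quality = 1, allele_ratio = 1, maf = 1,
                 class_rule = 1))
  expect_equal(qc$n_missing_score, 0L)
})

test_that("QC rules follow the documented thresholds and the cascade is order-invariant", {
  base <- data.frame(individual_id = "i", gene = "g", class = "missense",
                     DP = 30, GQ = 40, allele_ratio = 0.5, maf_cohort = 0,
                     maf_reference = 0, loftee_hc = NA, alphamissense = 0.95,
                     spliceai_delta = NA)
  expect_equal(qc_filter_short_variants(base)$n_retained, 1L)
  # boundary values are inclusive: DP 20, GQ 30, ratio 0.2/0.8, MAF 1e-3, AM 0.9
  b <- base; b$DP <- 20; b$GQ <- 30; b$allele_ratio <- 0.2; b$maf_cohort <- 1e-3
  expect_equal(qc_filter_short_variants(b)$n_retained, 1L)
  b$allele_ratio <- 0.81
  expect_equal(qc_filter_short_variants(b)$n_retained, 0L)
  # class rules: LoFtee for stop/frameshift, SpliceAI for splice, none for synonymous
  sg <- base; sg$class <- "stop_gained"; sg$loftee_hc <- FALSE
  expect_equal(qc_filter_short_variants(sg)$n_retained, 0L)
  sg$loftee_hc <- TRUE
  expect_equal(qc_filter_short_variants(sg)$n_retained, 1L)
  sp <- base; sp$class <- "splice"; sp$alphamissense <- NA; sp$spliceai_delta <- 0.8
  expect_equal(qc_filter_short_variants(sp)$n_retained, 1L)
  syn <- base; syn$class <- "synonymous"; syn$alphamissense <- NA
  expect_equal(qc_filter_short_variants(syn)$n_retained, 1L)
  # missing class score drops the record and is counted separately
  ms <- base; ms$alphamissense <- NA
  qm <- qc_filter_short_variants(ms)
  expect_equal(qm$n_retained, 0L)
  expect_equal(qm$n_missing_score, 1L)
  # order invariance: filtering a shuffled table gives the same retained set
  tv <- toy_variants()
  set.seed(4)
  shuf <- tv[sample(nrow(tv)), ]
  expect_setequal(qc_filter_short_variants(shuf)$variants$individual_id,
                  qc_filter_short_variants(tv)$variants$individual_id)
})

test_that("CNV filter applies size/score thresholds and classifies dosage", {
  cnvs <- data.frame(
    individual_id = c("i1", "i2", "i3", "i4"),
    chrom = "chr1",
    start = c(0, 0, 0, 0), end = c(4e4, 6e4, 6e4, 5e4),
    copy_number = c(1L, 1L, 3L, 0L),
    likelihood_score = c(50, 50, 31, 10))
  out <- filter_cnvs(cnvs)
  # 40 kb removed; score 10 removed; exactly-50kb retained? no: i4 fails score
  expect_setequal(out$individual_id, c("i2", "i3"))
  expect_equal(out$type[out$individual_id == "i2"], "deletion")
  expect_equal(out$type[out$individual_id == "i3"], "duplication")
  cn2 <- cnvs; cn2$copy_number[1] <- 2L
  expect_error(filter_cnvs(cn2), "not a CNV")
  # precomputed artifact-overlap flag removes calls when present
  cn3 <- cnvs; cn3$artifact_overlap <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(filter_cnvs(cn3)$individual_id, "i3")
})

test_that("batch heterogeneity filter removes batch-concentrated CNVs only", {
  samples <- data.frame(
    individual_id = sprintf("p%03d", 1:200),
    batch = rep(c("b1", "b2"), each = 100),
    is_parent = TRUE)
  # CNV "even" appears in 10 parents of each batch; "skewed" in 30 of batch 1
  mk <- function(ids, start) data.frame(
    individual_id = ids, chrom = "chr1", start = start, end = start + 6e4,
    copy_number = 1L, likelihood_score = 50, type = "deletion",
    batch = samples$batch[match(ids, samples$individual_id)])
  cnvs <- rbind(mk(sprintf("p%03d", c(1:10, 101:110)), 0),
                mk(sprintf("p%03d", 1:30), 1e6))
  res <- batch_heterogeneity_filter(cnvs, samples)
  expect_equal(res$removed, "chr1:1000000:1060000:deletion")
  expect_true(all(res$cnvs$start == 0))
  # hand chi-square on the skewed 2x2: 30/100 vs 0/100
  tab <- rbind(c(30, 0), c(70, 100))
  expect_equal(res$tests$p[res$tests$key == res$removed],
               suppressWarnings(chisq.test(tab, correct = FALSE))$p.value)
  # single batch: no-op
  s1 <- samples[samples$batch == "b1", ]
  res1 <- batch_heterogeneity_filter(cnvs[cnvs$individual_id %in% s1$individual_id, ], s1)
  expect_length(res1$removed, 0)
})

test_that("CNV-gene intersection is half-open and matches a brute-force scan", {
  genes <- data.frame(gene = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(150, 200, 500), end = c(300, 300, 600))
  cnvs <- data.frame(individual_id = "i1", chrom = "chr1",
                     start = 100, end = 200, copy_number = 1L,
                     likelihood_score = 50, type = "deletion")
  hits <- annotate_cnv_genes(cnvs, genes)
  # [100,200) overlaps [150,300) but not [200,300) (half-open boundary)
  expect_equal(hits$gene, "gA")
  expect_equal(hits$class, "deletion")
  # multigenic CNV emits one record per gene with a shared id
  cnvs$end <- 550
  hits3 <- annotate_cnv_genes(cnvs, genes)
  expect_setequal(hits3$gene, c("gA", "gB", "gC"))
  expect_equal(length(unique(hits3$cnv_id)), 1L)
  # property: random instances match the quadratic brute-force scan
  set.seed(8)
  for (rep in 1:5) {
    g <- data.frame(gene = sprintf("g%03d", 1:50), chrom = "chr1",
                    start = sample(0:5000, 50), end = 0)
    g$end <- g$start + sample(50:500, 50, TRUE)
    cv <- data.frame(individual_id = sprintf("i%02d", 1:20), chrom = "chr1",
                     start = sample(0:5000, 20), end = 0, copy_number = 3L,
                     likelihood_score = 50, type = "duplication")
    cv$end <- cv$start + sample(50:800, 20, TRUE)
    got <- annotate_cnv_genes(cv, g)
    brute <- sum(outer(seq_len(20), seq_len(50), Vectorize(function(i, j)
      cv$start[i] < g$end[j] && g$start[j] < cv$end[i])))
    expect_equal(nrow(got), brute)
  }
  # contig mismatch skipped with a warning
  cv2 <- cnvs; cv2$chrom <- "chrX"
  expect_warning(out <- annotate_cnv_genes(cv2, genes), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("gene collapse is binary, idempotent and matches an existence scan", {
  v <- data.frame(individual_id = c("i1", "i1", "i1", "i2"),
                  gene = c("gA", "gA", "gA", "gA"),
                  class = c("missense", "missense", "stop_gained", "missense"))
  coll <- collapse_by_gene(v)
  # three missense in one gene collapse to one flag; classes independent
  expect_equal(nrow(coll), 3L)
  expect_equal(sum(coll$individual_id == "i1" & coll$class == "missense"), 1L)
  expect_equal(sum(coll$individual_id == "i1" & coll$class == "stop_gained"), 1L)
  # idempotent and monotone
  expect_equal(collapse_by_gene(rbind(v, v)), coll)
  v2 <- rbind(v, data.frame(individual_id = "i3", gene = "gB", class = "splice"))
  expect_true(all(do.call(paste, coll) %in% do.call(paste, collapse_by_gene(v2))))
  # random instance vs brute-force per-triple scan
  set.seed(6)
  rv <- data.frame(individual_id = sample(sprintf("i%d", 1:5), 60, TRUE),
                   gene = sample(sprintf("g%d", 1:8), 60, TRUE),
                   class = sample(c("missense", "synonymous"), 60, TRUE))
  got <- collapse_by_gene(rv)
  brute <- unique(rv[, c("individual_id", "gene", "class")])
  expect_equal(nrow(got), nrow(brute))
})

test_that("de novo calling, severity selection and outlier removal work on trios", {
  ped <- data.frame(individual_id = c("dad", "mom", "kid", "solo"),
                    father_id = c(NA, NA, "dad", NA),
                    mother_id = c(NA, NA, "mom", NA))
  v <- data.frame(
    individual_id = c("kid", "kid", "kid", "kid", "solo"),
    gene = c("g1", "g2", "g2", "g3", "g4"),
    class = c("missense", "frameshift", "synonymous", "missense", "missense"),
    father_carrier = c(FALSE, FALSE, FALSE, TRUE, NA),
    mother_carrier = c(FALSE, FALSE, FALSE, FALSE, NA))
  res <- call_de_novo(v, ped)
  expect_equal(res$variants$de_novo, c(TRUE, TRUE, TRUE, FALSE, NA))
  # g2 has de novo frameshift + synonymous: frameshift kept, synonymous dropped
  g2 <- res$de_novo[res$de_novo$gene == "g2", ]
  expect_equal(g2$class, "frameshift")
  expect_equal(nrow(res$de_novo), 2L) # g1 missense + g2 frameshift
  expect_equal(res$n_unknown, 1L)
  # outlier offspring: > 10 genes with de novo synonymous removed entirely
  many <- data.frame(individual_id = "kid", gene = sprintf("s%02d", 1:11),
                     class = "synonymous", father_carrier = FALSE,
                     mother_carrier = FALSE)
  res2 <- call_de_novo(rbind(v, many), ped)
  expect_equal(res2$excluded_individuals, "kid")
  expect_equal(nrow(res2$de_novo), 0L)
})
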