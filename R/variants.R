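# Rare-variant and CNV quality-control cascades, gene collapsing, and
# trio-based de novo calling.
#
# Short-variant tables are tab-delimited with one row per variant call and
# columns: individual_id, gene, class (stop_gained, frameshift, missense,
# splice, synonymous), DP, GQ, allele_ratio, maf_cohort, maf_reference,
# loftee_hc, alphamissense, spliceai_delta, father_carrier, mother_carrier.
# CNV tables are BED-like (0-based half-open): individual_id, chrom, start,
# end, copy_number, likelihood_score, batch.

#' Severity order of variant consequence classes (most severe first)
#' @export
consequence_severity <- c("stop_gained", "frameshift", "splice", "missense",
                          "synonymous")

#' Quality-control filter for annotated rare short variants
#'
#' Retains variants passing all of: read depth DP >= 20, genotype quality
#' GQ >= 30, alternate allele ratio in `[0.2, 0.8]` (rare variants are not
#' expected homozygous), cohort and reference minor allele frequency
#' <= 1/1000, and the class-specific pathogenicity rule (LoFtee
#' high-confidence for stop-gained/frameshift; AlphaMissense >= 0.9 for
#' missense; SpliceAI max delta >= 0.8 for splice; no extra rule for
#' synonymous). Records missing their class-required score are dropped and
#' counted separately. All predicates are conjunctive, so the cascade is
#' order-invariant; attrition counts are marginal (a record can fail several
#' filters).
#'
#' @param variants short-variant data.frame (see file header for columns).
#' @param dp_min,gq_min,ratio_range,maf_max,am_min,spliceai_min threshold
#'   knobs; defaults are the standard cascade above.
#' @return list with `variants` (retained rows), `attrition` (named counts of
#'   records failing each filter), and `n_missing_score`.
#' @export
qc_filter_short_variants <- function(variants, dp_min = 20, gq_min = 30,
                                     ratio_range = c(0.2, 0.8), maf_max = 1e-3,
                                     am_min = 0.9, spliceai_min = 0.8) {
  req <- c("individual_id", "gene", "class", "DP", "GQ", "allele_ratio",
           "maf_cohort", "maf_reference")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  fail_dp <- variants$DP < dp_min
  fail_gq <- variants$GQ < gq_min
  fail_ratio <- variants$allele_ratio < ratio_range[1] |
    variants$allele_ratio > ratio_range[2]
  fail_maf <- variants$maf_cohort > maf_max | variants$maf_reference > maf_max

  cls <- variants$class
  score_missing <- rep(FALSE, nrow(variants))
  fail_class <- rep(FALSE, nrow(variants))
  lof <- cls %in% c("stop_gained", "frameshift")
  if (any(lof)) {
    sm <- is.na(variants$loftee_hc[lof])
    score_missing[lof] <- sm
    fail_class[lof] <- !sm & !variants$loftee_hc[lof]
  }
  mis <- cls == "missense"
  if (any(mis)) {
    sm <- is.na(variants$alphamissense[mis])
    score_missing[mis] <- sm
    fail_class[mis] <- !sm & variants$alphamissense[mis] < am_min
  }
  spl <- cls == "splice"
  if (any(spl)) {
    sm <- is.na(variants$spliceai_delta[spl])
    score_missing[spl] <- sm
    fail_class[spl] <- !sm & variants$spliceai_delta[spl] < spliceai_min
  }

  keep <- !(fail_dp | fail_gq | fail_ratio | fail_maf | fail_class | score_missing)
  list(
    variants = variants[keep, , drop = FALSE],
    attrition = c(depth = sum(fail_dp), genotype_quality = sum(fail_gq),
                  allele_ratio = sum(fail_ratio), maf = sum(fail_maf),
                  class_rule = sum(fail_class)),
    n_missing_score = sum(score_missing),
    n_retained = sum(keep)
  )
}

#' Size and likelihood filter for CNV calls
#'
#' Retains CNVs with likelihood score >= `min_score` and size >= `min_size`,
#' and classifies copy number < 2 as deletion and > 2 as duplication.
#' Records with copy number exactly 2 are rejected as non-CNVs.
#'
#' An optional logical `artifact_overlap` column (precomputed overlap with
#' segmental duplications, HLA or centromeric regions — computing it needs
#' external genome tracks) removes flagged calls when present.
#'
#' @param cnvs CNV data.frame (0-based half-open `start`/`end`).
#' @param min_size minimum CNV length in bp. Default 50000.
#' @param min_score minimum likelihood score. Default 30.
#' @return the retained rows with an added `type` column
#'   (`"deletion"`/`"duplication"`).
#' @export
filter_cnvs <- function(cnvs, min_size = 5e4, min_score = 30) {
  stopifnot(all(cnvs$end > cnvs$start))
  if (any(cnvs$copy_number == 2)) stop("copy_number = 2 is not a CNV")
  keep <- (cnvs$end - cnvs$start) >= min_size & cnvs$likelihood_score >= min_score
  if (!is.null(cnvs$artifact_overlap)) keep <- keep & !cnvs$artifact_overlap
  out <- cnvs[keep, , drop = FALSE]
  out$type <- ifelse(out$copy_number < 2, "deletion", "duplication")
  out
}

#' Remove CNVs with batch-heterogeneous parental frequency
#'
#' For each distinct CNV (same interval and type), tests homogeneity of the
#' carrier frequency among parents across genotyping batches with a
#' chi-square test, and removes CNVs whose heterogeneity is significant
#' after Benjamini-Hochberg correction. Guards against array- or
#' batch-related artifacts. Batches without parents are excluded from the
#' test (flagged via warning). A single-batch input is a no-op.
#'
#' @param cnvs filtered CNV data.frame with a `type` column (see
#'   [filter_cnvs()]) and `batch` per record.
#' @param samples data.frame with `individual_id`, `batch`, and logical
#'   `is_parent` covering the cohort (denominator for frequencies).
#' @param fdr significance level on BH-adjusted p-values. Default 0.05.
#' @return list with `cnvs` (retained rows), `removed` (distinct CNV keys
#'   removed), and `tests` (per-key p and q).
#' @export
batch_heterogeneity_filter <- function(cnvs, samples, fdr = 0.05) {
  parents <- samples[samples$is_parent, , drop = FALSE]
  bt <- table(parents$batch)
  if (length(bt) < 2L) {
    if (length(unique(samples$batch)) >= 2L)
      warning("fewer than 2 batches contain parents; filter is a no-op")
    return(list(cnvs = cnvs, removed = character(0), tests = NULL))
  }
  batches <- names(bt)
  cnv_key <- function(d) paste(d$chrom,
                               format(d$start, scientific = FALSE, trim = TRUE),
                               format(d$end, scientific = FALSE, trim = TRUE),
                               d$type, sep = ":")
  key <- cnv_key(cnvs)
  pc <- cnvs[cnvs$individual_id %in% parents$individual_id, , drop = FALSE]
  pkey <- cnv_key(pc)
  pbatch <- parents$batch[match(pc$individual_id, parents$individual_id)]
  keys <- unique(key)
  p <- vapply(keys, function(k) {
    carriers <- tapply(pc$individual_id[pkey == k], factor(pbatch[pkey == k], levels = batches),
                       function(x) length(unique(x)))
    carriers[is.na(carriers)] <- 0
    tab <- rbind(carriers, as.numeric(bt) - carriers)
    if (all(carriers == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, 0)
  q <- stats::p.adjust(p, "BH")
  removed <- keys[!is.na(q) & q < fdr]
  list(cnvs = cnvs[!(key %in% removed), , drop = FALSE], removed = removed,
       tests = data.frame(key = keys, p = p, q = q, row.names = NULL))
}

#' Intersect CNVs with gene intervals
#'
#' Emits one (individual, gene, type) record per gene whose interval overlaps
#' the CNV by at least 1 bp; multigenic CNVs emit several records sharing a
#' CNV id. Both CNVs and genes use 0-based half-open coordinates on the same
#' assembly. CNVs on contigs absent from the gene annotation are skipped and
#' counted.
#'
#' @param cnvs filtered CNV data.frame with `type` (see [filter_cnvs()]).
#' @param genes gene annotation data.frame with `gene`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return data.frame `individual_id`, `gene`, `class`
#'   (deletion/duplication), `cnv_id`; attribute `n_skipped_contig`.
#' @export
annotate_cnv_genes <- function(cnvs, genes) {
  known <- cnvs$chrom %in% genes$chrom
  skipped <- sum(!known)
  if (skipped) warning(skipped, " CNV(s) on contigs absent from gene annotation skipped")
  cn <- cnvs[known, , drop = FALSE]
  if (nrow(cn) == 0L) {
    out <- data.frame(individual_id = character(0), gene = character(0),
                      class = character(0), cnv_id = integer(0))
    attr(out, "n_skipped_contig") <- skipped
    return(out)
  }
  # convert half-open [start, end) to 1-based closed for IRanges
  gr_cnv <- GenomicRanges::GRanges(cn$chrom, IRanges::IRanges(cn$start + 1L, cn$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_cnv, gr_gene, minoverlap = 1L)
  out <- data.frame(
    individual_id = cn$individual_id[S4Vectors::queryHits(hits)],
    gene = genes$gene[S4Vectors::subjectHits(hits)],
    class = cn$type[S4Vectors::queryHits(hits)],
    cnv_id = which(known)[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped_contig") <- skipped
  out
}

#' Collapse variants to binary gene x individual x class disruption calls
#'
#' One record per (individual, gene, class) triple with at least one retained
#' variant of that class in that gene; repeated hits collapse to a single 1.
#' Short-variant classes and CNV-derived deletion/duplication records are
#' combined into a single 7-class universe.
#'
#' @param variants QC-filtered short-variant data.frame (or NULL).
#' @param cnv_genes gene-level CNV records from [annotate_cnv_genes()]
#'   (or NULL).
#' @return data.frame `individual_id`, `gene`, `class` of unique disruption
#'   triples, class `collapsed_genotypes`.
#' @export
collapse_by_gene <- function(variants = NULL, cnv_genes = NULL) {
  pieces <- list()
  if (!is.null(variants) && nrow(variants))
    pieces$sv <- variants[, c("individual_id", "gene", "class")]
  if (!is.null(cnv_genes) && nrow(cnv_genes))
    pieces$cnv <- cnv_genes[, c("individual_id", "gene", "class")]
  if (!length(pieces)) {
    out <- data.frame(individual_id = character(0), gene = character(0),
                      class = character(0))
  } else {
    out <- unique(do.call(rbind, pieces))
    rownames(out) <- NULL
  }
  class(out) <- c("collapsed_genotypes", "data.frame")
  out
}

#' Call de novo variants from trios
#'
#' A variant is de novo when neither parent shows any read evidence for it
#' (both carrier flags FALSE); applied before quality filtering, as parental
#' evidence is informative regardless of QC. Offspring lacking both parents
#' get unknown status and are excluded. Per offspring and gene, only the
#' single de novo variant with the most severe consequence is kept
#' (stop_gained > frameshift > splice > missense > synonymous). Offspring
#' with more than `max_synonymous_genes` genes carrying de novo synonymous
#' variants are removed entirely as likely technical outliers.
#'
#' @param variants short-variant data.frame with `father_carrier` and
#'   `mother_carrier` logical columns (NA when the parent is absent).
#' @param pedigree data.frame with `individual_id`, `father_id`, `mother_id`
#'   (NA for founders).
#' @param max_synonymous_genes outlier threshold. Default 10.
#' @return list with `variants` (input plus a `de_novo` logical column, NA
#'   when unknown), `de_novo` (one-per-gene most-severe de novo records,
#'   outlier offspring removed), `excluded_individuals`, and
#'   `n_unknown` (variants in offspring without a complete trio).
#' @export
call_de_novo <- function(variants, pedigree, max_synonymous_genes = 10) {
  ped <- pedigree[match(variants$individual_id, pedigree$individual_id), ]
  complete_trio <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  dn <- ifelse(complete_trio,
               !variants$father_carrier & !variants$mother_carrier, NA)
  variants$de_novo <- dn

  d <- variants[!is.na(dn) & dn, , drop = FALSE]
  if (nrow(d)) {
    sev <- match(d$class, consequence_severity)
    if (anyNA(sev)) stop("unknown consequence class in de novo records")
    ord <- order(d$individual_id, d$gene, sev)
    d <- d[ord, , drop = FALSE]
    d <- d[!duplicated(d[, c("individual_id", "gene")]), , drop = FALSE]
  }
  syn_genes <- tapply(d$gene[d$class == "synonymous"],
                      d$individual_id[d$class == "synonymous"],
                      function(x) length(unique(x)))
  excluded <- names(syn_genes)[syn_genes > max_synonymous_genes]
  d <- d[!(d$individual_id %in% excluded), , drop = FALSE]
  rownames(d) <- NULL
  list(variants = variants, de_novo = d,
       excluded_individuals = excluded %||% character(0),
       n_unknown = sum(is.na(dn)))
}
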