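# Synthetic family-structured rare-variant cohorts with planted effects.
#
# The generator emulates a family genetic cohort: a mix of trios, quads,
# singletons and all-affected families; per-class per-gene rare variants in
# founders, transmitted to offspring with probability 1/2 plus de novo
# injections; multigenic CNVs on a synthetic gene map; QC fields with
# controlled failure fractions; and disease status drawn from a logistic
# liability on the true (QC-passing) burden of planted gene sets.

#' Configuration for the cohort simulator
#'
#' @param n_families number of families.
#' @param structure_mix named proportions over `trio`, `quad`, `singleton`,
#'   `all_affected` (must sum to 1). All-affected families are trios whose
#'   members are all forced to case status (they exercise the strata filter).
#' @param case_fraction target case fraction among offspring; the liability
#'   intercept is calibrated against it.
#' @param n_genes size of the synthetic gene universe (`g0001`, ...). Genes
#'   are laid on chromosomes (60 kb genes every 100 kb) with LOEUF drawn
#'   uniform on (0, 2).
#' @param per_gene_rate named expected rare-variant count per gene per
#'   founder, one entry per short-variant class.
#' @param de_novo_rate named per-gene de novo rate per offspring; default
#'   one tenth of `per_gene_rate`.
#' @param sets named list of gene sets (subsets of the universe) that
#'   planted effects may reference.
#' @param planted_effects data.frame with columns `set`, `class`, `theta`
#'   (log-odds per burden unit), or NULL for a null cohort.
#' @param cnv_rate expected CNV count per individual.
#' @param cnv_multigene_rate probability a CNV spans more than one gene.
#' @param qc_fail_fractions named fractions of variants failing each QC
#'   field: `DP`, `GQ`, `allele_ratio`, `maf`, `class_score`, `cnv_score`,
#'   `cnv_size`. Failing variants are generated explicitly (not discarded)
#'   so filters have work to do; they never enter the true burden.
#' @param seed integer master seed; one RNG stream per table (pedigree,
#'   variants, CNVs, affection) is derived from it, so sub-results are
#'   stable when one table's settings change.
#' @return validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_families = 500,
                              structure_mix = c(trio = 0.5, quad = 0.3,
                                                singleton = 0.1, all_affected = 0.1),
                              case_fraction = 0.5, n_genes = 200,
                              per_gene_rate = c(stop_gained = 0.002,
                                                frameshift = 0.002,
                                                missense = 0.008,
                                                splice = 0.002,
                                                synonymous = 0.02),
                              de_novo_rate = NULL, sets = list(),
                              planted_effects = NULL, cnv_rate = 0.2,
                              cnv_multigene_rate = 0.3,
                              qc_fail_fractions = c(DP = 0.02, GQ = 0.02,
                                                    allele_ratio = 0.02,
                                                    maf = 0.02, class_score = 0.02,
                                                    cnv_score = 0.02, cnv_size = 0.02),
                              seed = 1) {
  if (abs(sum(structure_mix) - 1) > 1e-8) stop("structure_mix must sum to 1")
  qf <- c(DP = 0, GQ = 0, allele_ratio = 0, maf = 0, class_score = 0,
          cnv_score = 0, cnv_size = 0)
  bad <- setdiff(names(qc_fail_fractions), names(qf))
  if (length(bad)) stop("unknown QC field(s): ", paste(bad, collapse = ", "))
  qf[names(qc_fail_fractions)] <- qc_fail_fractions
  if (any(qf < 0 | qf > 1)) stop("qc_fail_fractions must be probabilities")
  qc_fail_fractions <- qf
  if (any(per_gene_rate < 0) || cnv_rate < 0) stop("rates must be >= 0")
  if (is.null(de_novo_rate)) de_novo_rate <- per_gene_rate * 0.1
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(planted_effects)) {
    stopifnot(all(c("set", "class", "theta") %in% names(planted_effects)))
    if (!all(planted_effects$set %in% names(sets)))
      stop("planted_effects reference unknown gene sets")
    if (any(lengths(sets[planted_effects$set]) == 0))
      stop("planted gene set is empty")
    if (!all(is.finite(planted_effects$theta))) stop("theta must be finite")
    if (!all(unlist(sets) %in% genes)) stop("set genes outside the gene universe")
  }
  structure(list(n_families = as.integer(n_families),
                 structure_mix = structure_mix, case_fraction = case_fraction,
                 n_genes = as.integer(n_genes), genes = genes,
                 per_gene_rate = per_gene_rate, de_novo_rate = de_novo_rate,
                 sets = sets, planted_effects = planted_effects,
                 cnv_rate = cnv_rate, cnv_multigene_rate = cnv_multigene_rate,
                 qc_fail_fractions = qc_fail_fractions, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# synthetic gene map: 60 kb genes every 100 kb, ~n/22 genes per chromosome
.gene_map <- function(genes) {
  n <- length(genes)
  per_chrom <- ceiling(n / 22)
  chrom_idx <- ((seq_len(n) - 1) %/% per_chrom) + 1
  local <- (seq_len(n) - 1) %% per_chrom
  data.frame(gene = genes, chrom = paste0("chr", chrom_idx),
             start = local * 1e5, end = local * 1e5 + 6e4,
             stringsAsFactors = FALSE)
}

#' Simulate a family-structured rare-variant cohort
#'
#' Generates pedigree/phenotype, short-variant, CNV and gene-annotation
#' tables plus a ground-truth record, deterministically given the config
#' seed. Founders draw variants per class at `per_gene_rate`; each founder
#' variant is transmitted to each child with probability 1/2 (the carrier
#' parent is recorded); de novo variants are injected into offspring only,
#' with both parental carrier flags FALSE. Disease status for every
#' individual is drawn from `plogis(alpha + sum_k theta_k * burden_k)`,
#' where burdens count the QC-passing disrupted set genes, with `alpha`
#' calibrated so the offspring case fraction matches the configured target;
#' all-affected families are then forced to case status.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `pedigree` (incl. sex, affected, batch, PC1..PC10,
#'   n_rare_synonymous), `variants`, `cnvs`, `genes` (annotation with
#'   LOEUF), and `truth` (planted effects, liability intercept, per-variant
#'   QC-pass and de novo labels, true burden matrix).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4)

  ## ---- pedigree stream ----
  set.seed(streams[1])
  nf <- config$n_families
  struct <- sample(names(config$structure_mix), nf, replace = TRUE,
                   prob = config$structure_mix)
  n_members <- c(trio = 3L, quad = 4L, singleton = 1L, all_affected = 3L)[struct]
  fam_id <- sprintf("fam%05d", seq_len(nf))
  fam <- rep(fam_id, n_members)
  member <- unlist(lapply(n_members, seq_len), use.names = FALSE)
  role <- rep("child", length(fam))
  role[member == 1 & rep(struct, n_members) != "singleton"] <- "father"
  role[member == 2 & rep(struct, n_members) != "singleton"] <- "mother"
  role[rep(struct, n_members) == "singleton"] <- "self"
  iid <- paste0(fam, "_", sprintf("%02d", member))
  father <- ifelse(role == "child", paste0(fam, "_01"), NA_character_)
  mother <- ifelse(role == "child", paste0(fam, "_02"), NA_character_)
  sex <- ifelse(role == "father", 1L,
                ifelse(role == "mother", 2L, sample(1:2, length(fam), TRUE)))
  pedigree <- data.frame(family_id = fam, individual_id = iid,
                         father_id = father, mother_id = mother, sex = sex,
                         role = role, stringsAsFactors = FALSE)
  pedigree$is_offspring <- role %in% c("child", "self")
  fam_batch <- stats::setNames(sample(c("batchA", "batchB"), nf, TRUE), fam_id)
  pedigree$batch <- fam_batch[pedigree$family_id]
  for (k in 1:10) pedigree[[paste0("PC", k)]] <- stats::rnorm(nrow(pedigree))

  genes_tab <- .gene_map(config$genes)
  genes_tab$loeuf <- round(stats::runif(nrow(genes_tab), 0, 2), 3)

  ## ---- variant stream ----
  set.seed(streams[2])
  qf <- config$qc_fail_fractions
  founders <- pedigree$individual_id[pedigree$role %in% c("father", "mother")]
  singles <- pedigree$individual_id[pedigree$role == "self"]
  children <- pedigree$individual_id[pedigree$role == "child"]
  children_of <- split(children, pedigree$family_id[pedigree$role == "child"])
  n_child_of <- stats::setNames(integer(nf), fam_id)
  n_child_of[names(children_of)] <- lengths(children_of)
  fam_of <- stats::setNames(pedigree$family_id, pedigree$individual_id)
  role_of <- stats::setNames(pedigree$role, pedigree$individual_id)

  draw_own <- function(ids, rate_map, origin) {
    pieces <- lapply(names(rate_map), function(cl) {
      N <- stats::rpois(1, rate_map[[cl]] * length(ids) * config$n_genes)
      if (N == 0) return(NULL)
      data.frame(individual_id = sample(ids, N, TRUE),
                 gene = sample(config$genes, N, TRUE), class = cl,
                 origin = origin, stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  }
  v_founder <- if (length(founders)) draw_own(founders, config$per_gene_rate, "founder")
  v_single <- if (length(singles)) draw_own(singles, config$per_gene_rate, "own")

  v_inherited <- NULL
  if (!is.null(v_founder) && nrow(v_founder)) {
    nk <- n_child_of[fam_of[v_founder$individual_id]]
    idx <- rep(seq_len(nrow(v_founder)), nk)
    if (length(idx)) {
      kids <- unlist(children_of[fam_of[v_founder$individual_id]],
                     use.names = FALSE)
      keep <- stats::runif(length(idx)) < 0.5
      if (any(keep)) {
        src <- v_founder[idx[keep], , drop = FALSE]
        v_inherited <- data.frame(
          individual_id = kids[keep], gene = src$gene, class = src$class,
          origin = "inherited", stringsAsFactors = FALSE)
        v_inherited$father_carrier <- role_of[src$individual_id] == "father"
        v_inherited$mother_carrier <- role_of[src$individual_id] == "mother"
      }
    }
  }
  v_denovo <- if (length(children)) draw_own(children, config$de_novo_rate, "de_novo")
  for (nm in c("v_founder", "v_single", "v_denovo")) {
    v <- get(nm)
    if (!is.null(v) && nrow(v)) {
      v$father_carrier <- if (nm == "v_denovo") FALSE else NA
      v$mother_carrier <- if (nm == "v_denovo") FALSE else NA
      assign(nm, v)
    }
  }
  variants <- do.call(rbind, Filter(Negate(is.null),
                                    list(v_founder, v_single, v_inherited, v_denovo)))
  if (is.null(variants))
    variants <- data.frame(individual_id = character(0), gene = character(0),
                           class = character(0), origin = character(0),
                           father_carrier = logical(0), mother_carrier = logical(0))
  nv <- nrow(variants)
  variants$variant_id <- if (nv) sprintf("var%06d", seq_len(nv)) else character(0)

  fail <- function(field, n) stats::runif(n) < qf[[field]]
  f_dp <- fail("DP", nv); f_gq <- fail("GQ", nv)
  f_ar <- fail("allele_ratio", nv); f_maf <- fail("maf", nv)
  f_cs <- fail("class_score", nv)
  variants$DP <- ifelse(f_dp, sample(5:19, nv, TRUE), sample(20:60, nv, TRUE))
  variants$GQ <- ifelse(f_gq, sample(5:29, nv, TRUE), sample(30:99, nv, TRUE))
  variants$allele_ratio <- ifelse(f_ar,
                                  ifelse(stats::runif(nv) < 0.5,
                                         stats::runif(nv, 0, 0.19),
                                         stats::runif(nv, 0.81, 1)),
                                  stats::runif(nv, 0.25, 0.75))
  variants$maf_cohort <- ifelse(f_maf, stats::runif(nv, 2e-3, 1e-2),
                                stats::runif(nv, 0, 1e-3))
  variants$maf_reference <- stats::runif(nv, 0, 1e-3)
  lofc <- variants$class %in% c("stop_gained", "frameshift")
  variants$loftee_hc <- ifelse(lofc, !f_cs, NA)
  variants$alphamissense <- ifelse(variants$class == "missense",
                                   ifelse(f_cs, stats::runif(nv, 0, 0.89),
                                          stats::runif(nv, 0.9, 1)), NA)
  variants$spliceai_delta <- ifelse(variants$class == "splice",
                                    ifelse(f_cs, stats::runif(nv, 0, 0.79),
                                           stats::runif(nv, 0.8, 1)), NA)
  qc_pass <- !(f_dp | f_gq | f_ar | f_maf |
                 (f_cs & variants$class != "synonymous"))

  ## ---- CNV stream ----
  set.seed(streams[3])
  n_ind <- nrow(pedigree)
  n_cnv <- stats::rpois(1, config$cnv_rate * n_ind)
  cnvs <- NULL; cnv_pass <- logical(0); cnv_gene_span <- list()
  if (n_cnv > 0) {
    ind <- sample(pedigree$individual_id, n_cnv, TRUE)
    g1 <- sample(config$n_genes, n_cnv, TRUE)
    span <- ifelse(stats::runif(n_cnv) < config$cnv_multigene_rate,
                   sample(2:4, n_cnv, TRUE), 1L)
    # clamp spans to the start gene's chromosome
    chrom1 <- genes_tab$chrom[g1]
    g2 <- pmin(g1 + span - 1L, config$n_genes)
    same <- genes_tab$chrom[g2] == chrom1
    while (any(!same)) {
      g2[!same] <- g2[!same] - 1L
      same <- genes_tab$chrom[g2] == chrom1
    }
    f_sc <- fail("cnv_score", n_cnv); f_sz <- fail("cnv_size", n_cnv)
    start <- pmax(genes_tab$start[g1] - 1000, 0)
    end <- genes_tab$end[g2] + 1000
    end[f_sz] <- start[f_sz] + 2e4 # undersized call, still touching its gene
    g2[f_sz] <- g1[f_sz]
    cnvs <- data.frame(
      individual_id = ind, chrom = chrom1, start = start, end = end,
      copy_number = sample(c(0L, 1L, 3L, 4L), n_cnv, TRUE,
                           prob = c(0.05, 0.45, 0.4, 0.1)),
      likelihood_score = ifelse(f_sc, stats::runif(n_cnv, 5, 29.9),
                                stats::runif(n_cnv, 30, 200)),
      batch = fam_batch[fam_of[ind]],
      cnv_id = sprintf("cnv%05d", seq_len(n_cnv)), stringsAsFactors = FALSE)
    cnv_pass <- !(f_sc | f_sz)
    cnv_gene_span <- Map(function(a, b) config$genes[a:b], g1, g2)
  }

  ## ---- affection stream ----
  set.seed(streams[4])
  ids <- pedigree$individual_id
  true_burden <- NULL
  lp <- numeric(length(ids))
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    true_burden <- matrix(0L, length(ids), nrow(pe),
                          dimnames = list(ids, paste(pe$set, pe$class, sep = ":")))
    for (k in seq_len(nrow(pe))) {
      set_genes <- config$sets[[pe$set[k]]]
      cl <- pe$class[k]
      if (cl %in% c("deletion", "duplication")) {
        if (!is.null(cnvs)) {
          type <- ifelse(cnvs$copy_number < 2, "deletion", "duplication")
          sel <- which(cnv_pass & type == cl)
          if (length(sel)) {
            recs <- data.frame(
              individual_id = rep(cnvs$individual_id[sel],
                                  lengths(cnv_gene_span[sel])),
              gene = unlist(cnv_gene_span[sel], use.names = FALSE),
              stringsAsFactors = FALSE)
            recs <- unique(recs[recs$gene %in% set_genes, ])
            tb <- table(factor(recs$individual_id, levels = ids))
            true_burden[, k] <- as.integer(tb)
          }
        }
      } else {
        sel <- qc_pass & variants$class == cl & variants$gene %in% set_genes
        recs <- unique(variants[sel, c("individual_id", "gene")])
        tb <- table(factor(recs$individual_id, levels = ids))
        true_burden[, k] <- as.integer(tb)
      }
      lp <- lp + pe$theta[k] * true_burden[, k]
    }
  }
  off <- pedigree$is_offspring
  target <- config$case_fraction
  if (all(lp[off] == lp[off][1])) {
    alpha <- stats::qlogis(target) - lp[off][1]
  } else {
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp[off])) - target,
                            c(-30, 30))$root
  }
  pedigree$affected <- stats::rbinom(length(ids), 1, stats::plogis(alpha + lp))
  aa_fam <- fam_id[struct == "all_affected"]
  pedigree$affected[pedigree$family_id %in% aa_fam] <- 1L

  syn <- variants$individual_id[qc_pass & variants$class == "synonymous"]
  pedigree$n_rare_synonymous <- as.integer(table(factor(syn, levels = ids)))

  truth <- list(planted_effects = pe, alpha = alpha, true_burden = true_burden,
                qc_pass = stats::setNames(qc_pass, variants$variant_id),
                cnv_pass = if (!is.null(cnvs)) stats::setNames(cnv_pass, cnvs$cnv_id),
                de_novo_ids = variants$variant_id[variants$origin == "de_novo"],
                all_affected_families = aa_fam)
  rownames(variants) <- NULL
  list(pedigree = pedigree, variants = variants, cnvs = cnvs,
       genes = genes_tab, truth = truth, config = config)
}
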