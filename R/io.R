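# Readers and writers for the standard interchange formats: Matrix Market
# expression matrices with cell/gene annotation tables, GMT gene sets,
# PED-like pedigrees, and tab-delimited variant/CNV/result tables.

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (e.g. from [assign_top_n()]).
#' @param path output file.
#' @param descriptions optional per-set description strings; defaults to the
#'   collection metadata (method/size) or `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    meta <- sprintf("method=%s;n=%s", attr(sets, "method") %||% "external",
                    attr(sets, "n") %||% "NA")
    descriptions <- rep(meta, length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated expression matrix to disk
#'
#' Matrix Market sparse counts plus tab-delimited cell and gene annotation
#' tables, the layout consumed by [read_expression()].
#'
#' @param sim a [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @export
write_expression <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "counts.mtx"))
  utils::write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression matrix written by [write_expression()]
#' @param dir directory containing `counts.mtx`, `cells.tsv`, `genes.tsv`.
#' @return list with `counts` (genes x cells, dimnames attached), `cells`,
#'   `genes`.
#' @export
read_expression <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene, cells$cell_id)
  list(counts = counts, cells = cells, genes = genes)
}

#' Write a simulated cohort to disk
#'
#' PED-like pedigree (family, individual, father, mother, sex, phenotype,
#' followed by covariate columns), tab-delimited variant/CNV/gene tables,
#' and the ground truth as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$pedigree, file.path(dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$variants, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$cnvs))
    utils::write.table(cohort$cnvs, file.path(dir, "cnvs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_burden <- NULL # matrix ground truth stays in-session
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}

#' Write a per-filter attrition report as JSON
#' @param qc a [qc_filter_short_variants()] result.
#' @param path output JSON file.
#' @export
write_attrition_report <- function(qc, path) {
  jsonlite::write_json(list(attrition = as.list(qc$attrition),
                            n_missing_score = qc$n_missing_score,
                            n_retained = qc$n_retained),
                       path, auto_unbox = TRUE)
  invisible(path)
}
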