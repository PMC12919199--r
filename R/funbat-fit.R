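# The FunBAT model: family-stratified conditional logistic regression of
# case status on a gene-set functional burden.
#
# The likelihood conditions each family (stratum) on its number of cases,
# which eliminates family-level confounding and relatedness; covariates
# constant within a stratum contribute nothing but are accepted for fidelity
# to the full model formula (burden + sex + PC1..10 + number of rare
# synonymous variants).

#' Gene-set functional burden per individual
#'
#' The burden is the number of distinct genes of the set carrying a collapsed
#' disruption call of the given class for the individual: the sum of the
#' binary per-gene flags, bounded by the set size. Individuals without any
#' disruption (or absent from the collapsed table) score 0.
#'
#' @param collapsed a [collapse_by_gene()] result (triples
#'   individual/gene/class).
#' @param genes character vector, the gene set (nonempty).
#' @param class variant class to count.
#' @param individuals character vector of cohort individual ids (the burden
#'   vector is defined over these, in order).
#' @return named integer vector of burdens.
#' @export
compute_burden <- function(collapsed, genes, class, individuals) {
  if (length(genes) == 0L) stop("empty gene set")
  hit <- collapsed$class == class & collapsed$gene %in% genes
  sub <- unique(collapsed[hit, c("individual_id", "gene")])
  counts <- table(factor(sub$individual_id, levels = individuals))
  stats::setNames(as.integer(counts), individuals)
}

#' Restrict a cohort to informative family strata
#'
#' Conditional logistic regression only learns from families with outcome
#' diversity: strata are retained when they have at least 2 members and both
#' affected and unaffected members. Singletons and all-affected (or
#' all-unaffected) families are dropped and counted.
#'
#' @param phenotype data.frame with `individual_id`, `family_id`, and binary
#'   `affected`.
#' @return the informative rows, with attributes `n_dropped_strata` and
#'   `n_dropped_individuals`.
#' @export
filter_strata <- function(phenotype) {
  stopifnot(all(c("individual_id", "family_id", "affected") %in% names(phenotype)))
  f <- phenotype$family_id
  n <- tapply(phenotype$affected, f, length)
  div <- tapply(phenotype$affected, f, function(a) any(a == 1) && any(a == 0))
  ok_fams <- names(n)[n >= 2 & div]
  keep <- f %in% ok_fams
  out <- phenotype[keep, , drop = FALSE]
  attr(out, "n_dropped_strata") <- length(n) - length(ok_fams)
  attr(out, "n_dropped_individuals") <- sum(!keep)
  out
}

#' Fit the FunBAT conditional logistic burden model
#'
#' Maximizes the exact stratified conditional likelihood (each family
#' conditioned on its number of cases) of
#' `affected ~ beta1 * burden + covariates`, via [survival::clogit()] with
#' the exact method. For copy-number classes, two genome-background burdens
#' (disrupted genes under and not under genetic constraint, outside the
#' studied set) can be supplied to absorb the cumulative effect of
#' multigenic CNVs; `beta1` remains the coefficient of interest.
#'
#' Non-informative strata are removed first (see [filter_strata()]); their
#' presence or absence does not change the likelihood. If the burden does
#' not vary within any retained stratum the coefficient is inestimable and
#' returned as NA with a flag; likelihood divergence (separation) is flagged
#' rather than capped.
#'
#' @param burden numeric vector named by individual id (see
#'   [compute_burden()]), or a number per row of `phenotype`.
#' @param phenotype cohort data.frame with `individual_id`, `family_id`,
#'   binary `affected`, and any covariate columns.
#' @param covariates character vector of covariate column names in
#'   `phenotype` (e.g. `c("sex", paste0("PC", 1:10), "n_rare_synonymous")`).
#'   Default none.
#' @param background optional data.frame/list with numeric elements
#'   `constrained` and `unconstrained`, named by individual id: the
#'   two-burden CNV background.
#' @return object of class `funbat`: estimate `beta` (log-OR per burden
#'   unit), `or`, `se`, `p` (Wald), stratum counts, convergence flags, the
#'   full coefficient vector, and the underlying survival fit.
#' @seealso [run_funbat()] for scanning a gene-set collection.
#' @export
funbat <- function(burden, phenotype, covariates = NULL, background = NULL) {
  stopifnot(all(c("individual_id", "family_id", "affected") %in% names(phenotype)))
  if (!all(phenotype$affected %in% c(0, 1))) stop("affected must be binary 0/1")
  if (!is.null(names(burden))) {
    burden <- burden[phenotype$individual_id]
  } else if (length(burden) != nrow(phenotype)) {
    stop("burden must be named by individual id or match phenotype rows")
  }
  ph <- phenotype
  ph$.burden <- as.numeric(burden)
  if (!is.null(background)) {
    ph$.bg_constrained <- as.numeric(background$constrained[ph$individual_id])
    ph$.bg_unconstrained <- as.numeric(background$unconstrained[ph$individual_id])
  }
  ph <- filter_strata(ph)
  n_dropped <- attr(ph, "n_dropped_strata")
  n_strata <- length(unique(ph$family_id))
  if (n_strata < 1L) stop("no informative strata")

  out <- list(beta = NA_real_, or = NA_real_, se = NA_real_, z = NA_real_,
              p = NA_real_, n_strata = n_strata, n_dropped_strata = n_dropped,
              n_individuals = nrow(ph), coefficients = NULL, vcov = NULL,
              converged = FALSE, diverged = FALSE, inestimable = FALSE,
              fit = NULL, call = match.call())
  class(out) <- "funbat"

  varies <- any(tapply(ph$.burden, ph$family_id, function(b) length(unique(b)) > 1))
  if (!varies) {
    out$inestimable <- TRUE
    return(out)
  }

  terms <- c(".burden",
             if (!is.null(background)) c(".bg_constrained", ".bg_unconstrained"),
             covariates, "survival::strata(family_id)")
  fml <- stats::reformulate(terms, response = "affected")
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::clogit(fml, data = ph, method = "exact"),
    warning = function(w) {
      if (grepl("converged|infinite|singular|beta may be infinite", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  out$fit <- fit
  out$coefficients <- cf
  out$vcov <- stats::vcov(fit)
  out$converged <- TRUE
  b <- cf[".burden"]
  if (is.na(b)) {
    out$inestimable <- TRUE
    return(out)
  }
  se <- sqrt(diag(out$vcov))[".burden"]
  out$beta <- unname(b)
  out$or <- exp(out$beta)
  out$se <- unname(se)
  out$z <- out$beta / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$diverged <- diverged || abs(out$beta) > 10 || out$se > 100
  out
}

#' @export
print.funbat <- function(x, digits = 4, ...) {
  cat("FunBAT conditional logistic burden fit\n")
  cat(sprintf("  informative strata: %d (dropped: %d), individuals: %d\n",
              x$n_strata, x$n_dropped_strata, x$n_individuals))
  if (x$inestimable) {
    cat("  burden shows no within-stratum variation: beta inestimable (NA)\n")
  } else {
    cat(sprintf("  beta1 = %.*f (OR %.*f), SE %.*f, Wald p = %.3g%s\n",
                digits, x$beta, digits, x$or, digits, x$se, x$p,
                if (x$diverged) "  [diverged]" else ""))
  }
  invisible(x)
}

#' @export
summary.funbat <- function(object, ...) {
  print(object)
  if (!is.null(object$coefficients)) {
    se <- sqrt(diag(object$vcov))
    tab <- cbind(coef = object$coefficients, `exp(coef)` = exp(object$coefficients),
                 se = se, z = object$coefficients / se,
                 p = 2 * stats::pnorm(-abs(object$coefficients / se)))
    cat("\nCoefficients:\n")
    stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
    invisible(tab)
  } else invisible(NULL)
}

#' @export
coef.funbat <- function(object, ...) object$coefficients

#' @export
vcov.funbat <- function(object, ...) object$vcov

#' @export
nobs.funbat <- function(object, ...) object$n_individuals

#' @export
confint.funbat <- function(object, parm = ".burden", level = 0.95, ...) {
  if (is.null(object$coefficients)) return(NULL)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(object$vcov))[parm]
  est <- object$coefficients[parm]
  out <- cbind(est - z * se, est + z * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
residuals.funbat <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::residuals(object$fit, ...)
}
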