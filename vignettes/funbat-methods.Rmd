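---
title: "Cell-type functional burden association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type functional burden association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funbat)
```

## The problem

Rare gene-disrupting variants contribute substantially to neurodevelopmental
conditions, but single-gene association tests are underpowered for all but
the largest effects. A complementary strategy aggregates variants over a
*functional* gene set — for example, the genes most specifically expressed
in one cortical cell type at one developmental epoch — and asks whether
carrying more disrupted genes from that set shifts disease risk. The burden
estimate then reads as the *liability* of that cell type. This package
implements that workflow end to end: building the cell-type gene sets from
a single-cell expression matrix, collapsing quality-filtered variants into
binary per-gene disruption calls, and fitting the family-stratified burden
model, together with the post-hoc analyses that interpret the scan.

## Expression specificity and gene-set construction

Cells are grouped into clusters formed by the Cartesian product of cell
type and developmental epoch; clusters under 50 cells (default) are
excluded because per-gene detection fractions become unstable. For every
gene and cluster we compute, on raw counts:

* **sensitivity** — the fraction of in-cluster cells with read count ≥ 1;
* **specificity** — the fraction of out-of-cluster cells with count 0;
* **AUC** — the area under the ROC curve obtained by sweeping the count
  threshold over all observed values (trapezoidal rule). This equals the
  Mann–Whitney probability that a random in-cluster cell out-expresses a
  random out-of-cluster cell, with ties given half credit; a constant gene
  scores exactly 0.5, a perfectly exclusive-and-ubiquitous marker 1.

Genes whose best-cluster detection (`sensitivity_max`) is below 10% are
dropped before set construction: at typical nuclear capture rates such
genes are mostly unexpressed in the tissue, and their scores are noise.

Four specificity scores are available on the log-CPM layer
(`log(1 + 1e6 * count / cell_total)`, natural log — the transform base is a
free choice and only rescales scores):

* **z-score** (default for set construction): per-cluster mean expression
  standardized by the mean and *population* SD over that gene's cluster
  means. The population-vs-sample convention only rescales scores
  uniformly, and only ranks feed the set construction, so nothing
  downstream depends on it. Constant genes (σ = 0) score 0 and are flagged.
* **Wilcoxon**: tie-corrected rank-sum z of in- versus out-of-cluster
  per-cell expression.
* **EP**, expression proportion: the gene's share of its summed per-cluster
  means; rows sum to 1.
* **EE**, expression enrichment: EP divided by the cluster's share of total
  expression, so 1 everywhere means "no enrichment". The defining identity
  `sum_i share_i * EE_i = 1` is enforced to 1e-12 in the tests. (The
  alternative reading of the formula — a per-cluster constant times this
  quantity — would not change any ranking, which is all the set
  construction consumes.)

Sets are the top *N* genes per cluster (default 600, roughly the top 5% of
an expressed-gene universe of ~12,000); rank ties break by score
descending then gene id ascending, for reproducibility. When a LOEUF table
is supplied, genes not under genetic constraint (LOEUF ≥ 0.6) are removed
*after* the top-N selection, mirroring the observation that burden signal
concentrates in constrained genes; sets therefore shrink below N. Missing
LOEUF is treated as unconstrained (and flagged) — the conservative choice
for a filter whose purpose is to keep only demonstrably constrained genes.

Set quality is validated by projecting all cells on the first principal
component of a window of ranked genes (log-CPM, gene-centered, unscaled;
component sign chosen so AUC ≥ 0.5) and computing the AUC of that
projection for in- versus out-of-cluster membership, typically over 15
windows of 100 genes.

## The burden model

For each individual, gene and variant class, all retained variants
collapse to one binary flag ("is this gene disrupted by this class"); the
burden of a gene set is the sum of those flags over the set. Disease
status is modelled by conditional logistic regression with the family as
the stratum:

```
affected ~ beta1 * burden + sex + PC1..PC10 + n_rare_synonymous + strata(family)
```

Conditioning each family on its number of cases removes all family-level
confounding (shared environment, ancestry, relatedness) without modelling
it; `beta1` is the log-odds ratio per disrupted set gene. Strata without
outcome diversity (singletons; all-affected families) contribute nothing
to that likelihood and are removed and counted — the fit is provably
identical with or without them (tested to 1e-10). Covariates constant
within a stratum likewise drop out but are accepted in the formula.
The likelihood is maximized exactly (`survival::clogit`, exact method);
the test suite checks the estimates against an independent brute-force
enumeration of the conditional likelihood and against the matched-pair
closed form `log(n10/n01)`.

Deletions and duplications are often multigenic, so their set burden is
confounded by the other genes a CNV removes. The CNV model therefore adds
two genome-background burdens — disrupted genes outside the studied set,
split at LOEUF 1 into constrained and unconstrained — as nuisance terms
(`beta2`, `beta3`). The two LOEUF cutoffs (0.6 for set membership, 1 for
the background split) are deliberately distinct and both exposed.

Numerical policy: convergence failures and separation (|beta| > 10 or
SE > 100, or an explicit optimizer warning) are *flagged*, never silently
capped; burdens without within-stratum variation return NA with an
`inestimable` flag. Scans over sets × classes apply Benjamini–Hochberg FDR
over all cells by default (configurable to per-class families), keeping NA
rows for bookkeeping.

## Variant and CNV quality control

Short variants pass when all of the following hold: DP ≥ 20, GQ ≥ 30,
alternate-allele ratio in [0.2, 0.8] (rare variants should be
heterozygous), cohort and reference MAF ≤ 1/1000, plus the class rule —
LoFtee high-confidence for stop-gained/frameshift, AlphaMissense ≥ 0.9 for
missense, SpliceAI delta ≥ 0.8 for splice; synonymous variants carry no
extra rule. All predicates are conjunctive, so filter order is irrelevant;
attrition is reported per filter. MAF is interpreted as allele frequency
(the gnomAD convention). CNVs pass at likelihood score ≥ 30 and size ≥
50 kb; copy number below 2 is a deletion, above 2 a duplication. Parental
carrier frequencies are compared across genotyping batches by chi-square
test and batch-heterogeneous CNVs removed at BH FDR 0.05. CNV–gene
intersection uses 0-based half-open intervals and counts any ≥ 1 bp
overlap as disruption (no minimum coverage is imposed; the threshold is a
documented, configurable choice).

De novo status is called *before* quality filtering — a parent's read
evidence is informative regardless of QC — as "no evidence in either
parent". Per offspring and gene only the most severe de novo consequence
is kept (stop_gained > frameshift > splice > missense > synonymous, the
standard effect-severity ranking), and offspring with more than 10 genes
carrying de novo synonymous calls are removed as technical outliers.

## Post-hoc analyses

* **Prioritization**: 1,000 random 100-gene subsets of a significant set
  are refit; subsets significant at BH FDR < 0.05 (one family over
  subsets) define the "significant" margin of a per-gene 2×2 Fisher table
  (significant × contains-gene), with a second BH family over genes. The
  two FDR families are deliberately separate. The per-gene table
  conditions on the realized subset memberships.
* **Enrichment**: two-sided Fisher exact tests over a declared gene
  universe; the reported OR is the sample OR with a Haldane 0.5 correction
  on zero cells (flagged).
* **Effect-size normalization**: random gene sets over a size grid (50 to
  950 by 50, 30 per size) give a per-size null mean and SD;
  `z = (estimate − mean)/SD` at the closest size (ties to smaller).
* **Subgroup bias**: cases are split by a label (sex, diagnosis age); the
  statistic is the difference of the two subgroup log-ORs (log-OR rather
  than OR, for symmetry), with controls shared; the null re-splits cases
  5,000 times preserving the subgroup proportion. Significance follows
  the 5%/95% percentile band, with a symmetric rank-based two-tail p
  reported alongside and BH-corrected.
* **Stability**: families are subsampled at 10%–90% (20 replicates each)
  and downsampled estimates correlated (Spearman) against the full-cohort
  scan.

## The synthetic-data generator

Because the real inputs of such studies (large family WES cohorts, a
developmental single-nucleus atlas) are access-restricted, validation runs
on synthetic data with planted ground truth.

The expression generator plants `markers_per_cluster` genes per cell-type
× epoch cluster whose negative-binomial mean is `marker_fold` × elevated in
their home cluster (defaults: baseline mean 0.3 counts, dispersion 0.5,
fold 8 — a sparse nuclear-capture regime with unambiguous markers), plus
optional uniform dropout. It does not emulate donor effects, library-size
gradients, ambient RNA or doublets, so passing marker-recovery tests shows
the scoring machinery is correct, not that it is robust to those artifacts.

The cohort generator mixes trios, quads, singletons and all-affected
families (defaults 50/30/10/10%). Founders draw per-class per-gene variant
counts (Poisson); each founder variant transmits to each child with
probability 1/2 with the carrier parent recorded; de novo variants enter
offspring only, at one tenth of the founder rate, with both parental
carrier flags false. Parental genotypes are drawn independently (no
assortment). QC-failing variants are generated explicitly at configurable
fractions so the filters have work to do; they never enter the true
burden. CNVs fall on a synthetic gene map (60 kb genes every 100 kb) and
span 2–4 genes with probability `cnv_multigene_rate`.

Disease status is drawn from `plogis(alpha + sum_k theta_k * burden_k)`
for **every** family member, with `alpha` calibrated so the offspring case
fraction hits its target (default 0.5, a case/sibling design). Drawing
parents from the same liability model — rather than forcing them to
control status — is what makes conditional-logistic recovery well-posed:
the conditional likelihood is exactly correct when all members' outcomes
are independent logistic draws given their burdens with a shared stratum
intercept. The cost is an unrealistically high parental case rate; since
affected parents only shift which strata are informative, not the
estimand, this is the right trade for a validation generator.
All randomness flows through one stream per table (pedigree, variants,
CNVs, affection), each seeded from the master seed, so one table's
configuration can change without perturbing the others.

## Validation scales

The test suite and the acceptance script validate at sizes chosen to give
tight Monte-Carlo error at interactive runtimes: oracle agreement on 50
three-family instances (tolerance 1e-4); type-I error over 1,000 null
cohorts of 500 families (nominal 0.05, binomial band [0.036, 0.064]);
recovery of a planted log-OR of 0.5 over 200 cohorts of 2,000 families
(within 2 Monte-Carlo SEs); a 1,000-gene, 1,200-cell matrix for marker
recovery (≥ 95% into their home sets, top-100 window AUC ≥ 0.9); driver
prioritization with 1,000 × 100-gene subsets on a 1,500-family cohort
where 10 of 300 genes carry a per-gene log-OR of 3 (a large,
syndromic-like effect concentrated in few genes — the architecture the
subsampling design is meant to detect); and 500 cohorts of 300 families
for the synonymous negative control (Kolmogorov–Smirnov uniformity).
The burden simulations use a 60-gene set with a founder missense rate of
0.015 per gene (about one disrupted set gene per individual), scaling a
600-gene set's carrier load down to a desk-size gene universe of 200–400
genes.

## Known limitations

* The conditional likelihood handles relatedness only *between* strata
  members via stratification; cryptic relatedness across families is not
  modelled (no kinship matrix).
* Wald p-values are asymptotic; with very sparse burdens or few
  informative strata they can drift from nominal, which is why the
  calibration test runs at realistic burden loads.
* The generator plants neither linkage disequilibrium nor site-frequency
  structure, and population structure is only present as independent PC
  covariate columns.
* X-chromosome models, variance-component (kernel) tests and upstream
  callers/annotators are out of scope; their outputs are consumed as
  input columns.
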