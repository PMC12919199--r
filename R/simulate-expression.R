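# Synthetic single-cell expression matrices with planted cell-type markers.
#
# The generator emulates the structure of a developmental cortex snRNA-seq
# atlas: cells annotated by cell type and developmental epoch, clusters of
# roughly equal size across the cell-type x epoch grid, negative-binomial
# counts with dropout, and a known set of marker genes whose mean expression
# is fold-elevated in exactly one home cluster.

#' Configuration for the expression simulator
#'
#' @param n_celltypes,n_epochs grid of annotation labels; clusters are their
#'   combinations.
#' @param cells_per_cluster cells per cell-type x epoch cluster.
#' @param n_genes total genes; must accommodate all planted markers.
#' @param markers_per_cluster planted marker genes per cluster.
#' @param marker_fold fold-elevation of a marker's negative-binomial mean in
#'   its home cluster (1 = no signal). Default 8.
#' @param baseline_mean mean count of non-marker expression. Default 0.3,
#'   a typical sparse nuclear capture rate.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2). Default 0.5.
#' @param dropout probability an observed count is zeroed (extra technical
#'   dropout on top of sampling zeros). Default 0.
#' @param n_donors donors assigned cyclically to cells. Default 4.
#' @param seed integer master seed.
#' @return validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_celltypes = 3, n_epochs = 2,
                                  cells_per_cluster = 200, n_genes = 1000,
                                  markers_per_cluster = 20, marker_fold = 8,
                                  baseline_mean = 0.3, dispersion = 0.5,
                                  dropout = 0, n_donors = 4, seed = 1) {
  cfg <- list(n_celltypes = as.integer(n_celltypes), n_epochs = as.integer(n_epochs),
              cells_per_cluster = as.integer(cells_per_cluster),
              n_genes = as.integer(n_genes),
              markers_per_cluster = as.integer(markers_per_cluster),
              marker_fold = marker_fold, baseline_mean = baseline_mean,
              dispersion = dispersion, dropout = dropout,
              n_donors = as.integer(n_donors), seed = as.integer(seed))
  n_clusters <- cfg$n_celltypes * cfg$n_epochs
  if (cfg$markers_per_cluster * n_clusters > cfg$n_genes)
    stop("infeasible config: more planted markers (",
         cfg$markers_per_cluster * n_clusters, ") than genes (", cfg$n_genes, ")")
  if (cfg$marker_fold <= 0 || cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
    stop("marker_fold, baseline_mean and dispersion must be positive")
  if (cfg$dropout < 0 || cfg$dropout > 1) stop("dropout must be in [0, 1]")
  class(cfg) <- "expression_sim_config"
  cfg
}

#' Simulate a cell x gene count matrix with planted markers
#'
#' Counts are negative-binomial with per-gene mean `baseline_mean`, except
#' that each marker gene's mean is multiplied by `marker_fold` in its home
#' cluster. An optional dropout step zeroes each count independently.
#' Deterministic given the config seed.
#'
#' @param config an [expression_sim_config()].
#' @return list with `counts` (sparse gene x cell [Matrix::dgCMatrix]),
#'   `cells` (data.frame `cell_id`, `cell_type`, `epoch`, `donor`), `genes`
#'   (data.frame `gene`), and `truth` (marker assignment: gene, cell_type,
#'   epoch, cluster).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  ct <- sprintf("ct%02d", seq_len(config$n_celltypes))
  ep <- sprintf("ep%d", seq_len(config$n_epochs))
  grid <- expand.grid(cell_type = ct, epoch = ep, stringsAsFactors = FALSE)
  n_clusters <- nrow(grid)
  n_cells <- n_clusters * config$cells_per_cluster
  cells <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(n_cells)),
    cell_type = rep(grid$cell_type, each = config$cells_per_cluster),
    epoch = rep(grid$epoch, each = config$cells_per_cluster),
    donor = sprintf("donor%d", rep_len(seq_len(config$n_donors), n_cells)),
    stringsAsFactors = FALSE)
  genes <- sprintf("gene%05d", seq_len(config$n_genes))

  # markers occupy the first markers_per_cluster * n_clusters gene slots
  truth <- data.frame(
    gene = genes[seq_len(config$markers_per_cluster * n_clusters)],
    cell_type = rep(grid$cell_type, each = config$markers_per_cluster),
    epoch = rep(grid$epoch, each = config$markers_per_cluster),
    stringsAsFactors = FALSE)
  truth$cluster <- paste(truth$cell_type, truth$epoch, sep = "|")

  mu <- matrix(config$baseline_mean, config$n_genes, n_clusters)
  home <- match(truth$cluster, paste(grid$cell_type, grid$epoch, sep = "|"))
  mu[cbind(seq_len(nrow(truth)), home)] <- config$baseline_mean * config$marker_fold

  cell_cluster <- rep(seq_len(n_clusters), each = config$cells_per_cluster)
  counts <- matrix(0L, config$n_genes, n_cells)
  size <- 1 / config$dispersion
  for (k in seq_len(n_clusters)) {
    idx <- which(cell_cluster == k)
    counts[, idx] <- stats::rnbinom(config$n_genes * length(idx), size = size,
                                    mu = mu[, k])
  }
  if (config$dropout > 0)
    counts[stats::runif(length(counts)) < config$dropout] <- 0L
  dimnames(counts) <- list(genes, cells$cell_id)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       cells = cells, genes = data.frame(gene = genes, stringsAsFactors = FALSE),
       truth = truth, config = config)
}
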