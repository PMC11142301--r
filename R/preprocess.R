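#' Per-cell quality-control metrics
#'
#' UMIs, detected genes, mitochondrial fraction, and library complexity
#' `log10(n_genes) / log10(n_umi)`. Complexity is undefined (NA) for cells
#' with fewer than 2 UMIs or no detected gene; such cells always fail the
#' downstream filter.
#'
#' @param data an [sc_dataset()] with mitochondrial gene flags
#' @return data.frame: barcode, n_umi, n_genes, pct_mito, complexity
#' @export
compute_cell_qc <- function(data) {
  cts <- data$counts
  n_umi <- Matrix::rowSums(cts)
  n_genes <- Matrix::rowSums(cts > 0)
  mito <- Matrix::rowSums(cts[, data$genes$mito, drop = FALSE])
  pct_mito <- ifelse(n_umi > 0, mito / n_umi, NA_real_)
  complexity <- ifelse(n_umi >= 2 & n_genes >= 1,
                       log10(n_genes) / log10(n_umi), NA_real_)
  data.frame(barcode = data$cells$barcode, n_umi = as.integer(n_umi),
             n_genes = as.integer(n_genes), pct_mito = pct_mito,
             complexity = complexity)
}

#' QC thresholds
#'
#' Boundary semantics follow the exclusion wording ("more than 15%
#' mitochondrial reads", "fewer than 300 transcripts", "fewer than 500
#' genes", "complexity less than 70%"): a cell exactly at a threshold is
#' kept.
#'
#' @param max_pct_mito,min_umi,min_genes,min_complexity cell-level cutoffs
#' @param min_cells_per_gene gene-level cutoff for [filter_genes()]
#' @export
qc_thresholds <- function(max_pct_mito = 0.15, min_umi = 300,
                          min_genes = 500, min_complexity = 0.70,
                          min_cells_per_gene = 10) {
  stopifnot(max_pct_mito > 0, min_umi > 0, min_genes > 0,
            min_complexity > 0, min_cells_per_gene > 0)
  list(max_pct_mito = max_pct_mito, min_umi = min_umi,
       min_genes = min_genes, min_complexity = min_complexity,
       min_cells_per_gene = min_cells_per_gene)
}

#' Cell filter
#'
#' @param qc output of [compute_cell_qc()]
#' @param thresholds a [qc_thresholds()] list
#' @return logical keep mask over cells
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  keep <- !is.na(qc$pct_mito) & qc$pct_mito <= thresholds$max_pct_mito &
    qc$n_umi >= thresholds$min_umi &
    qc$n_genes >= thresholds$min_genes &
    !is.na(qc$complexity) & qc$complexity >= thresholds$min_complexity
  keep
}

#' Gene filter: keep genes detected in at least `min_cells` cells
#'
#' @param data an [sc_dataset()] (post cell filtering)
#' @param min_cells minimum number of cells with a nonzero count
#' @return logical keep mask over genes
#' @export
filter_genes <- function(data, min_cells = 10) {
  Matrix::colSums(data$counts > 0) >= min_cells
}

#' Log-normalize counts
#'
#' `x' = ln(1 + scale_factor * x / total UMIs of the cell)`; invariant to
#' per-cell count scaling.
#'
#' @param counts sparse cell x gene count matrix (or an `sc_dataset`)
#' @param scale_factor library-size scale, default 10000
#' @return sparse cell x gene matrix of normalized values
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  if (inherits(counts, "sc_dataset")) counts <- counts$counts
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) stop("cells with zero total counts; filter cells first")
  log1p(counts * (scale_factor / tot))
}

#' Rank genes by standardized variance and return the top fraction
#'
#' Default method fits a local-polynomial trend of log10 variance against
#' log10 mean (span 0.3), standardizes each gene by the trend-expected
#' standard deviation with values clipped at sqrt(n cells), and scores genes
#' by the variance of the clipped standardized values; it is meant to run
#' on raw counts, whose mean-variance trend it stabilizes. `method = "raw"`
#' ranks by plain variance of whatever matrix is given. Ties break by
#' column order.
#'
#' @param expr cell x gene matrix (raw counts for the default method)
#' @param fraction fraction of genes to return, in (0, 1]
#' @param method `"vst"` (trend-standardized) or `"raw"`
#' @return character vector of `ceiling(fraction * G)` gene names, ordered
#'   from most to least variable
#' @export
select_variable_genes <- function(expr, fraction = 0.20,
                                  method = c("vst", "raw")) {
  method <- match.arg(method)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (ncol(expr) < 10) stop("need at least 10 genes")
  x <- as.matrix(expr)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  score <- if (method == "raw") v else {
    ok <- v > 0 & mu > 0
    fit <- rep(0, ncol(x))
    lo <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.3, degree = 2)
    fit[ok] <- 10^stats::fitted(lo)
    clip <- sqrt(n)
    s <- numeric(ncol(x))
    for (j in which(ok)) {
      z <- (x[, j] - mu[j]) / sqrt(fit[j])
      z[z > clip] <- clip; z[z < -clip] <- -clip
      s[j] <- stats::var(z)
    }
    s
  }
  k <- ceiling(fraction * ncol(x))
  ord <- order(-score, seq_along(score))
  colnames(x)[ord[seq_len(k)]]
}

#' Center and scale selected genes, clipping extreme values
#'
#' @param normalized cell x gene normalized matrix
#' @param genes gene names to scale (default all)
#' @param clip symmetric clip bound on scaled values
#' @return dense cell x gene matrix, per-gene mean 0 / sd 1, clipped
#' @export
scale_genes <- function(normalized, genes = colnames(normalized), clip = 10) {
  x <- as.matrix(normalized[, genes, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0                      # constant genes -> zero column
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

#' PCA with percent-variance bookkeeping
#'
#' Percent variance is relative to the total variance of the input matrix,
#' so `pv` sums to 100 over all (not just retained) components.
#'
#' @param scaled dense cell x gene matrix (already centered/scaled)
#' @param npcs number of components to retain
#' @return `pca_result`: list(scores, rotation, pv, cp, sdev)
#' @export
run_pca <- function(scaled, npcs = 40) {
  npcs <- min(npcs, nrow(scaled) - 1L, ncol(scaled))
  p <- stats::prcomp(scaled, center = FALSE, scale. = FALSE, rank. = npcs)
  total <- sum(p$sdev^2)
  nz <- sum(p$sdev > 1e-10)
  if (nz < npcs) {
    warning("rank-deficient input: only ", nz, " informative components")
    npcs <- nz
  }
  pv <- 100 * p$sdev[seq_len(npcs)]^2 / total
  structure(list(scores = p$x[, seq_len(npcs), drop = FALSE],
                 rotation = p$rotation[, seq_len(npcs), drop = FALSE],
                 pv = pv, cp = cumsum(pv), sdev = p$sdev),
            class = "pca_result")
}

#' Select the number of informative components
#'
#' Two criteria are evaluated on the percent-variance vector: (a) the first
#' component where the cumulative percent exceeds 90 while the component's
#' own percent is below 5; (b) the first component whose percent-variance
#' drop to the next component is below 0.1. The smaller of the two indices
#' is returned; if neither criterion is met, `length(pv)` with a warning.
#'
#' @param pv percent-variance vector (or a `pca_result`)
#' @param cp_min,pv_max,delta criterion constants
#' @param change `"absolute"` (default) compares `pv[i] - pv[i+1]` with
#'   `delta`; `"relative"` compares `(pv[i] - pv[i+1]) / pv[i]`.
#' @return integer component count
#' @export
select_optimal_dims <- function(pv, cp_min = 90, pv_max = 5, delta = 0.1,
                                change = c("absolute", "relative")) {
  change <- match.arg(change)
  if (inherits(pv, "pca_result")) pv <- pv$pv
  stopifnot(length(pv) >= 1)
  cp <- cumsum(pv)
  s2 <- which(cp > cp_min & pv < pv_max)
  s2 <- if (length(s2)) min(s2) else NA_integer_
  d <- pv[-length(pv)] - pv[-1]
  if (change == "relative") d <- d / pv[-length(pv)]
  s3 <- which(d < delta)
  s3 <- if (length(s3)) min(s3) else NA_integer_
  if (is.na(s2) && is.na(s3)) {
    warning("no dimension criterion met; using all components")
    return(length(pv))
  }
  min(s2, s3, na.rm = TRUE)
}

# shared-nearest-neighbor graph: k nearest neighbors (self included),
# Jaccard overlap weights, edges below `prune` removed
snn_graph <- function(coords, k = 20, prune = 1 / 15) {
  n <- nrow(coords)
  if (k > n) {
    warning("fewer cells than neighbors; reducing k to ", n)
    k <- n
  }
  d <- as.matrix(stats::dist(coords))
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  ind <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  jac <- methods::as(methods::as(Matrix::tcrossprod(ind), "CsparseMatrix"),
                     "generalMatrix")
  jac@x <- jac@x / (2 * k - jac@x)     # Jaccard: shared / (union)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  Matrix::drop0(jac)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Louvain community detection (igraph) on an SNN graph built from the
#' first `dims` principal components.
#'
#' @param scores cell x component score matrix (or a `pca_result`)
#' @param dims number of leading components to use
#' @param resolution Louvain resolution
#' @param k neighbors for the SNN graph
#' @param prune SNN edge-weight pruning threshold
#' @param seed RNG seed for the community search
#' @return integer cluster label per cell
#' @export
cluster_cells <- function(scores, dims = NULL, resolution = 2, k = 20,
                          prune = 1 / 15, seed = 0L) {
  if (inherits(scores, "pca_result")) scores <- scores$scores
  if (is.null(dims)) dims <- ncol(scores)
  stopifnot(dims <= ncol(scores))
  g <- snn_graph(scores[, seq_len(dims), drop = FALSE], k = k, prune = prune)
  gr <- igraph::graph_from_adjacency_matrix(g, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(gr, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Assign a major cell type to every cell via cluster-level markers
#'
#' Marker expression is z-scored per gene across cells; each cluster gets
#' the type whose markers have the highest mean scaled expression in it,
#' and every cell inherits its cluster's type. Ties break by type-name
#' order with a warning.
#'
#' @param clusters integer cluster label per cell
#' @param normalized cell x gene normalized matrix
#' @param markers data.frame with columns `gene`, `type`
#' @return character cell-type label per cell, with the cluster-to-type map
#'   in attribute `"cluster_types"`
#' @export
assign_cell_types <- function(clusters, normalized, markers) {
  present <- markers$gene %in% colnames(normalized)
  if (!any(present)) stop("no marker genes found in the matrix")
  lost <- setdiff(unique(markers$type), unique(markers$type[present]))
  if (length(lost))
    warning("no markers present for type(s): ", paste(lost, collapse = ", "))
  markers <- markers[present, , drop = FALSE]
  sc <- scale_genes(normalized, unique(markers$gene))
  types <- sort(unique(markers$type))
  cl <- sort(unique(clusters))
  score <- matrix(NA_real_, length(cl), length(types),
                  dimnames = list(cl, types))
  for (ci in seq_along(cl)) {
    rows <- clusters == cl[ci]
    for (t in types) {
      g <- markers$gene[markers$type == t]
      score[ci, t] <- mean(sc[rows, g, drop = FALSE])
    }
  }
  best <- apply(score, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1) warning("marker-score tie; using type-name order")
    types[min(w)]
  })
  structure(best[as.character(clusters)], names = NULL,
            cluster_types = stats::setNames(best, cl))
}
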