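#' Select the cells dominated by one module's expression
#'
#' A cell is selected when its mean normalized expression over the
#' module's genes strictly exceeds its mean over the genes of all other
#' non-grey modules (grey genes are excluded from both sides).
#'
#' @param normalized cell x gene normalized matrix
#' @param partition gene -> module label vector
#' @param module the module of interest (non-grey)
#' @return integer indices of the selected cells
#' @export
select_module_cells <- function(normalized, partition, module) {
  stopifnot(module != "grey")
  mods <- setdiff(unique(partition), "grey")
  if (!(module %in% mods)) stop("unknown module: ", module)
  if (length(mods) < 2) stop("need at least 2 modules to contrast")
  own <- names(partition)[partition == module]
  other <- names(partition)[partition != module & partition != "grey"]
  m_own <- Matrix::rowMeans(normalized[, own, drop = FALSE])
  m_oth <- Matrix::rowMeans(normalized[, other, drop = FALSE])
  sel <- which(as.vector(m_own) > as.vector(m_oth))
  if (length(sel) == 0)
    stop("no cells dominated by module ", module)
  sel
}

#' Sub-network adjacency of a module over its selected cells
#'
#' @param normalized cell x gene normalized matrix
#' @param cells selected cell indices (>= 10)
#' @param genes module gene names
#' @param power soft-threshold exponent (use the reference network's beta)
#' @param sign_mode adjacency flavor
#' @return gene x gene adjacency over the selected cells
#' @export
module_subnetwork <- function(normalized, cells, genes, power = 6,
                              sign_mode = "unsigned") {
  if (length(cells) < 10)
    stop("only ", length(cells), " selected cells; need at least 10")
  adjacency_matrix(as.matrix(normalized[cells, genes, drop = FALSE]),
                   power = power, sign_mode = sign_mode)
}

#' Top-fraction edges of two condition networks, with uniqueness flags
#'
#' All upper-triangle edges are ranked by weight per condition; the top
#' `ceiling(fraction * E)` form each condition's top set, and an edge is
#' unique to a condition when it is in that top set but not the other's.
#'
#' @param adj_ref,adj_test adjacency matrices over the same gene set
#' @param fraction top fraction of edges, default 0.10
#' @return list of data.frames `ref` and `test` with columns gene_i,
#'   gene_j, weight, unique
#' @export
top_unique_edges <- function(adj_ref, adj_test, fraction = 0.10) {
  stopifnot(identical(dim(adj_ref), dim(adj_test)))
  g <- colnames(adj_ref)
  ut <- which(upper.tri(adj_ref), arr.ind = TRUE)
  n_top <- ceiling(fraction * nrow(ut))
  top_of <- function(adj) {
    w <- adj[upper.tri(adj)]
    ord <- order(-w, seq_along(w))
    idx <- ord[seq_len(n_top)]
    data.frame(gene_i = g[ut[idx, 1]], gene_j = g[ut[idx, 2]],
               weight = w[idx], edge = idx)
  }
  tr <- top_of(adj_ref); tt <- top_of(adj_test)
  tr$unique <- !(tr$edge %in% tt$edge)
  tt$unique <- !(tt$edge %in% tr$edge)
  list(ref = tr[, c("gene_i", "gene_j", "weight", "unique")],
       test = tt[, c("gene_i", "gene_j", "weight", "unique")])
}

#' Spearman rank correlation of connectivities
#'
#' Without ties the textbook closed form `rho = 1 - 6 * sum(d^2) /
#' (n (n^2 - 1))` is used on the rank differences; with ties, average
#' ranks enter a product-moment correlation. Low rho = the module's
#' connectivity pattern differs between the two networks.
#'
#' @param k_ref,k_test per-gene connectivity in the same gene order (n >= 3)
#' @return rho in `[-1, 1]`, or NA with a warning for constant input
#' @export
connectivity_spearman <- function(k_ref, k_test) {
  n <- length(k_ref)
  stopifnot(length(k_test) == n, n >= 3)
  if (stats::sd(k_ref) == 0 || stats::sd(k_test) == 0) {
    warning("constant connectivity vector; rho undefined")
    return(NA_real_)
  }
  r1 <- rank(k_ref); r2 <- rank(k_test)
  if (anyDuplicated(r1) || anyDuplicated(r2))
    return(stats::cor(r1, r2))
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

#' Per-gene two-sample z-scores between conditions
#'
#' `z = (mean_test - mean_ref) / sqrt(var_test/n_test + var_ref/n_ref)`
#' with sample variances as plug-in estimates of the population variances;
#' the test condition is subtracted first, so positive z means higher in
#' the test condition. When both variances are zero, z is 0 for equal
#' means and +/-Inf (with a warning) otherwise.
#'
#' @param ref_expr,test_expr cell x gene matrices over the same genes
#'   (each with >= 2 cells), typically restricted to each condition's
#'   module-selected cells
#' @return named numeric z per gene
#' @export
gene_zscores <- function(ref_expr, test_expr) {
  ref_expr <- as.matrix(ref_expr); test_expr <- as.matrix(test_expr)
  stopifnot(identical(colnames(ref_expr), colnames(test_expr)),
            nrow(ref_expr) >= 2, nrow(test_expr) >= 2)
  m1 <- colMeans(test_expr); m0 <- colMeans(ref_expr)
  v1 <- apply(test_expr, 2, stats::var)
  v0 <- apply(ref_expr, 2, stats::var)
  se <- sqrt(v1 / nrow(test_expr) + v0 / nrow(ref_expr))
  z <- ifelse(se == 0, ifelse(m1 == m0, 0, sign(m1 - m0) * Inf),
              (m1 - m0) / se)
  if (any(is.infinite(z)))
    warning("zero-variance gene(s) with unequal means: z = +/-Inf")
  stats::setNames(z, colnames(ref_expr))
}

#' Compare one module's sub-networks between conditions
#'
#' Runs the module-cell selection, builds the per-condition sub-network
#' adjacencies over the module's genes, extracts the top-fraction unique
#' edges, computes node connectivities, their Spearman rho, and per-gene
#' two-sample z-scores (test vs reference) over the selected cells.
#'
#' @param ref_norm,test_norm cell x gene normalized matrices
#' @param partition gene -> module label vector
#' @param module module to compare
#' @param power soft-threshold exponent of the reference network
#' @param edge_fraction top edge fraction, default 0.10
#' @param sign_mode adjacency flavor
#' @return `subnetwork_comparison`: list(module, nodes, edges, rho,
#'   n_cells) where `nodes` has gene, k_ref, k_test, z and a clamped color
#'   value, and `edges` is the [top_unique_edges()] pair
#' @export
compare_module <- function(ref_norm, test_norm, partition, module,
                           power = 6, edge_fraction = 0.10,
                           sign_mode = "unsigned") {
  genes <- names(partition)[partition == module]
  cells_ref <- select_module_cells(ref_norm, partition, module)
  cells_test <- select_module_cells(test_norm, partition, module)
  a_ref <- module_subnetwork(ref_norm, cells_ref, genes, power, sign_mode)
  a_test <- module_subnetwork(test_norm, cells_test, genes, power, sign_mode)
  k_ref <- connectivity(a_ref)
  k_test <- connectivity(a_test)
  rho <- connectivity_spearman(k_ref, k_test)
  z <- gene_zscores(ref_norm[cells_ref, genes, drop = FALSE],
                    test_norm[cells_test, genes, drop = FALSE])
  nodes <- data.frame(gene = genes, k_ref = as.vector(k_ref),
                      k_test = as.vector(k_test), z = as.vector(z[genes]),
                      color = zscore_color(z[genes]), row.names = NULL)
  structure(list(module = module, nodes = nodes,
                 edges = top_unique_edges(a_ref, a_test, edge_fraction),
                 rho = rho,
                 n_cells = c(ref = length(cells_ref),
                             test = length(cells_test))),
            class = "subnetwork_comparison")
}

#' @exportS3Method base::print
print.subnetwork_comparison <- function(x, ...) {
  cat(sprintf(
    "subnetwork comparison, module %s: %d genes, rho = %.3f\n",
    x$module, nrow(x$nodes), x$rho))
  cat(sprintf("  cells: %d (ref) / %d (test); unique top edges: %d / %d\n",
              x$n_cells["ref"], x$n_cells["test"],
              sum(x$edges$ref$unique), sum(x$edges$test$unique)))
  invisible(x)
}

#' Map z-scores to a blue-white-red color scale
#'
#' Values are clamped to `[-2, 2]`: blue at -2 or lower, white at 0, red
#' at 2 or greater.
#'
#' @param z numeric z-scores
#' @return hex color per value
#' @export
zscore_color <- function(z) {
  zc <- pmax(pmin(z, 2), -2)
  ramp <- grDevices::colorRamp(c("blue", "white", "red"))
  rgb <- ramp((zc + 2) / 4)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Export a sub-network comparison as TSV tables (optional circle plot)
#'
#' Writes `<module>_nodes.tsv` and `<module>_edges_<ref|test>.tsv` under
#' `path`, and, when `plot = TRUE`, a circle plot with nodes on a circle,
#' per-condition edges, and z-colored node markers.
#'
#' @param cmp a [compare_module()] result
#' @param path output directory
#' @param plot draw a circle plot on the active device
#' @return `path`, invisibly
#' @export
export_comparison <- function(cmp, path, plot = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cmp$nodes,
                     file.path(path, paste0(cmp$module, "_nodes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in c("ref", "test"))
    utils::write.table(cmp$edges[[cond]],
                       file.path(path,
                                 paste0(cmp$module, "_edges_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (plot) plot_circle(cmp)
  invisible(path)
}

#' Circle plot of a module sub-network comparison
#'
#' @param cmp a [compare_module()] result
#' @param which which condition's unique edges to draw
#' @export
plot_circle <- function(cmp, which = c("both", "ref", "test")) {
  which <- match.arg(which)
  n <- nrow(cmp$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(cos(th), sin(th))
  rownames(xy) <- cmp$nodes$gene
  graphics::plot(xy, asp = 1, axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 main = paste0(cmp$module, "  (rho = ",
                               signif(cmp$rho, 2), ")"),
                 pch = NA)
  draw <- function(ed, col) {
    ed <- ed[ed$unique, , drop = FALSE]
    if (nrow(ed) == 0) return()
    graphics::segments(xy[ed$gene_i, 1], xy[ed$gene_i, 2],
                       xy[ed$gene_j, 1], xy[ed$gene_j, 2],
                       col = col, lwd = 0.5 + 3 * ed$weight)
  }
  if (which %in% c("both", "ref")) draw(cmp$edges$ref, "goldenrod")
  if (which %in% c("both", "test")) draw(cmp$edges$test, "brown")
  graphics::points(xy, pch = 21, bg = cmp$nodes$color, cex = 1.4)
  graphics::text(xy * 1.12, labels = cmp$nodes$gene, cex = 0.5)
  invisible(cmp)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test of a query gene list against each
#' gene set, restricted to a stated universe, with Benjamini-Hochberg
#' multiple-testing correction.
#'
#' @param query character vector of query genes (subset of `universe`)
#' @param gene_sets named list of gene-identifier vectors ([read_gmt()])
#' @param universe character vector of all analyzable genes
#' @return data.frame sorted by ascending p: set, overlap, set_size,
#'   query_size, p, q
#' @export
ora <- function(query, gene_sets, universe) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query gene list")
  if (!all(query %in% universe)) stop("query genes outside the universe")
  universe <- unique(universe)
  N <- length(universe); k <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    m <- length(set)
    ov <- length(intersect(query, set))
    p <- if (m == 0) 1 else
      stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set = s, overlap = ov, set_size = m, query_size = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}
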