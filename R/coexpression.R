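#' Weighted-network construction and module-detection parameters
#'
#' @param power soft-threshold exponent beta applied to the correlation
#' @param sign_mode `"unsigned"` (`|r|^beta`) or `"signed"`
#'   (`((1+r)/2)^beta`)
#' @param min_module_size smallest allowed module
#' @param merge_height modules whose eigengenes correlate above
#'   `1 - merge_height` are merged
#' @param deep_split 0..4; larger values split branches more aggressively
#' @param cut_height static cut as a fraction of the dendrogram height
#'   range; `NULL` uses 0.99
#' @param label_prefix prefix for module labels (`"M"`, `"E"`, `"R"`, ...)
#' @export
network_params <- function(power = 6, sign_mode = c("unsigned", "signed"),
                           min_module_size = 30, merge_height = 0.15,
                           deep_split = 2, cut_height = NULL,
                           label_prefix = "M") {
  sign_mode <- match.arg(sign_mode)
  stopifnot(power >= 1, min_module_size >= 2, merge_height > 0,
            merge_height < 1, deep_split %in% 0:4)
  list(power = power, sign_mode = sign_mode,
       min_module_size = as.integer(min_module_size),
       merge_height = merge_height, deep_split = as.integer(deep_split),
       cut_height = cut_height, label_prefix = label_prefix)
}

#' Variable genes shared by (or taken from) the reference condition
#'
#' `"intersection"` takes the genes present in both conditions' top
#' variable fractions; `"reference_only"` takes the reference's list alone.
#'
#' @param ref_expr,test_expr cell x gene matrices over a shared gene
#'   universe (raw counts for the default vst ranking)
#' @param mode `"intersection"` or `"reference_only"`
#' @param fraction top fraction of variable genes per condition
#' @param method passed to [select_variable_genes()]
#' @return character vector of gene names
#' @export
variable_gene_set <- function(ref_expr, test_expr,
                              mode = c("intersection", "reference_only"),
                              fraction = 0.20, method = "vst") {
  mode <- match.arg(mode)
  ref_top <- select_variable_genes(ref_expr, fraction, method)
  if (mode == "reference_only") return(ref_top)
  test_top <- select_variable_genes(test_expr, fraction, method)
  out <- ref_top[ref_top %in% test_top]
  if (length(out) == 0) stop("empty intersection of variable-gene sets")
  out
}

#' Scale-free fit index of a connectivity distribution
#'
#' Connectivities are binned into `nbreaks` equal-width bins; the log10
#' frequency is regressed on the log10 mean connectivity per bin. The
#' returned R-squared is signed by the negative slope, so heavy-tailed
#' (power-law-like) distributions score close to 1.
#'
#' @param k per-node connectivity vector
#' @param nbreaks number of bins
#' @return list(r2 = signed R-squared, slope, fit data.frame)
#' @export
scale_free_fit <- function(k, nbreaks = 10) {
  if (diff(range(k)) == 0) stop("degenerate connectivity: all values equal")
  bins <- cut(k, nbreaks)
  dk <- tapply(k, bins, mean)
  p <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & !is.na(p) & dk > 0
  df <- data.frame(log_k = log10(dk[ok]), log_p = log10(p[ok]))
  fit <- stats::lm(log_p ~ log_k, data = df)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["log_k"]]
  list(r2 = -sign(slope) * r2, slope = slope, fit = df)
}

#' Choose the soft-threshold power for scale-free topology
#'
#' @param expr cell x gene matrix (normalized values)
#' @param powers candidate exponents
#' @param target_r2 signed R-squared to reach
#' @param sign_mode adjacency flavor, see [network_params()]
#' @param nbreaks connectivity histogram bins
#' @return list(power, table of power/r2/slope/mean_k); if no power reaches
#'   the target the best-fitting one is returned with a warning
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.8,
                                sign_mode = "unsigned", nbreaks = 10) {
  if (ncol(expr) < 50) stop("need at least 50 genes to assess topology")
  C <- stats::cor(as.matrix(expr))
  base <- if (sign_mode == "unsigned") abs(C) else (1 + C) / 2
  diag(base) <- 0
  rows <- lapply(powers, function(b) {
    k <- colSums(base^b)
    f <- tryCatch(scale_free_fit(k, nbreaks),
                  error = function(e) list(r2 = NA_real_, slope = NA_real_))
    data.frame(power = b, r2 = f$r2, slope = f$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$r2)))
    stop("degenerate connectivity at every candidate power")
  hit <- which(!is.na(tab$r2) & tab$r2 >= target_r2)
  if (length(hit)) {
    power <- tab$power[min(hit)]
  } else {
    power <- tab$power[which.max(tab$r2)]
    warning("no power reached R^2 >= ", target_r2,
            "; using best fit (power ", power, ")")
  }
  list(power = power, table = tab)
}

#' Co-expression adjacency
#'
#' Pearson correlation over cells, mapped to `[0,1]` as `|r|^beta`
#' (unsigned) or `((1+r)/2)^beta` (signed). Constant genes get zero
#' correlations with a warning. The diagonal is 1 by convention;
#' operations that need it excluded ([connectivity()], edge listing)
#' handle that themselves.
#'
#' @param expr cell x gene matrix
#' @param power soft-threshold exponent
#' @param sign_mode `"unsigned"` or `"signed"`
#' @return symmetric gene x gene adjacency matrix
#' @export
adjacency_matrix <- function(expr, power = 6,
                             sign_mode = c("unsigned", "signed")) {
  sign_mode <- match.arg(sign_mode)
  x <- as.matrix(expr)
  sds <- apply(x, 2, stats::sd)
  C <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s): correlations set to 0")
    C[sds == 0, ] <- 0
    C[, sds == 0] <- 0
  }
  C[is.na(C)] <- 0
  a <- if (sign_mode == "unsigned") abs(C)^power else ((1 + C) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`, the shared-neighbor smoothing of the
#' adjacency; `TOM_ii = 1` and `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj symmetric adjacency with entries in `[0,1]`
#' @return symmetric TOM matrix
#' @export
topological_overlap <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  l <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Per-gene connectivity (weighted degree)
#'
#' Sum of a gene's adjacency weights, excluding the diagonal. With a
#' partition, the sum runs only over genes of the same module
#' (intramodular connectivity, kIM).
#'
#' @param adj adjacency matrix
#' @param partition optional gene -> module label vector aligned with `adj`
#' @return named numeric connectivity per gene
#' @export
connectivity <- function(adj, partition = NULL) {
  a <- as.matrix(adj)
  diag(a) <- 0
  if (is.null(partition)) return(colSums(a))
  stopifnot(length(partition) == ncol(a))
  k <- numeric(ncol(a))
  for (m in unique(partition)) {
    idx <- which(partition == m)
    k[idx] <- colSums(a[idx, idx, drop = FALSE])
  }
  names(k) <- colnames(a)
  k
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix, scaled
#' to unit norm and oriented so that it correlates non-negatively with the
#' module's average expression.
#'
#' @param expr cell x gene matrix
#' @param genes module member gene names (>= 2)
#' @return list(scores = cell vector, var_explained, kme = per-gene
#'   correlation with the eigengene)
#' @export
module_eigengene <- function(expr, genes) {
  stopifnot(length(genes) >= 2)
  x <- scale_genes(expr, genes, clip = Inf)
  if (all(x == 0)) stop("constant module submatrix")
  sv <- svd(x, nu = 1, nv = 0)
  e <- sv$u[, 1]
  orient <- suppressWarnings(stats::cor(e, rowMeans(x)))
  if (!is.na(orient) && orient < 0) e <- -e
  kme <- suppressWarnings(as.vector(stats::cor(x, e)))
  kme[is.na(kme)] <- 0
  names(kme) <- genes
  list(scores = e, var_explained = sv$d[1]^2 / sum(sv$d^2), kme = kme)
}

# ---- tree cutting -----------------------------------------------------

# members of every internal node of an hclust tree, as leaf index lists
tree_members <- function(merge) {
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    a <- merge[i, 1]; b <- merge[i, 2]
    members[[i]] <- c(if (a < 0) -a else members[[a]],
                      if (b < 0) -b else members[[b]])
  }
  members
}

# recursive branch identification: walk down from the root, splitting any
# node whose merge height sits above `gamma` (relative to the height
# range); emit branches of at least `core_min` leaves
tree_branches <- function(h, members, gamma, core_min) {
  hmin <- min(h$height)
  rel <- (h$height - hmin) / max(diff(range(h$height)),
                                 .Machine$double.eps)
  branches <- list()
  stack <- nrow(h$merge)
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    if (node < 0) next
    if (rel[node] <= gamma || length(members[[node]]) < 2 * core_min) {
      if (length(members[[node]]) >= core_min)
        branches[[length(branches) + 1L]] <- members[[node]]
      next
    }
    stack <- c(stack, h$merge[node, 1], h$merge[node, 2])
  }
  branches
}

#' Detect modules by hierarchical clustering of the TOM dissimilarity
#'
#' Average-linkage clustering of `1 - TOM`, followed by a dynamic-style
#' tree cut in three stages. (1) Branch identification: walking down from
#' the dendrogram root, nodes merging high in the height range (threshold
#' set by `deep_split`) are split; surviving branches of at least two
#' thirds of `min_module_size` become module cores. (2) Membership
#' refinement (needs `expr`): each gene is assigned to the core whose
#' eigengene it correlates with best (its kME), or to `"grey"` below
#' `kme_prune`. (3) Modules whose eigengenes correlate above
#' `1 - merge_height` are merged iteratively, and modules below
#' `min_module_size` are dissolved into grey. Labels are assigned in
#' ascending size order (`<prefix>1` = smallest).
#'
#' @param tom TOM (or any similarity whose complement is a dissimilarity)
#' @param expr optional cell x gene matrix for the kME refinement and
#'   eigengene merge stages; without it the raw branches are returned
#' @param params a [network_params()] list
#' @param kme_prune minimum |kME| for module membership in the refinement
#'   stage
#' @return `module_partition`: named character vector gene -> label with
#'   attributes `sizes` (named, ascending) and `dendrogram`
#' @export
detect_modules <- function(tom, expr = NULL, params = network_params(),
                           kme_prune = 0.3) {
  g <- colnames(tom)
  if (is.null(g)) g <- paste0("g", seq_len(ncol(tom)))
  if (ncol(tom) < params$min_module_size)
    stop("fewer genes than min_module_size")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  gamma <- c(0.95, 0.90, 0.85, 0.80, 0.75)[params$deep_split + 1L]
  if (!is.null(params$cut_height)) gamma <- params$cut_height
  core_min <- max(12L, floor(2 * params$min_module_size / 3))
  members <- tree_members(h$merge)
  branches <- tree_branches(h, members, gamma, core_min)

  labels <- rep("grey", length(g))
  for (i in seq_along(branches)) labels[branches[[i]]] <- paste0("tmp", i)
  names(labels) <- g

  if (!is.null(expr) && length(branches)) {
    expr <- as.matrix(expr)
    # kME refinement: reassign every gene to its best-matching eigengene
    mods <- setdiff(unique(labels), "grey")
    me <- vapply(mods, function(m)
      module_eigengene(expr, g[labels == m])$scores, numeric(nrow(expr)))
    kme <- suppressWarnings(stats::cor(expr, me))
    kme[is.na(kme)] <- 0
    best <- max.col(abs(kme), ties.method = "first")
    hit <- abs(kme)[cbind(seq_along(best), best)] >= kme_prune
    labels <- ifelse(hit, mods[best], "grey")
    names(labels) <- g
    # iterative eigengene merging
    repeat {
      mods <- setdiff(unique(labels), "grey")
      if (length(mods) < 2) break
      me <- vapply(mods, function(m)
        module_eigengene(expr, g[labels == m])$scores, numeric(nrow(expr)))
      cc <- stats::cor(me)
      diag(cc) <- -Inf
      top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[top[1], top[2]] <= 1 - params$merge_height) break
      labels[labels == mods[top[2]]] <- mods[top[1]]
    }
  }
  for (m in setdiff(unique(labels), "grey"))
    if (sum(labels == m) < params$min_module_size)
      labels[labels == m] <- "grey"

  # relabel ascending by size
  mods <- setdiff(unique(labels), "grey")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- order(sizes, mods)
  new <- stats::setNames(paste0(params$label_prefix, seq_along(mods)),
                         mods[ord])
  out <- ifelse(labels == "grey", "grey", new[labels])
  names(out) <- g
  sizes <- sort(table(out[out != "grey"]))
  structure(out, class = "module_partition",
            sizes = stats::setNames(as.integer(sizes), names(sizes)),
            dendrogram = h)
}

#' @exportS3Method base::print
print.module_partition <- function(x, ...) {
  s <- attr(x, "sizes")
  cat(sprintf("module_partition: %d genes, %d modules, %d grey\n",
              length(x), length(s), sum(x == "grey")))
  if (length(s)) print(s)
  invisible(x)
}
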