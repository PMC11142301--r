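# Names of the preservation statistics; the first four are density
# statistics (computed in the test network over a reference module's
# genes), the last three compare per-gene quantities between networks.
pres_stat_names <- function() {
  c("mean_cor", "mean_adj", "prop_var_expl", "mean_kme",
    "cor_kim", "cor_kme", "cor_cor")
}

# leading eigenvector summary of a correlation submatrix: kME of each gene
# with the module eigengene, derived without touching expression (genes
# are standardized, so kME_g = (C v)_g / sqrt(v' C v)).
cor_kme_vec <- function(Csub) {
  ev <- eigen(Csub, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  denom <- sqrt(max(as.numeric(crossprod(v, Csub %*% v)), .Machine$double.eps))
  as.vector(Csub %*% v) / denom
}

# the seven preservation statistics for one gene set, given the two
# precomputed correlation matrices over the analyzed universe
pres_set_stats <- function(idx, Cref, Ctest, power, sign_mode) {
  Cr <- Cref[idx, idx]; Ct <- Ctest[idx, idx]
  toadj <- function(C) if (sign_mode == "unsigned") abs(C)^power
    else ((1 + C) / 2)^power
  Ar <- toadj(Cr); At <- toadj(Ct)
  off <- upper.tri(Ct)
  kme_t <- cor_kme_vec(Ct); kme_r <- cor_kme_vec(Cr)
  kim_r <- rowSums(Ar) - 1; kim_t <- rowSums(At) - 1
  safe_cor <- function(a, b) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (length(a) < 2 || is.na(sa) || is.na(sb) || sa == 0 || sb == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
  c(mean_cor = mean(Ct[off]),
    mean_adj = mean(At[off]),
    prop_var_expl = mean(kme_t^2),
    mean_kme = mean(abs(kme_t)),
    cor_kim = safe_cor(kim_r, kim_t),
    cor_kme = safe_cor(kme_r, kme_t),
    cor_cor = safe_cor(Cr[off], Ct[off]))
}

#' Median preservation ranks from an observed-statistics table
#'
#' Modules are ranked per statistic with rank 1 = most preserved (largest
#' value), ties receiving average ranks. The density and connectivity
#' median ranks are the medians over their statistic groups; the composite
#' `median_rank_pres` averages the two sub-medians, following the
#' convention of the permutation-Z preservation framework.
#'
#' @param obs module x statistic matrix with columns named as in the
#'   preservation report (4 density then 3 connectivity statistics)
#' @return data.frame: median_rank_density, median_rank_connectivity,
#'   median_rank_pres (one row per module, in input order)
#' @export
median_ranks <- function(obs) {
  obs <- round(as.matrix(obs), 10)   # let numerically equal stats tie
  rk <- apply(obs, 2, function(x) rank(-x, ties.method = "average",
                                       na.last = "keep"))
  if (is.null(dim(rk))) rk <- matrix(rk, nrow = 1)
  dens <- rk[, 1:4, drop = FALSE]
  conn <- rk[, 5:7, drop = FALSE]
  mrd <- apply(dens, 1, stats::median, na.rm = TRUE)
  mrc <- apply(conn, 1, stats::median, na.rm = TRUE)
  data.frame(median_rank_density = mrd, median_rank_connectivity = mrc,
             median_rank_pres = (mrd + mrc) / 2)
}

#' Module preservation statistics between two conditions
#'
#' For each reference module, density statistics (mean within-module
#' correlation, mean adjacency, eigengene variance explained, mean |kME|)
#' are computed in the test network, and connectivity statistics
#' (correlation of intramodular connectivity, of kME, and of the
#' vectorized within-module correlations between reference and test)
#' compare the two networks. Permutation Z-scores reassign each module's
#' label to random gene sets of the same size drawn from the analyzed
#' universe; `Z = (obs - mean_perm) / sd_perm`, with `Zdensity` /
#' `Zconnectivity` the medians of their groups and `Zsummary` their mean.
#' Median ranks are computed from the observed statistics (see
#' [median_ranks()]).
#'
#' @param ref_expr,test_expr cell x gene normalized matrices sharing the
#'   partition's gene universe
#' @param partition a gene -> module label vector ([detect_modules()]
#'   output or any named character vector; `"grey"` is ignored as a module
#'   but stays in the permutation universe)
#' @param power,sign_mode adjacency parameters (use the reference
#'   network's)
#' @param n_perm permutations for the Z statistics; 0 skips them (median
#'   ranks and observed statistics only)
#' @param seed RNG seed for the permutations
#' @return a `preservation_report` data.frame: one row per module with
#'   size, the seven observed statistics, median ranks, and (if permuted)
#'   per-statistic Z, Zdensity, Zconnectivity, Zsummary
#' @export
module_preservation <- function(ref_expr, test_expr, partition, power = 6,
                                sign_mode = "unsigned", n_perm = 50,
                                seed = 1L) {
  genes <- names(partition)
  present <- genes %in% colnames(ref_expr) & genes %in% colnames(test_expr)
  if (!all(present)) {
    warning(sum(!present), " partition gene(s) absent from an expression ",
            "matrix; dropped")
    partition <- partition[present]
    genes <- genes[present]
  }
  universe <- genes
  Cref <- suppressWarnings(stats::cor(as.matrix(ref_expr[, universe])))
  Ctest <- suppressWarnings(stats::cor(as.matrix(test_expr[, universe])))
  Cref[is.na(Cref)] <- 0; Ctest[is.na(Ctest)] <- 0

  mods <- setdiff(unique(partition), "grey")
  sizes <- vapply(mods, function(m) sum(partition == m), integer(1))
  ord <- order(sizes, mods)
  mods <- mods[ord]
  sizes <- sizes[ord]
  if (length(mods) < 1) stop("no non-grey modules in the partition")
  idx_of <- lapply(mods, function(m) which(partition == m))

  obs <- t(vapply(idx_of, pres_set_stats, numeric(7), Cref = Cref,
                  Ctest = Ctest, power = power, sign_mode = sign_mode))
  colnames(obs) <- pres_stat_names()
  mr <- median_ranks(obs)

  rep_df <- data.frame(module = mods, size = as.integer(sizes),
                       fragile = sizes < 3, obs, mr, row.names = NULL)

  if (n_perm > 0) {
    if (n_perm < 20) warning("n_perm < 20: Z statistics will be unstable")
    set.seed(seed)
    # draw permutation gene sets from the name-sorted universe so the Z
    # statistics do not depend on the input gene order
    canon <- order(universe)
    perm <- array(NA_real_, c(length(mods), 7, n_perm))
    for (p in seq_len(n_perm)) {
      for (i in seq_along(mods)) {
        ridx <- canon[sample(length(universe), sizes[i])]
        perm[i, , p] <- pres_set_stats(ridx, Cref, Ctest, power, sign_mode)
      }
    }
    mu <- apply(perm, 1:2, mean, na.rm = TRUE)
    sdv <- apply(perm, 1:2, stats::sd, na.rm = TRUE)
    Z <- (obs - mu) / sdv
    Z[sdv == 0] <- NA
    colnames(Z) <- paste0("Z_", pres_stat_names())
    zdens <- apply(Z[, 1:4, drop = FALSE], 1, stats::median, na.rm = TRUE)
    zconn <- apply(Z[, 5:7, drop = FALSE], 1, stats::median, na.rm = TRUE)
    rep_df <- cbind(rep_df, Z, Zdensity = zdens, Zconnectivity = zconn,
                    Zsummary = (zdens + zconn) / 2)
  }
  class(rep_df) <- c("preservation_report", "data.frame")
  rep_df
}

#' @exportS3Method base::print
print.preservation_report <- function(x, ...) {
  cat("module preservation report:", nrow(x), "modules\n")
  cols <- intersect(c("module", "size", "median_rank_pres", "Zsummary",
                      "cor_kim"), names(x))
  print.data.frame(x[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Flag non-preserved modules
#'
#' A module is flagged when its composite median rank is at least
#' `rank_threshold` and its size is at most `size_threshold` (default:
#' median rank >= 10 and size <= 100).
#'
#' @param report a [module_preservation()] report
#' @param rank_threshold,size_threshold flagging criteria
#' @return data.frame: module, median_rank, size, flagged
#' @export
flag_nonpreserved <- function(report, rank_threshold = 10,
                              size_threshold = 100) {
  data.frame(module = report$module,
             median_rank = report$median_rank_pres,
             size = report$size,
             flagged = report$median_rank_pres >= rank_threshold &
               report$size <= size_threshold)
}
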