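#' Largest-remainder quotas that equalize group totals
#'
#' Every non-base group is given per-type quotas proportional to its own
#' type composition and summing exactly to the base group's total
#' (Hamilton apportionment; naive rounding cannot guarantee the exact
#' total). Quotas never exceed the available count: any capped surplus is
#' redistributed over the remaining types by largest remainder.
#'
#' @param counts group x type matrix of cell counts (rownames = groups)
#' @param base_group name of the base group whose total is the target
#' @return data.frame: group, cell_type, n_orig, quota
#' @export
compute_quotas <- function(counts, base_group) {
  counts <- as.matrix(counts)
  if (!base_group %in% rownames(counts))
    stop("base group ", base_group, " not found")
  totals <- rowSums(counts)
  n_base <- totals[[base_group]]
  if (any(totals < n_base))
    warning("base group is not the smallest; some quotas will be capped")
  out <- list()
  for (g in rownames(counts)) {
    orig <- counts[g, ]
    quota <- if (g == base_group) orig else
      largest_remainder(n_base * orig / totals[[g]], cap = orig)
    out[[g]] <- data.frame(group = g, cell_type = colnames(counts),
                           n_orig = as.integer(orig),
                           quota = as.integer(quota), row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Hamilton apportionment of fractional shares to integers preserving the
# total; optional per-entry capacity. Ties in remainders break by index.
largest_remainder <- function(shares, cap = NULL) {
  target <- round(sum(shares))
  q <- floor(shares)
  if (!is.null(cap)) q <- pmin(q, cap)
  left <- target - sum(q)
  rem <- shares - floor(shares)
  while (left > 0) {
    open <- if (is.null(cap)) rep(TRUE, length(q)) else q < cap
    if (!any(open)) break
    pick <- which(open)[order(-rem[open], which(open))][seq_len(min(left, sum(open)))]
    q[pick] <- q[pick] + 1L
    rem[pick] <- -Inf
    left <- target - sum(q)
  }
  q
}

#' Greedy farthest-point (max-min) sampling
#'
#' Space-filling selection: start from the point farthest from the
#' centroid, then repeatedly add the point with the largest minimum
#' Euclidean distance to the already selected set. Fully deterministic;
#' ties break by row index, so duplicated points are picked last.
#'
#' @param coords numeric point x dimension matrix
#' @param k number of points to select (<= rows)
#' @return integer vector of selected row indices, in selection order
#' @export
farthest_point_sample <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n) stop("k exceeds the number of points")
  if (k == n) return(seq_len(n))
  ctr <- colMeans(coords)
  d0 <- rowSums(sweep(coords, 2, ctr)^2)
  sel <- integer(k)
  sel[1] <- which.max(d0)              # which.max breaks ties by index
  mind <- rowSums(sweep(coords, 2, coords[sel[1], ])^2)
  for (i in seq_len(k - 1L)) {
    mind[sel[seq_len(i)]] <- -Inf
    sel[i + 1L] <- which.max(mind)
    di <- rowSums(sweep(coords, 2, coords[sel[i + 1L], ])^2)
    mind <- pmin(mind, di)
  }
  sel
}

#' Stratified down-sampling to the base group's total
#'
#' Within each (group, cell type) stratum, select the quota's worth of
#' cells either by farthest-point sampling on provided coordinates
#' (`"space_filling"`, diversity-preserving) or uniformly at random
#' (`"uniform"`). The base group is untouched.
#'
#' @param data an [sc_dataset()] with `group` and `cell_type` metadata
#' @param quotas output of [compute_quotas()]
#' @param strategy `"space_filling"` or `"uniform"`
#' @param coords cell x dim matrix (e.g. PCA scores) aligned with `data`;
#'   required for the space-filling strategy
#' @param seed RNG seed (used by the uniform strategy)
#' @return the down-sampled `sc_dataset`; kept barcodes in attribute
#'   `"kept"`
#' @export
stratified_downsample <- function(data, quotas,
                                  strategy = c("space_filling", "uniform"),
                                  coords = NULL, seed = 0L) {
  strategy <- match.arg(strategy)
  if (strategy == "space_filling" && is.null(coords))
    stop("space_filling strategy needs cell coordinates")
  if (!is.null(coords)) stopifnot(nrow(coords) == nrow(data$counts))
  set.seed(seed)
  keep <- logical(nrow(data$counts))
  for (r in seq_len(nrow(quotas))) {
    idx <- which(data$cells$group == quotas$group[r] &
                   data$cells$cell_type == quotas$cell_type[r])
    q <- quotas$quota[r]
    if (q >= length(idx)) { keep[idx] <- TRUE; next }
    if (q == 0) next
    pick <- if (strategy == "uniform") sample(length(idx), q)
      else farthest_point_sample(coords[idx, , drop = FALSE], q)
    keep[idx[pick]] <- TRUE
  }
  out <- subset_dataset(data, cells = which(keep))
  attr(out, "kept") <- data$cells$barcode[keep]
  out
}
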