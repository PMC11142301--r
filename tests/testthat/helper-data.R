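# Shared scenario builders. Sizes are kept small enough for the default
# test run; the study-scale scenario (2000 cells per condition, 1500
# genes, 12 planted modules) is used only where a check is about that
# scale.

# study-scale two-condition scenario
study_config <- function(seed, ...) {
  synth_config(groups = condition_groups(2000, 2000), seed = seed, ...)
}

# small fast scenario: 4 modules, ~600 cells per condition
small_config <- function(seed, n_cells = 600, n_genes = 400,
                         modules = default_modules(4, nonpreserved = 2L)) {
  synth_config(n_genes = n_genes, modules = modules,
               groups = condition_groups(n_cells, n_cells), seed = seed)
}

# dense cell x gene matrix of correlated blocks: each block shares one
# standard-normal factor with loading sqrt(r) (within-block correlation r)
block_expr <- function(n_cells, block_sizes, r = 0.9, n_noise = 0,
                       seed = 1) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_cells)
    cols[[b]] <- sapply(seq_len(block_sizes[b]), function(i)
      sqrt(r) * f + sqrt(1 - r) * rnorm(n_cells))
  }
  x <- do.call(cbind, c(cols, list(matrix(rnorm(n_cells * n_noise),
                                          n_cells, n_noise))))
  colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
  x
}
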