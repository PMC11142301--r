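#' Specification of one planted co-expression module
#'
#' Each planted module is driven by a per-cell latent factor `a ~ N(0,1)`
#' that multiplies the negative-binomial rate of its member genes by
#' `exp(lambda * loading * a)` in cells of the module's target types. In the
#' reference condition all loadings are 1 and the strength is `lambda_ref`.
#' For a preserved module the test condition uses the same loadings and
#' strength; for a non-preserved module the factor is either removed
#' (`mode = "drop"`, the default: `lambda_test = 0`) or rewired
#' (`mode = "rewire"`: independent per-gene standard-normal loadings).
#'
#' @param n_genes number of member genes (>= 5)
#' @param target_types character vector of target cell-type labels
#' @param lambda_ref factor strength in the reference condition (>= 0)
#' @param preserved logical; is the module preserved in the test condition?
#' @param mode non-preservation mechanism, `"drop"` or `"rewire"`
#' @param lambda_test factor strength in the test condition; defaults to
#'   `lambda_ref` when preserved, 0 when dropped, `lambda_ref` when rewired
#' @return a `planted_module` list
#' @export
planted_module <- function(n_genes, target_types, lambda_ref = 1,
                           preserved = TRUE, mode = c("drop", "rewire"),
                           lambda_test = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 5, lambda_ref >= 0)
  if (is.null(lambda_test))
    lambda_test <- if (preserved || mode == "rewire") lambda_ref else 0
  stopifnot(lambda_test >= 0)
  structure(list(n_genes = as.integer(n_genes), target_types = target_types,
                 lambda_ref = lambda_ref, lambda_test = lambda_test,
                 preserved = isTRUE(preserved), mode = mode),
            class = "planted_module")
}

#' The seven major cell-type labels used by the default configuration
#' @export
major_cell_types <- function() {
  c("TNK", "B", "plasma", "mast", "myeloid", "stroma", "epithelial")
}

default_type_props <- function() {
  c(TNK = 0.25, B = 0.10, plasma = 0.05, mast = 0.05,
    myeloid = 0.15, stroma = 0.15, epithelial = 0.25)
}

#' Default planted-module roster
#'
#' Twelve modules with sizes evenly spaced over 30-90 genes, distinct
#' target-type pairs, and (by default) two non-preserved members.
#'
#' @param n number of modules
#' @param nonpreserved indices of modules planted as non-preserved
#' @param lambda reference-condition factor strength shared by all modules
#' @param mode non-preservation mechanism, `"drop"` or `"rewire"`
#' @return list of [planted_module()] specs
#' @export
default_modules <- function(n = 12, nonpreserved = c(2L, 5L),
                            lambda = 1, mode = "drop") {
  sizes <- round(seq(30, 90, length.out = n))
  types <- major_cell_types()
  # distinct target-type pairs so no two modules share the same activity
  # pattern across types; rare types (plasma, mast) are paired with
  # abundant partners so every module is active in a workable share of
  # the cells
  pairs <- matrix(c(1, 2,   2, 3,   3, 7,   4, 1,   5, 6,   6, 7,
                    7, 1,   1, 3,   2, 5,   3, 5,   4, 6,   5, 7),
                  ncol = 2, byrow = TRUE)
  lapply(seq_len(n), function(i) {
    tt <- types[pairs[(i - 1L) %% nrow(pairs) + 1L, ]]
    planted_module(sizes[i], tt, lambda_ref = lambda,
                   preserved = !(i %in% nonpreserved), mode = mode)
  })
}

#' Two-condition group layout for simulation studies
#'
#' Convenience builder for a minimal design with one reference group and
#' one test group of given sizes, split over the seven major cell types in
#' the default proportions.
#'
#' @param n_ref,n_test total cells in the reference / test group
#' @param props named cell-type proportions (summing to 1)
#' @return a `groups` list for [synth_config()]
#' @export
condition_groups <- function(n_ref = 2000, n_test = 2000,
                             props = NULL) {
  if (is.null(props)) props <- default_type_props()
  list(list(label = "early", condition = "ref",
            cells_per_type = round(props * n_ref)),
       list(label = "late", condition = "test",
            cells_per_type = round(props * n_test)))
}

#' Configuration for the synthetic two-condition generator
#'
#' Defaults emulate a staged tumor cohort: a small early-stage base group in
#' the reference condition and three larger late-stage groups in the test
#' condition (deliberately unequal so the down-sampling stage has work to
#' do), seven major cell types in fixed proportions, lognormal library
#' sizes, a mitochondrial gene subset flagged by the "MT-" name prefix, and
#' twelve planted modules of 30-90 genes of which two are non-preserved.
#'
#' @param n_genes total number of genes
#' @param groups list of groups; each a list with `label`, `condition`
#'   ("ref" or "test") and `cells_per_type`, a named integer vector over the
#'   cell-type labels
#' @param modules list of [planted_module()] specs (gene sets are disjoint)
#' @param frac_mito fraction of genes flagged mitochondrial (< 0.5)
#' @param libsize_logmean,libsize_logsd lognormal library-size factor
#' @param nb_dispersion shared negative-binomial dispersion (size = 1/disp)
#' @param baseline_meanlog,baseline_sdlog lognormal per-gene baseline mean
#' @param type_sdlog lognormal spread of gene x type effects
#' @param factor_mean mean of the per-cell module factor scores. A
#'   positive mean elevates module genes in their target cell types (by
#'   `exp(lambda * factor_mean)` on average), so modules behave like
#'   cell-type programs; because the elevation rides on the factor it
#'   disappears together with the co-variation when a module's factor is
#'   dropped in the test condition
#' @param n_markers_per_type,marker_strength planted marker genes per type
#'   and the multiplicative boost of their effect in their own type
#' @param seed integer RNG seed; the whole generation is reproducible from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_genes = 1500,
                         groups = NULL,
                         modules = default_modules(),
                         frac_mito = 0.05,
                         libsize_logmean = 0,
                         libsize_logsd = 0.35,
                         nb_dispersion = 0.4,
                         baseline_meanlog = log(2),
                         baseline_sdlog = 1,
                         type_sdlog = 0.4,
                         factor_mean = 1,
                         n_markers_per_type = 5,
                         marker_strength = 6,
                         seed = 1L) {
  if (is.null(groups)) {
    props <- default_type_props()
    mk <- function(label, condition, total) {
      n <- round(props * total)
      list(label = label, condition = condition, cells_per_type = n)
    }
    groups <- list(mk("pT1", "ref", 500), mk("pT2", "test", 600),
                   mk("pT3", "test", 700), mk("pT4", "test", 800))
  }
  stopifnot(length(groups) >= 2, frac_mito >= 0, frac_mito < 0.5,
            nb_dispersion > 0, libsize_logsd >= 0)
  for (g in groups) {
    stopifnot(all(c("label", "condition", "cells_per_type") %in% names(g)),
              g$condition %in% c("ref", "test"),
              all(g$cells_per_type >= 0))
  }
  n_mod_genes <- sum(vapply(modules, `[[`, integer(1), "n_genes"))
  n_mito <- round(frac_mito * n_genes)
  n_mark <- n_markers_per_type * length(major_cell_types())
  if (n_mod_genes + n_mito + n_mark > n_genes)
    stop("module, mitochondrial and marker genes exceed n_genes")
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 modules = modules, frac_mito = frac_mito,
                 libsize_logmean = libsize_logmean,
                 libsize_logsd = libsize_logsd,
                 nb_dispersion = nb_dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 type_sdlog = type_sdlog,
                 factor_mean = factor_mean,
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_strength = marker_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Read / write a generator configuration as YAML
#' @param path YAML file
#' @param config a `synth_config`
#' @return `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$modules <- lapply(cfg$modules, unclass)
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$cells_per_type <- as.list(g$cells_per_type); g
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$modules <- lapply(cfg$modules, function(m)
    planted_module(m$n_genes, unlist(m$target_types), m$lambda_ref,
                   m$preserved, m$mode, m$lambda_test))
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$cells_per_type <- unlist(g$cells_per_type); g
  })
  do.call(synth_config, cfg)
}

#' Generate a synthetic two-condition dataset with ground truth
#'
#' Counts are negative binomial with mean
#' `baseline_g * type_effect[g, type(c)] * libsize_c * exp(sum_m lambda_m *
#' loading_gm * a_mc)`, where the latent factor `a_mc` is standard normal
#' per cell and module and only acts in cells of the module's target types.
#' The two conditions share baselines, type effects and marker placement and
#' differ only through each module's preservation setting.
#'
#' @param config a [synth_config()]
#' @return list with `ref` and `test` (`sc_dataset` per condition) and
#'   `truth`, a list holding the planted module map (`module`, named by
#'   gene, `"grey"` for background), per-module `preserved` flags and specs,
#'   the marker table, and the gene x type effect matrix.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  types <- major_cell_types()
  G <- config$n_genes
  n_mito <- round(config$frac_mito * G)

  gene <- sprintf("G%04d", seq_len(G))
  if (n_mito > 0) gene[seq_len(n_mito)] <- sprintf("MT-G%04d", seq_len(n_mito))

  # assign module gene blocks after the mitochondrial block
  module_of <- rep("grey", G)
  pos <- n_mito
  mod_labels <- sprintf("M%d", seq_along(config$modules))
  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    module_of[pos + seq_len(m$n_genes)] <- mod_labels[i]
    pos <- pos + m$n_genes
  }
  # marker genes drawn from the remaining background block
  marker_idx <- pos + seq_len(config$n_markers_per_type * length(types))
  markers <- data.frame(
    gene = gene[marker_idx],
    type = rep(types, each = config$n_markers_per_type))

  baseline <- exp(stats::rnorm(G, config$baseline_meanlog, config$baseline_sdlog))
  type_effect <- matrix(exp(stats::rnorm(G * length(types), 0, config$type_sdlog)),
                        G, length(types), dimnames = list(gene, types))
  for (i in seq_along(marker_idx))
    type_effect[marker_idx[i], markers$type[i]] <-
      type_effect[marker_idx[i], markers$type[i]] * config$marker_strength

  # per-condition, per-module loadings over member genes
  loadings <- lapply(seq_along(config$modules), function(i) {
    m <- config$modules[[i]]
    idx <- which(module_of == mod_labels[i])
    l_ref <- rep(1, length(idx))
    l_test <- if (m$preserved) l_ref
      else if (m$mode == "rewire") stats::rnorm(length(idx))
      else rep(1, length(idx))
    list(idx = idx, ref = l_ref, test = l_test)
  })

  gen_condition <- function(cond) {
    gs <- Filter(function(g) g$condition == cond, config$groups)
    if (length(gs) == 0) return(NULL)
    blocks <- list(); meta <- list()
    for (g in gs) {
      for (t in types) {
        if (!t %in% names(g$cells_per_type)) next
        n <- g$cells_per_type[[t]]
        if (n == 0) next
        lib <- exp(stats::rnorm(n, config$libsize_logmean, config$libsize_logsd))
        lograte <- matrix(log(baseline * type_effect[, t]), n, G, byrow = TRUE)
        for (i in seq_along(config$modules)) {
          m <- config$modules[[i]]
          if (!(t %in% m$target_types)) next
          lam <- if (cond == "ref") m$lambda_ref else m$lambda_test
          ld <- loadings[[i]]
          a <- stats::rnorm(n, mean = config$factor_mean)
          if (lam > 0)
            lograte[, ld$idx] <- lograte[, ld$idx] +
              outer(a, lam * (if (cond == "ref") ld$ref else ld$test))
        }
        mu <- exp(lograte) * lib
        cts <- matrix(stats::rnbinom(n * G, mu = mu,
                                     size = 1 / config$nb_dispersion), n, G)
        blocks[[length(blocks) + 1L]] <- cts
        meta[[length(meta) + 1L]] <- data.frame(group = g$label, cell_type = t,
                                                n = n)
      }
    }
    if (length(blocks) == 0) return(NULL)
    counts <- do.call(rbind, blocks)
    md <- do.call(rbind, meta)
    cells <- data.frame(
      barcode = sprintf("%s_%05d", cond, seq_len(nrow(counts))),
      group = rep(md$group, md$n),
      cell_type = rep(md$cell_type, md$n))
    dimnames(counts) <- list(cells$barcode, gene)
    sc_dataset(Matrix::Matrix(counts, sparse = TRUE), cells,
               data.frame(gene = gene, mito = startsWith(gene, "MT-")))
  }

  ref <- gen_condition("ref")
  test <- gen_condition("test")
  names(module_of) <- gene
  truth <- list(
    module = module_of,
    preserved = stats::setNames(
      vapply(config$modules, `[[`, logical(1), "preserved"), mod_labels),
    specs = stats::setNames(config$modules, mod_labels),
    markers = markers,
    type_effect = type_effect)
  list(ref = ref, test = test, truth = truth)
}
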