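# toy normalized matrix with two planted modules for cell-selection tests
sel_fixture <- function() {
  x <- rbind(c(5, 5, 0, 0),    # cell dominated by module A
             c(0, 0, 5, 5),    # cell dominated by module B
             c(2, 2, 2, 2))    # exactly balanced
  dimnames(x) <- list(paste0("c", 1:3), paste0("g", 1:4))
  part <- setNames(c("A", "A", "B", "B"), colnames(x))
  list(x = x, part = part)
}

test_that("module-cell selection applies a strict mean comparison", {
  f <- sel_fixture()
  expect_identical(select_module_cells(f$x, f$part, "A"), 1L)
  expect_identical(select_module_cells(f$x, f$part, "B"), 2L)
  expect_error(select_module_cells(f$x, f$part, "grey"))
  expect_error(select_module_cells(f$x, setNames(rep("A", 4), colnames(f$x)),
                                   "A"), "2 modules")
})

test_that("cells of a module's target types dominate its selection", {
  sim <- generate_dataset(small_config(91))
  norm <- log_normalize(sim$ref$counts)
  part <- sim$truth$module[sim$truth$module != "grey"]
  m <- "M3"
  tt <- sim$truth$specs[[m]]$target_types
  sel <- select_module_cells(norm, part, m)
  in_target <- sim$ref$cells$cell_type %in% tt
  a <- sum(in_target[sel]); b <- sum(!in_target[sel])
  cc <- sum(in_target[-sel]); d <- sum(!in_target[-sel])
  expect_gt((a / b) / (cc / d), 2)
})

test_that("sub-network adjacency follows the correlation over selected cells", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  x[, 2] <- 3 * x[, 1]
  a <- module_subnetwork(x, 1:60, colnames(x), power = 6)
  expect_equal(a[1, 2], 1)
  for (i in 1:5) for (j in 1:5) if (i != j)
    expect_lt(abs(a[i, j] - abs(cor_oracle(x[, i], x[, j]))^6), 1e-12)
  a2 <- module_subnetwork(x, 1:60, colnames(x), power = 12)
  off <- upper.tri(a)
  expect_true(all(a2[off] <= a[off] + 1e-15))
  expect_error(module_subnetwork(x, 1:5, colnames(x)), "at least 10")
})

test_that("top-edge extraction counts, ranks, and flags uniqueness", {
  set.seed(22)
  x <- matrix(rnorm(80 * 10), 80, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  a <- adjacency_matrix(x, 2)
  te <- top_unique_edges(a, a, 0.10)
  expect_identical(nrow(te$ref), 5L)       # ceil(0.1 * 45)
  expect_identical(sum(te$ref$unique), 0L)
  expect_identical(sum(te$test$unique), 0L)
  # force disjoint top sets with block-diagonal weights
  b1 <- diag(10); b1[1:5, 1:5] <- 0.9; diag(b1) <- 1
  b2 <- diag(10); b2[6:10, 6:10] <- 0.9; diag(b2) <- 1
  dimnames(b1) <- dimnames(b2) <- dimnames(a)
  td <- top_unique_edges(b1, b2, 0.10)
  expect_true(all(td$ref$unique))
  expect_true(all(td$test$unique))
})

test_that("connectivity Spearman matches the closed form and a library oracle", {
  expect_equal(connectivity_spearman(1:5, 1:5 * 2), 1)
  expect_equal(connectivity_spearman(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand-evaluated: ranks (1,2,3,4) vs (2,1,4,3) -> 1 - 24/60
  expect_equal(connectivity_spearman(c(10, 20, 30, 40), c(2, 1, 4, 3)), 0.6)
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    expect_lt(abs(connectivity_spearman(x, y) -
                    cor(x, y, method = "spearman")), 1e-12)
  }
  xt <- c(1, 1, 2, 3); yt <- c(4, 4, 2, 1)
  expect_lt(abs(connectivity_spearman(xt, yt) -
                  cor(rank(xt), rank(yt))), 1e-12)
  expect_warning(out <- connectivity_spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})

test_that("gene z-scores match closed-form arithmetic and antisymmetry", {
  # exact mean 1 / mean 2, sample variance 1, n = 100 each
  d <- sqrt(99 / 100)
  ref <- matrix(rep(c(1 - d, 1 + d), 50), ncol = 1,
                dimnames = list(NULL, "g"))
  test <- matrix(rep(c(2 - d, 2 + d), 50), ncol = 1,
                 dimnames = list(NULL, "g"))
  z <- gene_zscores(ref, test)
  expect_equal(unname(z), 1 / sqrt(0.02), tolerance = 1e-10)
  expect_equal(unname(gene_zscores(test, ref)), -unname(z))
  expect_equal(unname(gene_zscores(ref, ref)), 0)
  same <- matrix(rep(1, 10), ncol = 1, dimnames = list(NULL, "g"))
  diff <- matrix(rep(2, 10), ncol = 1, dimnames = list(NULL, "g"))
  expect_equal(unname(gene_zscores(same, same)), 0)
  expect_warning(zi <- gene_zscores(same, diff), "Inf")
  expect_identical(unname(zi), Inf)
})

test_that("z-score colors clamp at the ends and whiten at zero", {
  cols <- zscore_color(c(-5, -2, 0, 2, 7))
  expect_identical(cols[1], cols[2])
  expect_identical(cols[4], cols[5])
  expect_identical(cols[3], "#FFFFFF")
  expect_identical(cols[1], "#0000FF")
  expect_identical(cols[5], "#FF0000")
})

test_that("a full module comparison exports and re-imports cleanly", {
  sim <- generate_dataset(small_config(92))
  rn <- log_normalize(sim$ref$counts)
  tn <- log_normalize(sim$test$counts)
  part <- sim$truth$module[sim$truth$module != "grey"]
  cmp <- compare_module(rn, tn, part, "M4", power = 6)
  expect_s3_class(cmp, "subnetwork_comparison")
  expect_true(cmp$rho >= -1 && cmp$rho <= 1)
  ng <- sum(part == "M4")
  expect_identical(nrow(cmp$nodes), ng)
  expect_identical(nrow(cmp$edges$ref), as.integer(ceiling(0.1 * choose(ng, 2))))
  # unique sets are disjoint between conditions
  key <- function(e) paste(e$gene_i, e$gene_j)
  expect_length(intersect(key(cmp$edges$ref[cmp$edges$ref$unique, ]),
                          key(cmp$edges$test[cmp$edges$test$unique, ])), 0)
  d <- withr::local_tempdir()
  export_comparison(cmp, d)
  back <- read.delim(file.path(d, "M4_nodes.tsv"))
  expect_equal(back$k_ref, cmp$nodes$k_ref, tolerance = 1e-12)
  expect_identical(back$gene, cmp$nodes$gene)
})

test_that("over-representation analysis matches hypergeometric arithmetic", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(hit = universe[1:50], miss = universe[51:60])
  res <- ora(universe[1:50], sets, universe)
  expect_lt(res$p[res$set == "hit"], 0.01)
  expect_equal(res$p[res$set == "miss"],
               phyper(-1, 10, 90, 50, lower.tail = FALSE))
  res2 <- ora(universe[61:70], list(s = universe[1:10]), universe)
  expect_equal(res2$p, 1)
  # BH step-up oracle on the returned p-values
  m <- nrow(res)
  ord <- order(res$p)
  q_oracle <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, res$p[ord[i]] * m / i)
    q_oracle[ord[i]] <- prev
  }
  expect_equal(res$q, q_oracle)
  expect_error(ora(character(0), sets, universe), "empty")
  expect_error(ora("nope", sets, universe), "universe")
})

test_that("GMT files parse into named gene sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tanother\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_identical(names(gs), c("setA", "setB"))
  expect_identical(gs$setA, c("g1", "g2", "g3"))
  writeLines("bad\tline", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("rho separates preserved from rewired modules", {
  # drop-mode separation at study scale is covered by the acceptance
  # suite; here the rewired mechanism on a small scenario
  seps <- logical(3)
  for (s in 1:3) {
    sim <- generate_dataset(small_config(
      930 + s, modules = default_modules(4, nonpreserved = 2L,
                                         mode = "rewire")))
    rn <- log_normalize(sim$ref$counts)
    tn <- log_normalize(sim$test$counts)
    part <- sim$truth$module[sim$truth$module != "grey"]
    rho <- vapply(names(sim$truth$preserved), function(m)
      compare_module(rn, tn, part, m, power = 6)$rho, numeric(1))
    np <- !sim$truth$preserved
    seps[s] <- mean(rho[np]) < mean(rho[!np])
  }
  expect_gte(sum(seps), 2)
})
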