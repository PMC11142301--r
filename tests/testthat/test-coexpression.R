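test_that("variable-gene set modes behave on identical and disjoint inputs", {
  set.seed(9)
  x <- matrix(rpois(300 * 40, 5), 300, 40,
              dimnames = list(NULL, sprintf("g%02d", 1:40)))
  expect_identical(variable_gene_set(x, x, "intersection", 0.25),
                   variable_gene_set(x, x, "reference_only", 0.25))
  # opposite halves variable in the two matrices -> empty intersection
  a <- x; a[, 1:20] <- a[, 1:20] * rpois(300, 8)
  b <- x; b[, 21:40] <- b[, 21:40] * rpois(300, 8)
  expect_error(variable_gene_set(a, b, "intersection", 0.25,
                                 method = "raw"), "empty")
  expect_length(variable_gene_set(a, b, "reference_only", 0.25,
                                  method = "raw"), 10)
})

test_that("planted module genes survive the variable-gene intersection", {
  sim <- generate_dataset(small_config(
    61, modules = default_modules(3, nonpreserved = integer(0))))
  vg <- variable_gene_set(sim$ref$counts, sim$test$counts,
                          "intersection", 0.5)
  tm <- sim$truth$module
  planted <- names(tm)[tm != "grey"]
  expect_gt(mean(planted %in% vg), 0.8)
})

test_that("scale-free fit matches an independent least-squares oracle", {
  set.seed(10)
  k <- c(rep(1.2, 40), rep(3.4, 25), rep(5.1, 15), rep(7.7, 8), rep(9.9, 2))
  f <- scale_free_fit(k, nbreaks = 5)
  # independent oracle: histogram on 5 equal bins over the range of k
  br <- seq(min(k), max(k), length.out = 6)
  idx <- findInterval(k, br, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx == 0] <- 1
  dk <- tapply(k, idx, mean)
  p <- as.vector(table(idx)) / length(k)
  fit <- lm(log10(p) ~ log10(dk))
  expect_lt(abs(f$r2 - (-sign(coef(fit)[2]) * summary(fit)$r.squared)),
            1e-10)
  expect_lt(abs(f$slope - coef(fit)[2]), 1e-10)
  expect_error(scale_free_fit(rep(2, 10)), "degenerate")
})

test_that("hub-structured expression passes the scale-free criterion", {
  set.seed(11)
  n <- 400; G <- 200
  f <- rnorm(n)
  w <- runif(G)^3                      # few strong hubs, many weak genes
  x <- sapply(w, function(wi) sqrt(wi) * f + sqrt(1 - wi) * rnorm(n))
  colnames(x) <- sprintf("g%03d", seq_len(G))
  ps <- pick_soft_threshold(x)
  expect_gte(ps$table$r2[ps$table$power == ps$power], 0.8)
})

test_that("anti-scale-free input takes the warning path", {
  set.seed(12)
  # one big tight block plus a few stragglers: p(k) increases with k
  x <- block_expr(200, 60, r = 0.95, n_noise = 5)
  expect_warning(ps <- pick_soft_threshold(x, powers = 1:6), "best fit")
  expect_true(ps$power %in% 1:6)
})

test_that("adjacency matches powers of hand-computed correlations", {
  expect_equal(abs(0.5)^6, 0.015625)
  set.seed(13)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x[, 2] <- 2 * x[, 1]                 # perfectly correlated pair
  a <- adjacency_matrix(x, 6)
  expect_equal(a[1, 2], 1)
  for (i in 1:4) for (j in 1:4) {
    expect_lt(abs(a[i, j] - abs(cor_oracle(x[, i], x[, j]))^6), 1e-12)
  }
  s <- adjacency_matrix(x, 2, sign_mode = "signed")
  expect_lt(abs(s[1, 3] - ((1 + cor_oracle(x[, 1], x[, 3])) / 2)^2), 1e-12)
  xc <- cbind(x, g5 = rep(1, 50))
  expect_warning(ac <- adjacency_matrix(xc, 6), "constant")
  expect_true(all(ac[5, -5] == 0))
})

test_that("topological overlap matches the formula evaluated by hand", {
  a <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.5,
                0.3, 0.5, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  tom <- topological_overlap(a)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    u <- setdiff(1:3, c(i, j))
    l <- sum(a[i, u] * a[u, j])
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    expect_lt(abs(tom[i, j] - (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])),
              1e-12)
  }
  # identical columns fully connected -> maximal overlap
  b <- matrix(1, 3, 3)
  expect_equal(topological_overlap(b)[1, 2], 1)
  # no edge, no shared neighbors -> zero overlap
  d <- diag(3)
  expect_equal(topological_overlap(d)[1, 2], 0)
})

test_that("adjacency and TOM stay symmetric in [0,1] under fuzzing", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- matrix(rnorm(80 * n), 80, n,
                dimnames = list(NULL, paste0("g", seq_len(n))))
    a <- adjacency_matrix(x, sample(1:8, 1),
                          sample(c("unsigned", "signed"), 1))
    tom <- topological_overlap(a)
    expect_equal(a, t(a))
    expect_equal(tom, t(tom))
    expect_true(all(a >= 0 & a <= 1))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("connectivity sums edge weights within its scope", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  colnames(a) <- rownames(a) <- paste0("g", 1:3)
  expect_equal(unname(connectivity(a)), rep(1, 3))
  iso <- diag(4); colnames(iso) <- rownames(iso) <- paste0("g", 1:4)
  expect_equal(unname(connectivity(iso)), rep(0, 4))
  set.seed(15)
  x <- block_expr(100, c(10, 10), r = 0.7)
  adj <- adjacency_matrix(x, 2)
  part <- rep(c("A", "B"), each = 10)
  k <- connectivity(adj, part)
  for (i in seq_len(20)) {
    idx <- setdiff(which(part == part[i]), i)
    expect_lt(abs(k[i] - sum(adj[i, idx])), 1e-12)
  }
})

test_that("module eigengenes are oriented, unit summaries of their block", {
  set.seed(16)
  g <- rnorm(120)
  x <- sapply(1:5, function(i) g)      # identical genes
  colnames(x) <- paste0("g", 1:5)
  e <- module_eigengene(x, colnames(x))
  expect_gt(abs(cor(e$scores, g)), 1 - 1e-10)
  expect_gte(cor(e$scores, rowMeans(scale(x))), 0)
  expect_equal(e$var_explained, 1)
  # rank-1 + noise: variance explained close to the planted share
  share <- 0.6
  xb <- block_expr(3000, 40, r = share, seed = 17)
  eb <- module_eigengene(xb, colnames(xb))
  expected <- share + (1 - share) / 40
  expect_lt(abs(eb$var_explained - expected), 0.05)
})

test_that("module detection separates clean planted blocks", {
  x <- block_expr(300, c(40, 40), r = 0.9, seed = 18)
  tom <- topological_overlap(adjacency_matrix(x, 6))
  part <- detect_modules(tom, expr = x,
                         params = network_params(min_module_size = 20))
  truth <- rep(c("A", "B"), each = 40)
  expect_identical(length(attr(part, "sizes")), 2L)
  expect_equal(ari_oracle(unclass(part), truth), 1)
})

test_that("i.i.d. noise comes out almost entirely grey", {
  set.seed(19)
  x <- matrix(rnorm(500 * 150), 500, 150,
              dimnames = list(NULL, sprintf("g%03d", 1:150)))
  tom <- topological_overlap(adjacency_matrix(x, 6))
  part <- detect_modules(tom, expr = x)
  expect_gte(mean(part == "grey"), 0.9)
})

test_that("split halves of one block merge back into a single module", {
  # one factor drives 60 genes; whatever the cut does, eigengene merging
  # must leave them in one module
  x <- block_expr(400, 60, r = 0.9, seed = 20)
  tom <- topological_overlap(adjacency_matrix(x, 6))
  part <- detect_modules(tom, expr = x,
                         params = network_params(min_module_size = 20,
                                                 deep_split = 4))
  expect_identical(length(attr(part, "sizes")), 1L)
  expect_true(all(part == part[1]))
})

test_that("module labels are ordered by ascending size", {
  sim <- generate_dataset(small_config(71))
  norm <- as.matrix(log_normalize(sim$ref$counts))
  tom <- topological_overlap(adjacency_matrix(norm, 4))
  part <- detect_modules(tom, expr = norm,
                         params = network_params(power = 4,
                                                 label_prefix = "E"))
  s <- attr(part, "sizes")
  expect_true(all(startsWith(names(s), "E")))
  ord <- order(as.integer(sub("E", "", names(s))))
  expect_true(all(diff(s[ord]) >= 0))
})
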