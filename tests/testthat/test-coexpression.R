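block_expr <- function(n_blocks = 2, block_size = 40, n_samples = 20,
                       noise = 0, seed = 31) {
  set.seed(seed)
  z <- matrix(rnorm(n_blocks * n_samples), n_blocks)
  x <- z[rep(seq_len(n_blocks), each = block_size), ]
  if (noise > 0) x <- x + noise * matrix(rnorm(length(x)), nrow(x))
  dimnames(x) <- list(sprintf("g%03d", seq_len(nrow(x))),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

test_that("signed-hybrid adjacency zeroes negative correlations", {
  set.seed(32)
  z <- rnorm(20)
  expr <- rbind(a = z, b = -z, c = z + 0.5 * rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  a <- adjacency_signed_hybrid(expr, 2)
  expect_equal(a["a", "b"], 0)                       # cor = -1 -> 0
  expect_equal(a["a", "a"], 1)
  expect_equal(a["a", "c"], cor(z, expr["c", ])^2)   # cor^beta
  expect_true(isSymmetric(unname(a)))
  expect_true(all(a >= 0 & a <= 1))
  # a perfectly correlated pair has adjacency 1 at any power
  expr2 <- rbind(a = z, b = 2 * z + 3, c = rnorm(20))
  colnames(expr2) <- sprintf("s%02d", 1:20)
  expect_equal(adjacency_signed_hybrid(expr2, 7)["a", "b"], 1)
  # constant gene excluded with warning
  expr3 <- rbind(expr, const = rep(1, 20))
  expect_warning(a3 <- adjacency_signed_hybrid(expr3, 2), "constant")
  expect_false("const" %in% rownames(a3))
  expect_error(adjacency_signed_hybrid(expr, 0.5), "power")
})

test_that("TOM matches the hand example and the triple-loop oracle", {
  # 3 genes: a12 = 0.8, a13 = 0.4, a23 = 0 -> TOM12 = 0.8
  adj <- matrix(c(1, 0.8, 0.4,
                  0.8, 1, 0,
                  0.4, 0, 1), 3, 3)
  tom <- tom_similarity(adj)
  expect_equal(tom[1, 2], 0.8, tolerance = 1e-12)
  # no edges: off-diagonal TOM is zero
  tom_id <- tom_similarity(diag(5))
  expect_equal(tom_id, diag(5))
  # random instances against the definitional triple loop
  for (seed in 33:35) {
    set.seed(seed)
    n <- sample(10:15, 1)
    cmat <- stats::cov2cor(crossprod(matrix(rnorm(n * n * 2), 2 * n, n)))
    a <- pmax(cmat, 0)^3
    diag(a) <- 1
    expect_equal(tom_similarity(a), brute_tom(a), tolerance = 1e-10)
    t1 <- tom_similarity(a)
    expect_true(isSymmetric(unname(t1)))
    expect_true(all(t1 >= -1e-12 & t1 <= 1 + 1e-12))
  }
})

test_that("mean connectivity decreases strictly with the power", {
  expr <- block_expr(noise = 0.6, seed = 36)
  scans <- purrr::map_dfr(2:6, ~scale_free_fit(expr, .x))
  expect_true(all(diff(scans$mean_k) < 0))
})

test_that("degenerate equal-correlation networks report an undefined fit", {
  # all genes carry the same signal: every connectivity is identical
  expr <- block_expr(n_blocks = 1, block_size = 12, noise = 0, seed = 37)
  sf <- scale_free_fit(expr, 2)
  expect_true(is.na(sf$r_squared_signed))
  # an empty network errors
  set.seed(38)
  z <- rnorm(20)
  expr2 <- rbind(a = z, b = -z)
  colnames(expr2) <- sprintf("s%02d", 1:20)
  expect_error(scale_free_fit(expr2, 2), "empty network")
})

test_that("power selection follows the stated rules", {
  sim <- small_sim(seed = 39, n_genes = 300, n_modules = 3,
                   module_size_range = c(25, 40), n_de = 0)
  expr <- log_normalize(sim$counts)
  expr <- expr[apply(expr, 1, stats::sd) > 0, ]
  scan <- pick_power(expr, powers = 2:12)
  qual <- which(scan$r_squared_signed > 0.8)
  if (length(qual)) {
    # minimal mean connectivity among qualifying powers
    expect_equal(attr(scan, "selected_power"),
                 scan$power[qual[which.min(scan$mean_k[qual])]])
    expect_false(attr(scan, "flagged"))
    # conventional rule: smallest qualifying power
    scan2 <- pick_power(expr, powers = 2:12, rule = "smallest")
    expect_equal(attr(scan2, "selected_power"), min(scan$power[qual]))
  }
  # fallback: raise the cutoff beyond reach and expect the argmax, flagged
  scan3 <- pick_power(expr, powers = 2:4, r2_cutoff = 0.999)
  expect_true(attr(scan3, "flagged"))
  expect_equal(attr(scan3, "selected_power"),
               scan3$power[which.max(scan3$r_squared_signed)])
  # synthetic modular data reaches a scale-free fit above 0.8 somewhere
  expect_gt(max(scan$r_squared_signed, na.rm = TRUE), 0.8)
})

test_that("two perfect blocks are recovered exactly by both cut methods", {
  expr <- block_expr(n_blocks = 2, block_size = 40, noise = 0.1, seed = 40)
  adj <- adjacency_signed_hybrid(expr, 6)
  tom <- tom_similarity(adj)
  for (method in c("static", "dynamic_tree")) {
    lab <- detect_modules(tom, min_module_size = 30, method = method)
    expect_equal(sort(unique(lab)), c(1L, 2L))
    expect_length(unique(lab[1:40]), 1L)
    expect_length(unique(lab[41:80]), 1L)
    expect_false(lab[1] == lab[41])
  }
  # an absurd minimum size labels everything background
  expect_true(all(detect_modules(tom, min_module_size = 1e6) == 0L))
})

test_that("module labels are invariant to gene input order up to renaming", {
  skip_if_not_installed("mclust")
  expr <- block_expr(n_blocks = 3, block_size = 35, noise = 0.5, seed = 41)
  adj <- adjacency_signed_hybrid(expr, 6)
  tom <- tom_similarity(adj)
  lab <- detect_modules(tom)
  perm <- sample(nrow(tom))
  lab_p <- detect_modules(tom[perm, perm])
  expect_equal(mclust::adjustedRandIndex(lab, lab_p[names(lab)]), 1)
})

test_that("eigengenes match a brute-force eigendecomposition oracle", {
  set.seed(42)
  expr <- block_expr(n_blocks = 2, block_size = 20, noise = 0.7, seed = 42)
  labels <- stats::setNames(rep(1:2, each = 20), rownames(expr))
  eg <- eigengenes(expr, labels)
  expect_equal(dim(eg$me), c(20L, 2L))
  expect_equal(apply(eg$me, 2, stats::sd), c(M1 = 1, M2 = 1), tolerance = 1e-12)
  # oracle: leading eigenvector of the sample covariance of standardized genes
  for (m in 1:2) {
    xs <- t(scale(t(expr[labels == m, ])))
    ev <- eigen(crossprod(xs))
    v <- ev$vectors[, 1]
    v <- v / stats::sd(v)
    if (mean(stats::cor(t(expr[labels == m, ]), v)) < 0) v <- -v
    expect_equal(unname(eg$me[, m]), unname(v), tolerance = 1e-8)
    expect_equal(unname(eg$var_explained[m]),
                 ev$values[1] / sum(ev$values), tolerance = 1e-8)
  }
  # orientation: mean correlation with member genes is positive
  expect_gt(mean(stats::cor(t(expr[labels == 1, ]), eg$me[, 1])), 0)
})

test_that("degenerate modules have the stated eigengene properties", {
  set.seed(43)
  z <- rnorm(12)
  expr <- rbind(solo = z, twin1 = 2 * z + 1, twin2 = 2 * z + 1)
  colnames(expr) <- sprintf("s%02d", 1:12)
  labels <- stats::setNames(c(1L, 2L, 2L), rownames(expr))
  eg <- eigengenes(expr, labels)
  # single-gene module: eigengene is the gene's standardized expression
  expect_equal(unname(eg$me[, "M1"]), unname(scale(z)[, 1]), tolerance = 1e-10)
  # identical genes: eigengene explains all variance
  expect_equal(unname(eg$var_explained["M2"]), 1, tolerance = 1e-12)
})

test_that("module membership is the gene-eigengene correlation", {
  expr <- block_expr(n_blocks = 2, block_size = 15, noise = 0.6, seed = 44)
  labels <- stats::setNames(rep(1:2, each = 15), rownames(expr))
  eg <- eigengenes(expr, labels)
  kme <- module_membership(expr, eg$me)
  expect_equal(unname(kme), unname(stats::cor(t(expr), eg$me)),
               tolerance = 1e-12)
  expect_true(all(abs(kme) <= 1 + 1e-12))
  # a gene equal to minus the eigengene has kME -1
  expr2 <- rbind(expr, anti = -eg$me[, 1])
  kme2 <- module_membership(expr2, eg$me)
  expect_equal(unname(kme2["anti", "M1"]), -1, tolerance = 1e-10)
  # single-gene module: own-module kME is 1
  labels3 <- stats::setNames(c(1L, rep(0L, nrow(expr) - 1)), rownames(expr))
  eg3 <- eigengenes(expr, labels3)
  expect_equal(unname(module_membership(expr, eg3$me)[1, "M1"]), 1,
               tolerance = 1e-10)
})

test_that("eigengene group regression equals the pooled two-sample t", {
  set.seed(45)
  me <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20),
                                                 c("M1", "M2")))
  group <- rep(c("Control", "Stressed"), each = 10)
  reg <- me_group_regression(me, group)
  for (i in 1:2) {
    tt <- stats::t.test(me[11:20, i], me[1:10, i], var.equal = TRUE)
    expect_equal(reg$b[i], mean(me[11:20, i]) - mean(me[1:10, i]),
                 tolerance = 1e-12)
    expect_equal(reg$b[i] / reg$se[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(reg$p[i], tt$p.value, tolerance = 1e-10)
  }
  # identical eigengene across groups: coefficient 0
  me0 <- cbind(M1 = rep(c(1, 2), 10))
  rownames(me0) <- sprintf("s%02d", 1:20)
  expect_equal(me_group_regression(me0, rep(c("a", "b"), each = 10))$b, 0,
               tolerance = 1e-12)
})

test_that("hub genes are ranked by absolute membership with stable ties", {
  kme <- matrix(c(0.9, -0.95, 0.5, 0.5, 0.2), 5, 1,
                dimnames = list(c("gB", "gA", "gD", "gC", "gE"), "M1"))
  labels <- stats::setNames(c(1L, 1L, 1L, 1L, 1L), rownames(kme))
  hubs <- hub_genes(kme, labels, top_n = 5)
  expect_identical(hubs$gene, c("gA", "gB", "gC", "gD", "gE"))
  expect_identical(hubs$rank, 1:5)
  # top_n larger than the module returns all members
  labels_small <- stats::setNames(c(1L, 1L, 1L, 0L, 0L), rownames(kme))
  hubs3 <- hub_genes(kme, labels_small, top_n = 5)
  expect_equal(nrow(hubs3), 3L)
  # brute-force sort oracle on random data
  set.seed(46)
  kme2 <- matrix(runif(30, -1, 1), 30, 1,
                 dimnames = list(sprintf("g%02d", 1:30), "M1"))
  labels2 <- stats::setNames(rep(1L, 30), rownames(kme2))
  hubs2 <- hub_genes(kme2, labels2, top_n = 4)
  ord <- rownames(kme2)[order(-abs(kme2[, 1]), rownames(kme2))]
  expect_identical(hubs2$gene, ord[1:4])
  # a gene constructed to equal the eigengene ranks first
  expr <- block_expr(n_blocks = 1, block_size = 10, noise = 0.8, seed = 47)
  labels4 <- stats::setNames(rep(1L, 10), rownames(expr))
  eg <- eigengenes(expr, labels4)
  expr_sp <- rbind(expr, spike = eg$me[, 1])
  labels5 <- stats::setNames(rep(1L, 11), rownames(expr_sp))
  kme5 <- module_membership(expr_sp, eigengenes(expr_sp, labels5)$me)
  expect_identical(hub_genes(kme5, labels5, top_n = 1)$gene, "spike")
})
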