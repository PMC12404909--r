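sim_norm <- function(seed = 21, n_genes = 300, n_de = 0) {
  sim <- simulate_experiment(sim_params(n_genes = n_genes, n_de = n_de,
                                        n_modules = 0, seed = seed))
  list(norm = voom_transform(filter_min_count(sim$counts), sim$samples$group),
       sim = sim)
}

test_that("weighted fits reduce to group mean differences and match brute force", {
  s <- sim_norm()
  norm <- s$norm
  # equal weights: coefficient is the difference of group means
  norm_eq <- norm
  norm_eq$weights[] <- 1
  fit <- fit_gene_models(norm_eq)
  g2 <- s$sim$samples$group == "Stressed"
  expect_equal(fit$log2fc,
               rowMeans(norm$logcpm[, g2]) - rowMeans(norm$logcpm[, !g2]),
               ignore_attr = TRUE)
  expect_equal(fit$df_residual, rep.int(18L, nrow(fit)))

  # exact two-level gene has zero residual variance and unit coefficient
  norm2 <- norm_eq
  norm2$logcpm[1, ] <- as.numeric(g2)
  fit2 <- fit_gene_models(norm2)
  expect_equal(fit2$log2fc[1], 1)
  expect_equal(fit2$sigma2[1], 0, tolerance = 1e-12)

  # arbitrary positive weights match the normal-equations oracle
  fitw <- fit_gene_models(norm)
  for (g in c(3, 57, 140)) {
    o <- brute_wls(norm$logcpm[g, ], as.numeric(g2), norm$weights[g, ])
    expect_equal(fitw$log2fc[g], o$beta, tolerance = 1e-10)
    expect_equal(fitw$stdev_unscaled[g], o$stdev_unscaled, tolerance = 1e-10)
    expect_equal(fitw$sigma2[g], o$sigma2, tolerance = 1e-10)
  }
})

test_that("moderation matches the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  s <- sim_norm(seed = 22, n_genes = 500)
  fit <- fit_gene_models(s$norm)
  mod <- ebayes_moderate(fit)
  design <- stats::model.matrix(~s$sim$samples$group)
  ref <- limma::lmFit(s$norm$logcpm, design, weights = s$norm$weights)
  ref <- limma::eBayes(ref)
  expect_equal(attr(mod, "d0"), ref$df.prior, tolerance = 1e-6)
  expect_equal(attr(mod, "s02"), ref$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$p, unname(ref$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t equals ordinary t in both prior-df limits", {
  s <- sim_norm(seed = 23)
  fit <- fit_gene_models(s$norm)
  ordinary_t <- fit$log2fc / (fit$stdev_unscaled * sqrt(fit$sigma2))
  # d0 = 0: no moderation
  mod0 <- ebayes_moderate(fit, d0 = 0)
  expect_equal(mod0$t, ordinary_t, tolerance = 1e-10)
  # d0 = Inf: ordinary t with the common prior variance
  modInf <- ebayes_moderate(fit, d0 = Inf)
  s0 <- mean(fit$sigma2[fit$sigma2 > 0])
  expect_equal(modInf$t, fit$log2fc / (fit$stdev_unscaled * sqrt(s0)),
               tolerance = 1e-10)
  # identical variances route to the d0 = Inf branch rather than an error
  fit_const <- fit
  fit_const$sigma2 <- rep(0.5, nrow(fit))
  mod_const <- ebayes_moderate(fit_const)
  expect_identical(attr(mod_const, "d0"), Inf)
  expect_equal(mod_const$t,
               fit_const$log2fc / (fit_const$stdev_unscaled * sqrt(0.5)),
               tolerance = 1e-10)
})

test_that("trigamma inversion recovers generating variance parameters", {
  expect_equal(trigamma_inverse(trigamma(c(0.5, 3, 42))), c(0.5, 3, 42),
               tolerance = 1e-6)
  # scaled chi-square variances: moment matching recovers (d0, s02)
  set.seed(24)
  d0_true <- 8; s02_true <- 0.3; dg <- 18
  n <- 10000
  # marginal model: s^2 ~ s0^2 F(dg, d0)
  s2 <- s02_true * stats::rf(n, dg, d0_true)
  fit <- tibble::tibble(gene = as.character(1:n), log2fc = 0,
                        stdev_unscaled = 1, sigma2 = s2,
                        df_residual = rep(dg, n))
  mod <- ebayes_moderate(fit)
  expect_equal(attr(mod, "d0"), d0_true, tolerance = 0.15)
  expect_equal(attr(mod, "s02"), s02_true, tolerance = 0.05)
})

test_that("eFDR reproduces the hand-computed toy example", {
  observed <- c(0.01, 0.04, 0.50)
  null <- structure(
    list(p_sorted = sort(c(0.30, 0.60, 0.90, 0.02, 0.70, 0.95)),
         n_perm = 2, n_genes = 3, seed = 1),
    class = "permutation_null"
  )
  # raw ratios (0/1, 0.5/2, 1/3); already monotone in p
  expect_equal(compute_efdr(observed, null), c(0, 0.25, 1 / 3),
               tolerance = 1e-12)
  # smallest observed p with no smaller null p has eFDR 0
  expect_equal(compute_efdr(observed, null)[1], 0)
  # all-equal observed p values share one eFDR
  expect_length(unique(compute_efdr(rep(0.2, 5), null)), 1L)
  expect_error(compute_efdr(c(0.5, 1.2), null), "\\[0, 1\\]")
})

test_that("eFDR is in [0,1], monotone in p, and gene-order invariant", {
  set.seed(25)
  s <- sim_norm(seed = 25, n_genes = 200)
  null <- permutation_null(s$norm, n_perm = 30, seed = 7)
  p <- stats::runif(200)
  e <- compute_efdr(p, null)
  expect_true(all(e >= 0 & e <= 1))
  ord <- order(p)
  expect_true(all(diff(e[ord]) >= -1e-12))
  perm <- sample(200)
  expect_equal(compute_efdr(p[perm], null), e[perm])
})

test_that("permutation null is seed-deterministic and the identity permutation recovers observed p", {
  s <- sim_norm(seed = 26, n_genes = 150)
  n1 <- permutation_null(s$norm, n_perm = 20, seed = 3)
  n2 <- permutation_null(s$norm, n_perm = 20, seed = 3)
  expect_identical(n1, n2)
  n3 <- permutation_null(s$norm, n_perm = 20, seed = 4)
  expect_false(identical(n1$p_sorted, n3$p_sorted))
  # identity permutation: null p equals observed p
  ident <- permutation_null(s$norm,
                            permutations = list(factor(s$sim$samples$group)))
  mod <- ebayes_moderate(fit_gene_models(s$norm))
  expect_equal(sort(mod$p), ident$p_sorted, tolerance = 1e-12)
})

test_that("pooled null p-values are approximately uniform under the global null", {
  s <- sim_norm(seed = 27, n_genes = 400)
  null <- permutation_null(s$norm, n_perm = 25, seed = 5)
  ks <- stats::ks.test(null$p_sorted, "punif")$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("DEG calls follow the fold-change and eFDR thresholds", {
  de <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    log2fc = c(0.1, -0.3, 0.5, 0.25),
    efdr = c(0.001, 0.04, 0.2, 0.01)
  )
  out <- call_degs(de)
  expect_identical(out$call, c("ns", "down", "ns", "up"))
  expect_identical(attr(out, "n_up") + attr(out, "n_down") +
                     sum(out$call == "ns"), nrow(out))
  # exact threshold: log2fc = 0.2 counts as a call
  expect_identical(call_degs(tibble::tibble(gene = "x", log2fc = 0.2,
                                            efdr = 0.01))$call, "up")
  expect_error(call_degs(de, lfc_threshold = -1), "positive")
})

test_that("planted DE calls agree with a brute-force threshold application", {
  sim <- simulate_experiment(sim_params(n_genes = 500, n_de = 60, lfc_de = 1,
                                        n_modules = 0, seed = 28))
  norm <- voom_transform(filter_min_count(sim$counts), sim$samples$group)
  de <- run_de(norm, n_perm = 60, seed = 29)
  manual <- ifelse(de$efdr < 0.05 & de$log2fc >= 0.2, "up",
                   ifelse(de$efdr < 0.05 & de$log2fc <= -0.2, "down", "ns"))
  expect_identical(de$call, manual)
  expect_lte(attr(de, "n_up") + attr(de, "n_down"), attr(de, "n_tested"))
})

test_that("cross-region tables classify overlap and incongruence", {
  mk <- function(genes, calls) {
    tibble::tibble(gene = genes, log2fc = 0, efdr = 0,
                   call = calls)
  }
  res <- list(
    LH = mk(c("Zfp36", "Apcdd1", "Tchh", "Fos", "only_lh", "Pdyn"),
            c("up", "up", "up", "down", "up", "up")),
    DMH = mk(c("Zfp36", "Apcdd1", "Tchh", "Desi1", "Pdyn"),
             c("up", "up", "down", "up", "down")),
    ARC = mk(c("Zfp36", "Tchh", "Fos", "Desi1"),
             c("up", "up", "down", "ns"))
  )
  tabs <- cross_region_tables(res)
  # the triple-region pattern appears once, with regions in input order
  z <- tabs$overlap[tabs$overlap$gene == "Zfp36", ]
  expect_equal(nrow(z), 1L)
  expect_identical(z$direction, "Up")
  expect_identical(z$regions, "LH, DMH, ARC")
  # up in two regions, down in the third: overlap and incongruence rows
  tchh_o <- tabs$overlap[tabs$overlap$gene == "Tchh", ]
  expect_identical(tchh_o$regions, "LH, ARC")
  tchh_i <- tabs$incongruence[tabs$incongruence$gene == "Tchh", ]
  expect_identical(tchh_i$regions_up, "LH, ARC")
  expect_identical(tchh_i$regions_down, "DMH")
  # down in two regions: a Down overlap row
  fos <- tabs$overlap[tabs$overlap$gene == "Fos", ]
  expect_identical(fos$direction, "Down")
  expect_identical(fos$regions, "LH, ARC")
  # up in one region and down in another: incongruence only
  expect_false("Pdyn" %in% tabs$overlap$gene)
  expect_true("Pdyn" %in% tabs$incongruence$gene)
  # a single-region DEG appears nowhere
  expect_false("only_lh" %in% c(tabs$overlap$gene, tabs$incongruence$gene))
  # disjoint DEG sets give empty tables
  disj <- list(LH = mk("a", "up"), DMH = mk("b", "down"))
  tabs2 <- cross_region_tables(disj)
  expect_equal(nrow(tabs2$overlap), 0L)
  expect_equal(nrow(tabs2$incongruence), 0L)
})
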