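#' Per-gene weighted least-squares fits for a two-group design
#'
#' Fits, for every gene, a weighted linear model of log-CPM on an intercept
#' plus group indicator using the voom precision weights. The group
#' coefficient is the log2 fold change (second factor level minus first,
#' i.e. Stressed - Control with default level order).
#'
#' @param norm A `normalized_counts` object from [voom_transform()].
#' @param group Optional two-level factor overriding `norm$group`.
#' @return A tibble of class `gene_fit` with columns `gene`, `log2fc`,
#'   `stdev_unscaled`, `sigma2` (residual variance), `df_residual`.
#' @export
fit_gene_models <- function(norm, group = NULL) {
  group <- as.factor(if (is.null(group)) norm$group else group)
  if (nlevels(droplevels(group)) != 2 || any(table(droplevels(group)) < 2)) {
    stop("design must have two groups with at least 2 samples each", call. = FALSE)
  }
  if (any(norm$weights <= 0)) stop("weights must be positive", call. = FALSE)
  g2 <- group == levels(droplevels(group))[2]
  f <- .wls_two_group(norm$logcpm, norm$weights, g2)
  tibble::new_tibble(
    tibble::tibble(
      gene = rownames(norm$logcpm),
      log2fc = f$beta,
      stdev_unscaled = f$stdev_unscaled,
      sigma2 = f$sigma2,
      df_residual = f$df
    ),
    class = "gene_fit"
  )
}

# vectorized weighted LS for intercept + indicator: fitted values are the
# weighted group means, so the whole matrix solves in a few rowSums.
.wls_two_group <- function(y, w, g2) {
  sw1 <- rowSums(w[, !g2, drop = FALSE])
  sw2 <- rowSums(w[, g2, drop = FALSE])
  m1 <- rowSums((w * y)[, !g2, drop = FALSE]) / sw1
  m2 <- rowSums((w * y)[, g2, drop = FALSE]) / sw2
  rss <- rowSums(w * y * y) - sw1 * m1^2 - sw2 * m2^2
  df <- ncol(y) - 2L
  list(
    beta = unname(m2 - m1),
    stdev_unscaled = unname(sqrt(1 / sw1 + 1 / sw2)),
    sigma2 = unname(pmax(rss, 0) / df),
    df = rep.int(df, nrow(y))
  )
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x` for `y > 0`; used to
#' moment-match the prior degrees of freedom of the variance model.
#'
#' @param x Positive numeric vector.
#' @return Numeric vector `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

# moment-match log s^2 to a scaled F / log-chi-square model.
# Returns list(d0, s02).
.fit_variance_prior <- function(sigma2, df) {
  ok <- sigma2 > 0
  if (sum(ok) < 2) stop("need at least 2 genes with positive residual variance",
                        call. = FALSE)
  e <- log(sigma2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(sigma2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment-matching the log residual variances (trigamma inversion), shrinks
#' each gene's variance to the posterior
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and returns moderated t statistics
#' with two-sided p-values on `d0 + d_g` degrees of freedom (`d0 = Inf`
#' gives a normal reference).
#'
#' @param fit A `gene_fit` tibble from [fit_gene_models()].
#' @param d0 Optional override of the prior df: `0` disables moderation
#'   (ordinary t), `Inf` forces complete shrinkage to the common variance.
#' @return A tibble of class `moderated_fit` with columns `gene`, `log2fc`,
#'   `t`, `p`, `sigma2_post`, `df_total`, and attributes `d0`, `s02`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL) {
  s2 <- fit$sigma2
  dg <- fit$df_residual
  if (is.null(d0)) {
    if (sum(s2 > 0) < 10) {
      stop("need at least 10 genes with positive residual variance to moderate",
           call. = FALSE)
    }
    prior <- .fit_variance_prior(s2, dg)
  } else if (identical(d0, 0) || identical(d0, 0L)) {
    prior <- list(d0 = 0, s02 = NA_real_)
  } else if (is.infinite(d0)) {
    prior <- list(d0 = Inf, s02 = mean(s2[s2 > 0]))
  } else {
    prior <- list(d0 = d0, s02 = .fit_variance_prior(s2, dg)$s02)
  }
  s2_post <- if (prior$d0 == 0) {
    s2
  } else if (is.infinite(prior$d0)) {
    rep.int(prior$s02, length(s2))
  } else {
    (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  }
  tval <- fit$log2fc / (fit$stdev_unscaled * sqrt(s2_post))
  df_total <- dg + prior$d0
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  out <- tibble::new_tibble(
    tibble::tibble(
      gene = fit$gene,
      log2fc = fit$log2fc,
      t = tval,
      p = p,
      sigma2_post = s2_post,
      df_total = df_total
    ),
    class = "moderated_fit"
  )
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

# one permutation pass: weighted fit + moderation -> p-values
.perm_pvalues <- function(y, w, g2) {
  f <- .wls_two_group(y, w, g2)
  prior <- .fit_variance_prior(f$sigma2, f$df)
  s2_post <- if (is.infinite(prior$d0)) {
    rep.int(prior$s02, length(f$sigma2))
  } else {
    (prior$d0 * prior$s02 + f$df * f$sigma2) / (prior$d0 + f$df)
  }
  tval <- f$beta / (f$stdev_unscaled * sqrt(s2_post))
  2 * stats::pt(-abs(tval), df = f$df + prior$d0)
}

#' Permutation null distribution of p-values
#'
#' Shuffles the group labels uniformly at random over samples (`n_perm`
#' times, with replacement over labelings; the identity labeling is not
#' excluded), re-runs the weighted fit and empirical-Bayes moderation on
#' each shuffle, and pools the resulting p-values into a sorted null store.
#'
#' @param norm A `normalized_counts` object.
#' @param n_perm Number of permutations (the study design used 5000).
#' @param seed Integer seed making the shuffles reproducible.
#' @param group Optional two-level factor overriding `norm$group`.
#' @param permutations Optional list of explicit label vectors (each a
#'   permutation of `group`), overriding random shuffling — useful for
#'   forcing the identity permutation.
#' @return An object of class `permutation_null`: list with
#'   `p_sorted` (pooled sorted null p-values), `n_perm`, `n_genes`, `seed`.
#' @export
permutation_null <- function(norm, n_perm = 5000, seed = 1L, group = NULL,
                             permutations = NULL) {
  group <- as.factor(if (is.null(group)) norm$group else group)
  lev2 <- levels(droplevels(group))[2]
  y <- norm$logcpm
  w <- norm$weights
  if (!is.null(permutations)) {
    n_perm <- length(permutations)
  } else {
    if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
    set.seed(seed)
  }
  pooled <- numeric(nrow(y) * n_perm)
  for (b in seq_len(n_perm)) {
    labels <- if (is.null(permutations)) sample(group) else permutations[[b]]
    pooled[((b - 1) * nrow(y) + 1):(b * nrow(y))] <-
      .perm_pvalues(y, w, labels == lev2)
  }
  structure(
    list(p_sorted = sort(pooled), n_perm = n_perm, n_genes = nrow(y),
         seed = seed),
    class = "permutation_null"
  )
}

#' @param x A `permutation_null` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @rdname permutation_null
#' @method print permutation_null
#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null:", x$n_perm, "permutations x", x$n_genes, "genes\n")
  invisible(x)
}

#' Per-gene empirical false discovery rate
#'
#' For each gene, the eFDR is the expected number of null p-values at or
#' below the gene's observed p (averaged over permutations) divided by the
#' observed number of genes at or below that p, capped at 1 and made
#' monotone non-decreasing in the observed p by a running minimum taken
#' from the largest observed p downward (q-value convention).
#'
#' @param observed_p Numeric vector of per-gene p-values.
#' @param null A `permutation_null` object.
#' @return Numeric vector of eFDR values in `[0, 1]`, same order as
#'   `observed_p`.
#' @export
compute_efdr <- function(observed_p, null) {
  if (any(!is.finite(observed_p) | observed_p < 0 | observed_p > 1)) {
    stop("observed p-values must lie in [0, 1]", call. = FALSE)
  }
  if (!length(null$p_sorted)) stop("permutation null is empty", call. = FALSE)
  n_null_le <- findInterval(observed_p, null$p_sorted)
  n_obs_le <- rank(observed_p, ties.method = "max")
  raw <- pmin(1, (n_null_le / null$n_perm) / pmax(1, n_obs_le))
  ord <- order(observed_p, decreasing = TRUE)
  raw[ord] <- cummin(raw[ord])
  raw
}

#' Call differentially expressed genes
#'
#' A gene is `up` when `log2fc >= lfc_threshold` and `efdr < efdr_threshold`,
#' `down` symmetrically, `ns` otherwise.
#'
#' @param de Tibble with at least `gene`, `log2fc` and `efdr` columns.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.2,
#'   i.e. a ~15% difference).
#' @param efdr_threshold eFDR threshold (default 0.05).
#' @return The tibble with a `call` column added, class `deg_results`, and
#'   attributes `n_up`, `n_down`, `n_tested`, `lfc_threshold`,
#'   `efdr_threshold`.
#' @export
call_degs <- function(de, lfc_threshold = 0.2, efdr_threshold = 0.05) {
  if (lfc_threshold <= 0 || efdr_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  de <- tibble::as_tibble(de)
  de$call <- dplyr::case_when(
    de$efdr < efdr_threshold & de$log2fc >= lfc_threshold ~ "up",
    de$efdr < efdr_threshold & de$log2fc <= -lfc_threshold ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble::new_tibble(de, class = "deg_results")
  attr(out, "n_up") <- sum(de$call == "up")
  attr(out, "n_down") <- sum(de$call == "down")
  attr(out, "n_tested") <- nrow(de)
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "efdr_threshold") <- efdr_threshold
  out
}

#' Differential expression with permutation eFDR, end to end
#'
#' Convenience wrapper: weighted per-gene fits, empirical-Bayes moderation,
#' permutation null, per-gene eFDR, and DEG calls.
#'
#' @inheritParams permutation_null
#' @inheritParams call_degs
#' @return A `deg_results` tibble with columns `gene`, `log2fc`, `t`, `p`,
#'   `efdr`, `call` and the attributes of [call_degs()] plus `d0`, `s02`,
#'   `n_perm`, `seed`.
#' @export
run_de <- function(norm, n_perm = 5000, seed = 1L, group = NULL,
                   lfc_threshold = 0.2, efdr_threshold = 0.05) {
  fit <- fit_gene_models(norm, group)
  mod <- ebayes_moderate(fit)
  null <- permutation_null(norm, n_perm = n_perm, seed = seed, group = group)
  efdr <- compute_efdr(mod$p, null)
  de <- tibble::tibble(gene = mod$gene, log2fc = mod$log2fc, t = mod$t,
                       p = mod$p, efdr = efdr)
  out <- call_degs(de, lfc_threshold, efdr_threshold)
  attr(out, "d0") <- attr(mod, "d0")
  attr(out, "s02") <- attr(mod, "s02")
  attr(out, "n_perm") <- null$n_perm
  attr(out, "seed") <- seed
  out
}

#' Cross-region DEG overlap and incongruence tables
#'
#' Overlap: genes with the same non-`ns` call in at least two regions, with
#' the direction and the region list. Incongruence: genes called `up` in at
#' least one region and `down` in at least one other, with the regions
#' listed per direction. Region names keep the order of the input list.
#'
#' @param results Named list (region -> `deg_results` tibble).
#' @return List with tibbles `overlap` (`gene`, `direction`, `regions`) and
#'   `incongruence` (`gene`, `regions_up`, `regions_down`).
#' @export
cross_region_tables <- function(results) {
  if (length(results) < 2 || is.null(names(results))) {
    stop("need a named list of at least 2 regions", call. = FALSE)
  }
  regions <- names(results)
  calls <- purrr::imap_dfr(results, function(de, region) {
    tibble::tibble(region = region, gene = de$gene, call = de$call)
  })
  calls <- dplyr::filter(calls, .data$call != "ns")
  calls$region <- factor(calls$region, levels = regions)

  summ <- dplyr::summarise(
    dplyr::group_by(calls, .data$gene),
    up = list(as.character(sort(.data$region[.data$call == "up"]))),
    down = list(as.character(sort(.data$region[.data$call == "down"]))),
    .groups = "drop"
  )
  join <- function(x) purrr::map_chr(x, paste, collapse = ", ")
  overlap <- dplyr::bind_rows(
    tibble::tibble(gene = summ$gene[lengths(summ$up) >= 2], direction = "Up",
                   regions = join(summ$up[lengths(summ$up) >= 2])),
    tibble::tibble(gene = summ$gene[lengths(summ$down) >= 2], direction = "Down",
                   regions = join(summ$down[lengths(summ$down) >= 2]))
  )
  overlap <- dplyr::arrange(overlap, dplyr::desc(.data$direction), .data$gene)

  both <- lengths(summ$up) >= 1 & lengths(summ$down) >= 1
  incong <- tibble::tibble(
    gene = summ$gene[both],
    regions_up = join(summ$up[both]),
    regions_down = join(summ$down[both])
  )
  incong <- dplyr::arrange(incong, .data$gene)
  list(overlap = overlap, incongruence = incong)
}
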