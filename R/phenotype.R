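#' Group summary for a Welch test
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (>= 2).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  structure(list(label = label, mean = mean, sd = sd, n = n),
            class = "group_summary")
}

#' Welch's t-test with Cohen's d from group summaries
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom;
#' the statistics are signed as group 2 minus group 1 (report the Stressed
#' group second to match the Stressed - Control convention). Cohen's d uses
#' the average-variance pooled denominator `sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `label`, `mean`,
#'   `sd`, `n`).
#' @return An object of class `welch_htest`: list with `t`, `df`, `p`, `d`,
#'   `estimate` (mean difference), and the two summaries.
#' @export
#' @examples
#' welch_test(group_summary("Control", 48.89, 7.08, 10),
#'            group_summary("Stressed", 59.38, 7.01, 10))
welch_test <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  diff <- g2$mean - g1$mean
  if (v1 + v2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- g1$n + g2$n - 2
  } else {
    t <- diff / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  pooled <- sqrt((g1$sd^2 + g2$sd^2) / 2)
  d <- if (pooled == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / pooled
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(
    list(t = t, df = df, p = p, d = d, estimate = diff, g1 = g1, g2 = g2),
    class = "welch_htest"
  )
}

#' Welch's t-test with Cohen's d from raw vectors
#'
#' Reduces exactly to [welch_test()] applied to the vectors' summaries.
#'
#' @param x,y Numeric vectors (length >= 2 each); statistics are signed as
#'   `y` minus `x`.
#' @param labels Optional length-2 character vector of group labels.
#' @return A `welch_htest` object.
#' @export
welch_test_raw <- function(x, y, labels = c("group1", "group2")) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  welch_test(
    group_summary(labels[1], mean(x), stats::sd(x), length(x)),
    group_summary(labels[2], mean(y), stats::sd(y), length(y))
  )
}

#' @param x A `welch_htest` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @rdname welch_test
#' @method print welch_htest
#' @export
print.welch_htest <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test (%s vs %s)\n", x$g2$label, x$g1$label))
  cat(sprintf("t(%.2f) = %.2f, p = %.4g, d = %.2f\n", x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Holm step-down adjustment with an explicit family size
#'
#' Orders raw p-values ascending and sets
#' `p_holm(i) = max_{j <= i} min(1, (m - j + 1) p_raw(j))` where `m` is the
#' family size, which may exceed the number of p-values supplied (for
#' screens where only part of the family is materialized).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size `m` cannot be smaller than length(p)",
                          call. = FALSE)
  ord <- order(p)
  adj <- pmin(1, (m - seq_along(ord) + 1) * p[ord])
  adj <- cummax(adj)
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Spearman correlations with Holm correction
#'
#' Correlates each gene's expression with each behaviour across the shared
#' samples: `r` is the Pearson correlation of mid-ranks (average ranks for
#' ties) and the raw p comes from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df. Holm adjustment uses
#' family size `m` (default: number of tests in the table).
#'
#' @param expr Gene x sample numeric matrix (e.g. log-CPM of the top DEGs).
#' @param behaviors Behaviour x sample numeric matrix (row names are
#'   behaviour names), or a tibble with a `sample_id` column and one column
#'   per behaviour.
#' @param family_size Holm family size `m`; `NULL` uses the number of
#'   gene-behaviour pairs tested.
#' @return A tibble with `gene`, `behavior`, `n`, `r`, `p_raw`, `p_holm`.
#'   Pairs with a constant vector have `NA` statistics and are excluded
#'   from the family.
#' @export
spearman_holm <- function(expr, behaviors, family_size = NULL) {
  if (is.data.frame(behaviors)) {
    ids <- behaviors$sample_id
    behaviors <- t(as.matrix(behaviors[, setdiff(names(behaviors),
                                                 c("sample_id", "group")),
                                       drop = FALSE]))
    colnames(behaviors) <- ids
  }
  shared <- intersect(colnames(expr), colnames(behaviors))
  if (length(shared) < 3) stop("need at least 3 shared samples", call. = FALSE)
  grid <- tidyr::expand_grid(gene = rownames(expr),
                             behavior = rownames(behaviors))
  res <- purrr::pmap_dfr(grid, function(gene, behavior) {
    x <- expr[gene, shared]
    y <- behaviors[behavior, shared]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(gene = gene, behavior = behavior, n = n,
                            r = NA_real_, p_raw = NA_real_))
    }
    r <- stats::cor(rank(x[ok]), rank(y[ok]))
    p <- if (abs(r) >= 1) 0 else {
      tv <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tv), n - 2)
    }
    tibble::tibble(gene = gene, behavior = behavior, n = n, r = r, p_raw = p)
  })
  tested <- !is.na(res$p_raw)
  m <- if (is.null(family_size)) sum(tested) else family_size
  res$p_holm <- NA_real_
  res$p_holm[tested] <- holm_adjust(res$p_raw[tested], m = m)
  res
}

#' Top differentially expressed genes by fold change
#'
#' Among genes with `efdr < efdr_threshold`, selects the `k_each` largest
#' positive and `k_each` most negative log2 fold changes (ties broken by
#' smaller eFDR, then gene id). If a side has fewer than `k_each`
#' significant genes, what exists is returned and the result is flagged via
#' the `short` attribute.
#'
#' @param de A `deg_results` (or any tibble with `gene`, `log2fc`, `efdr`).
#' @param k_each Genes per direction (default 5).
#' @param efdr_threshold Significance filter (default 0.05).
#' @return Character vector of gene ids (positive side first), with
#'   attribute `short = TRUE` when either side was underfilled.
#' @export
top_degs <- function(de, k_each = 5, efdr_threshold = 0.05) {
  sig <- de[de$efdr < efdr_threshold, , drop = FALSE]
  up <- sig[sig$log2fc > 0, , drop = FALSE]
  dn <- sig[sig$log2fc < 0, , drop = FALSE]
  up <- up[order(-up$log2fc, up$efdr, up$gene), , drop = FALSE]
  dn <- dn[order(dn$log2fc, dn$efdr, dn$gene), , drop = FALSE]
  sel_up <- utils::head(up$gene, k_each)
  sel_dn <- utils::head(dn$gene, k_each)
  out <- c(sel_up, sel_dn)
  attr(out, "short") <- length(sel_up) < k_each || length(sel_dn) < k_each
  out
}
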