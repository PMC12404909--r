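#' Validate a gene x sample count matrix
#'
#' Checks that entries are non-negative integers and that gene and sample
#' identifiers are present and unique. Returns the matrix in integer storage
#' with dimnames intact.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @return The validated integer matrix.
#' @export
count_matrix <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("count matrix must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0 | values != round(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "count matrix entries must be non-negative integers; offending value %s at gene '%s', sample '%s'",
      format(values[i, j]), rownames(values)[i], colnames(values)[j]
    ), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  values
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: genes in rows, first column gene ids, header row of sample
#' ids. MatrixMarket layout: a `.mtx` triplet file with two sidecar files,
#' `<path>.rownames` and `<path>.colnames`, one identifier per line.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @return A validated integer gene x sample matrix.
#' @seealso [write_counts()] for the inverse; TSV round-trips bit-exactly.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      stop("MatrixMarket sidecar name files do not match matrix dimensions",
           call. = FALSE)
    }
    dimnames(m) <- list(rn, cn)
  }
  count_matrix(m)
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' @param counts Gene x sample count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"` (writes `<path>.rownames` /
#'   `<path>.colnames` sidecars).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Drop genes that never reach a minimum count
#'
#' Default reading (`drop_if = "all_below"`): a gene is removed only when its
#' count is below `min_count` in every sample, i.e. kept if any sample
#' reaches `min_count`. The stricter alternative (`drop_if = "any_below"`)
#' removes a gene as soon as one sample falls below the floor; it is provided
#' because the rule "less than `min_count` counts for each sample" admits
#' both readings, but at Tag-seq depths it discards most of the matrix.
#'
#' @param counts Gene x sample count matrix.
#' @param min_count Count floor (default 10).
#' @param drop_if `"all_below"` (default) or `"any_below"`.
#' @return The filtered matrix (same samples, subset of genes, order kept).
#' @export
filter_min_count <- function(counts, min_count = 10,
                             drop_if = c("all_below", "any_below")) {
  drop_if <- match.arg(drop_if)
  if (min_count < 0) stop("`min_count` must be >= 0", call. = FALSE)
  keep <- if (drop_if == "all_below") {
    apply(counts, 1, max) >= min_count
  } else {
    apply(counts, 1, min) >= min_count
  }
  if (!any(keep)) warning("no genes pass the minimum-count filter")
  counts[keep, , drop = FALSE]
}

#' Drop genes with low counts in most samples
#'
#' Removes genes whose count is below `min_count` in more than
#' `max_low_fraction` of samples (strict inequality; a gene low in exactly
#' that fraction is retained).
#'
#' @param counts Gene x sample count matrix.
#' @param min_count Low-expression floor (default 15).
#' @param max_low_fraction Maximum tolerated fraction of low samples
#'   (default 0.75).
#' @return The filtered matrix.
#' @export
filter_prevalence <- function(counts, min_count = 15, max_low_fraction = 0.75) {
  if (max_low_fraction < 0 || max_low_fraction > 1) {
    stop("`max_low_fraction` must be in [0, 1]", call. = FALSE)
  }
  low_frac <- rowMeans(counts < min_count)
  keep <- low_frac <= max_low_fraction
  if (!any(keep)) warning("no genes pass the prevalence filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of that sample's count to the gene's geometric mean across
#' samples; reference genes are those with strictly positive counts in every
#' sample. Factors are rescaled to geometric mean 1.
#'
#' @param counts Gene x sample count matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has strictly positive counts in every sample; filter low-count genes first",
         call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Log2 normalized counts for network analysis
#'
#' Divides counts by median-of-ratios size factors and returns
#' `log2(normalized count + 1)`.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Optional precomputed size factors (defaults to
#'   [size_factors()] of `counts`).
#' @return Gene x sample matrix of log2 normalized counts.
#' @export
log_normalize <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Voom-style log-CPM transform with precision weights
#'
#' Computes `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits unweighted
#' group means per gene, smooths the square-root residual standard
#' deviations against average log2 counts with lowess, and converts the
#' trend into per-observation inverse-variance weights
#' (interpolated sqrt-sd to the power -4, with flat extrapolation outside
#' the fitted range so extreme genes get bounded weights).
#'
#' @param counts Filtered gene x sample count matrix.
#' @param group Character or factor of length `ncol(counts)` with two
#'   levels, each represented by at least 2 samples.
#' @param span Lowess span (default 0.5).
#' @return An object of class `normalized_counts`: list with `logcpm`,
#'   `weights` (both gene x sample), `lib_sizes`, `group`, and `trend`
#'   (tibble of knots: mean log2 count `x`, sqrt residual SD `y`).
#' @export
voom_transform <- function(counts, group, span = 0.5) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2 || any(table(group) < 2)) {
    stop("design must have two groups with at least 2 samples each", call. = FALSE)
  }
  lib <- colSums(counts)
  y <- log2(sweep(counts + 0.5, 2, lib + 1, `/`) * 1e6)

  g2 <- group == levels(group)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  mu1 <- rowMeans(y[, !g2, drop = FALSE])
  mu2 <- rowMeans(y[, g2, drop = FALSE])
  fitted <- matrix(0, nrow(y), ncol(y))
  fitted[, !g2] <- mu1
  fitted[, g2] <- mu2
  df_res <- ncol(y) - 2L
  sigma <- sqrt(rowSums((y - fitted)^2) / df_res)

  # mean-variance trend on the count scale
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- stats::lowess(sx, sy, f = span)
  lo <- stats::approxfun(l$x, l$y, rule = 2, ties = mean)

  lambda <- fitted + matrix(rep(log2(lib + 1), each = nrow(y)), nrow(y)) - log2(1e6)
  w <- lo(lambda)^-4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y) <- dimnames(counts)

  structure(
    list(
      logcpm = y,
      weights = w,
      lib_sizes = lib,
      group = group,
      trend = tibble::tibble(x = l$x, y = l$y)
    ),
    class = "normalized_counts"
  )
}

#' @param x A `normalized_counts` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @rdname voom_transform
#' @method print normalized_counts
#' @export
print.normalized_counts <- function(x, ...) {
  cat("Voom-style normalized counts:", nrow(x$logcpm), "genes x",
      ncol(x$logcpm), "samples\n")
  cat("groups:", paste(levels(x$group), table(x$group), collapse = " / "), "\n")
  invisible(x)
}

#' Sample PCA with a simple distance-based outlier flag
#'
#' Genes are standardized across samples (constant genes dropped); scores
#' are the samples' coordinates on the leading principal axes. A sample is
#' flagged when its Euclidean distance from the score centroid exceeds
#' `k` times the median distance.
#'
#' @param x A `normalized_counts` object or a gene x sample numeric matrix.
#' @param n_components Number of principal components to return (default 2).
#' @param k Outlier multiplier on the median centroid distance (default 3).
#' @return A tibble with `sample_id`, score columns `PC1..PCn`,
#'   `centroid_dist`, `outlier`, plus a `var_explained` attribute.
#' @export
pca_samples <- function(x, n_components = 2, k = 3) {
  m <- if (inherits(x, "normalized_counts")) x$logcpm else x
  if (ncol(m) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  m <- m[sds > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("matrix is constant; PCA undefined", call. = FALSE)
  zs <- t(scale(t(m)))
  pc <- stats::prcomp(t(zs), center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  dist <- sqrt(rowSums(scale(scores, center = TRUE, scale = FALSE)^2))
  out <- tibble::tibble(sample_id = colnames(m))
  for (i in seq_len(n_components)) out[[paste0("PC", i)]] <- scores[, i]
  out$centroid_dist <- dist
  out$outlier <- dist > k * stats::median(dist)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  out
}

#' Check presence and expression of region marker genes
#'
#' Reports, for each marker, whether it is present in the matrix and its
#' mean counts-per-million (computed with the same +0.5 / +1 offsets as the
#' voom transform, so an all-zero marker reports the offset floor rather
#' than zero).
#'
#' @param counts Gene x sample count matrix.
#' @param markers Character vector of gene ids (e.g. region markers such as
#'   hcrt, npvf, npy).
#' @return A tibble with `marker`, `found`, `mean_cpm`.
#' @export
validate_markers <- function(counts, markers) {
  lib <- colSums(counts)
  purrr::map_dfr(markers, function(mk) {
    if (!mk %in% rownames(counts)) {
      return(tibble::tibble(marker = mk, found = FALSE, mean_cpm = NA_real_))
    }
    cpm <- (counts[mk, ] + 0.5) / (lib + 1) * 1e6
    tibble::tibble(marker = mk, found = TRUE, mean_cpm = mean(cpm))
  })
}
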