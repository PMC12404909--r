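#' Signed-hybrid adjacency matrix
#'
#' Computes the Pearson correlation of genes across samples and raises
#' positive correlations to the soft-thresholding power; non-positive
#' correlations map to 0 (signed hybrid mode). Diagonal is 1. Genes with
#' constant expression (undefined correlation) are dropped with a warning.
#'
#' @param expr Gene x sample numeric matrix (typically log2 normalized
#'   counts, see [log_normalize()]).
#' @param power Soft-thresholding power `beta >= 1`.
#' @return Symmetric gene x gene adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_signed_hybrid <- function(expr, power) {
  if (power < 1) stop("`power` must be >= 1", call. = FALSE)
  expr <- .drop_constant_genes(expr)
  a <- pmax(stats::cor(t(expr)), 0)^power
  diag(a) <- 1
  a
}

.drop_constant_genes <- function(expr) {
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0),
            " constant gene(s) excluded from the network (undefined correlation)")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("need at least 2 non-constant genes", call. = FALSE)
  expr
}

# connectivity from an adjacency with unit diagonal
.connectivity <- function(adj) rowSums(adj) - 1

# scale-free fit index on a connectivity vector
.scale_free_index <- function(k, n_bins) {
  if (all(k == 0)) {
    stop("empty network: all correlations are non-positive at this power",
         call. = FALSE)
  }
  if (min(k) == max(k)) {
    # every gene equally connected: a single occupied bin, fit undefined
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  occupied <- table(bin) > 0
  if (sum(occupied) < 2) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  dk <- tapply(k, bin, mean)[occupied]
  pk <- (table(bin) / length(k))[occupied]
  keep <- dk > 0 & pk > 0
  if (sum(keep) < 2) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(as.numeric(pk[keep])) ~ log10(as.numeric(dk[keep])))
  list(r2 = summary(fit)$r.squared, slope = stats::coef(fit)[2])
}

#' Scale-free topology fit at one soft power
#'
#' Builds the signed-hybrid adjacency at the given power, bins the
#' connectivity distribution, regresses `log10 p(k)` on `log10 k` over the
#' occupied bins, and reports the signed fit index
#' `R^2 x (-sign(slope))` together with the mean connectivity. A degenerate
#' connectivity distribution (fewer than two occupied bins) yields an
#' undefined fit (`NA`).
#'
#' @param expr Gene x sample matrix.
#' @param power Soft-thresholding power.
#' @param n_bins Number of connectivity bins (default 10).
#' @return Tibble with `power`, `r_squared_signed`, `mean_k`.
#' @export
scale_free_fit <- function(expr, power, n_bins = 10) {
  adj <- adjacency_signed_hybrid(expr, power)
  k <- .connectivity(adj)
  sf <- .scale_free_index(k, n_bins)
  tibble::tibble(
    power = power,
    r_squared_signed = if (is.na(sf$r2)) NA_real_ else sf$r2 * -sign(sf$slope),
    mean_k = mean(k)
  )
}

#' Scan soft powers and select one by the scale-free criterion
#'
#' Evaluates the scale-free fit over candidate powers. Under
#' `rule = "min_k"`, among candidates whose signed fit exceeds `r2_cutoff`
#' the power with minimal mean connectivity is selected (since mean
#' connectivity decreases with the power, this is the largest qualifying
#' power). `rule = "smallest"` selects the smallest qualifying power, the
#' usual WGCNA convention. If no candidate exceeds the cutoff, the candidate
#' with the maximal fit is selected and the scan is flagged.
#'
#' A `min_mean_k` floor excludes powers whose mean connectivity has dropped
#' below a viable level: on data whose scale-free fit stays high at every
#' power, the minimal-connectivity rule would otherwise select a power so
#' large that the network is essentially empty. The floor corresponds to
#' the minimal mean connectivities a practitioner accepts (single digits to
#' low tens for networks of this size).
#'
#' @param expr Gene x sample matrix.
#' @param powers Candidate powers (default 1:20).
#' @param rule Selection rule, `"min_k"` (fit above the cutoff with minimal mean connectivity) or `"smallest"`.
#' @param r2_cutoff Scale-free fit threshold (default 0.8).
#' @param min_mean_k Minimum viable mean connectivity for an eligible power
#'   (default 0, no floor).
#' @param n_bins Connectivity bins for the fit index.
#' @return An object of class `power_scan`: tibble (`power`,
#'   `r_squared_signed`, `mean_k`) with attributes `selected_power` and
#'   `flagged` (TRUE when no power reached the cutoff).
#' @export
pick_power <- function(expr, powers = 1:20, rule = c("min_k", "smallest"),
                       r2_cutoff = 0.8, min_mean_k = 0, n_bins = 10) {
  rule <- match.arg(rule)
  expr <- .drop_constant_genes(expr)
  cor_pos <- pmax(stats::cor(t(expr)), 0)
  scan <- purrr::map_dfr(powers, function(b) {
    adj <- cor_pos^b
    diag(adj) <- 1
    k <- .connectivity(adj)
    sf <- tryCatch(.scale_free_index(k, n_bins),
                   error = function(e) list(r2 = NA_real_, slope = NA_real_))
    tibble::tibble(
      power = b,
      r_squared_signed = if (is.na(sf$r2)) NA_real_ else sf$r2 * -sign(sf$slope),
      mean_k = mean(k)
    )
  })
  if (all(is.na(scan$r_squared_signed))) {
    stop("scale-free fit undefined at every candidate power", call. = FALSE)
  }
  qual <- which(!is.na(scan$r_squared_signed) &
                  scan$r_squared_signed > r2_cutoff &
                  scan$mean_k >= min_mean_k)
  if (length(qual)) {
    sel <- switch(rule,
      min_k = qual[which.min(scan$mean_k[qual])],
      smallest = qual[which.min(scan$power[qual])]
    )
    flagged <- FALSE
  } else {
    sel <- which.max(scan$r_squared_signed)
    flagged <- TRUE
  }
  out <- tibble::new_tibble(scan, class = "power_scan")
  attr(out, "selected_power") <- scan$power[sel]
  attr(out, "flagged") <- flagged
  attr(out, "rule") <- rule
  attr(out, "r2_cutoff") <- r2_cutoff
  out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' the sum runs over shared neighbours `u != i, j` and
#' `k_i = sum_{u != i} a_iu`. Diagonal is 1.
#'
#' @param adj Symmetric adjacency matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @return Symmetric TOM with entries in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj))) stop("adjacency must be symmetric", call. = FALSE)
  k <- .connectivity(adj)
  # assembled stepwise to keep at most four n x n matrices alive at once
  tom <- adj %*% adj
  tom <- tom - adj    # = sum_{u != i,j} a_iu a_uj + a_ij  (diag(adj) = 1)
  denom <- outer(k, k, pmin)
  denom <- denom - adj
  denom <- denom + 1
  tom <- tom / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`.
#' `method = "static"` cuts the tree at `cut_height`.
#' `method = "dynamic_tree"` (default) is a branch-adaptive variant: after
#' the static cut, each branch is refined top-down, splitting a branch into
#' its two sub-branches whenever their topological overlap ratio — the mean
#' TOM between the sub-branches divided by the geometric mean of the mean
#' TOM within each — falls below `split_ratio`. Fragments of one coherent
#' module have a ratio near 1 and stay together; branches that were only
#' chained by weak cross-correlation split apart. Clusters smaller than
#' `min_module_size` are assigned the background label 0; remaining modules
#' are labelled 1, 2, ... by decreasing size.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Tree cut height on the `1 - TOM` scale (default 0.995).
#' @param method `"dynamic_tree"` (default) or `"static"`.
#' @param split_ratio Branch-split threshold on the topological overlap
#'   ratio (default 0.5); used by `"dynamic_tree"` only.
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.995,
                           method = c("dynamic_tree", "static"),
                           split_ratio = 0.5) {
  method <- match.arg(method)
  n <- nrow(tom)
  if (min_module_size > n) {
    return(stats::setNames(integer(n), rownames(tom)))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (method == "static") {
    cl <- stats::cutree(h, h = cut_height)
  } else {
    cl <- .tree_stat_cut(tom, h, cut_height, split_ratio)
  }
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(n)
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) labels[cl == as.integer(keep[i])] <- i
  }
  stats::setNames(labels, rownames(tom))
}

# Branch-adaptive cut of an average-linkage tree on 1 - TOM.
# Bottom-up replay of the merges accumulates, per internal node, the number
# of leaves, the sum of TOM over within-node pairs, and the sum over pairs
# crossing its two children (each leaf pair contributes to exactly one node,
# so the whole replay is O(n^2)). The top-down pass always splits nodes at
# or above `cut_height` (reproducing the static cut) and below it splits a
# node when the mean cross-child TOM over the geometric mean of the
# children's within-branch means falls below `split_ratio`.
.tree_stat_cut <- function(tom, h, cut_height, split_ratio) {
  n <- nrow(tom)
  m <- nrow(h$merge)
  node_n <- integer(m)
  node_s <- numeric(m)       # sum of TOM over pairs within the node
  node_cross <- numeric(m)   # sum of TOM over pairs crossing the children
  sets <- vector("list", m)
  leafset <- function(id) if (id < 0) -id else sets[[id]]
  stat_n <- function(id) if (id < 0) 1L else node_n[id]
  stat_s <- function(id) if (id < 0) 0 else node_s[id]
  for (i in seq_len(m)) {
    a <- h$merge[i, 1]; b <- h$merge[i, 2]
    sa <- leafset(a); sb <- leafset(b)
    cross <- sum(tom[sa, sb])
    node_cross[i] <- cross
    node_n[i] <- stat_n(a) + stat_n(b)
    node_s[i] <- stat_s(a) + stat_s(b) + cross
    sets[[i]] <- c(sa, sb)
    if (a > 0) sets[a] <- list(NULL)
    if (b > 0) sets[b] <- list(NULL)
  }

  mean_within <- function(id) {
    nn <- stat_n(id)
    if (nn < 2) return(NA_real_)
    stat_s(id) / (nn * (nn - 1) / 2)
  }
  gather <- function(id) {
    # leaf indices under a node, iteratively (trees can be deep chains)
    stack <- id
    out <- integer(0)
    while (length(stack)) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (x < 0) out <- c(out, -x)
      else stack <- c(stack, h$merge[x, ])
    }
    out
  }

  cl <- integer(n)
  next_label <- 0L
  stack <- m   # node ids to examine; leaves are emitted as singletons
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0) {
      next_label <- next_label + 1L
      cl[-node] <- next_label
      next
    }
    a <- h$merge[node, 1]; b <- h$merge[node, 2]
    split <- if (h$height[node] >= cut_height) {
      TRUE
    } else {
      mwa <- mean_within(a); mwb <- mean_within(b)
      cross_mean <- node_cross[node] / (stat_n(a) * stat_n(b))
      denom <- if (is.na(mwa) && is.na(mwb)) NA_real_
               else if (is.na(mwa)) mwb
               else if (is.na(mwb)) mwa
               else sqrt(mwa * mwb)
      if (!is.finite(denom) || denom <= 0) {
        cross_mean > 0   # degenerate: keep together only if children empty too
      } else {
        cross_mean / denom < split_ratio
      }
    }
    if (split) {
      stack <- c(stack, a, b)
    } else {
      next_label <- next_label + 1L
      cl[gather(node)] <- next_label
    }
  }
  cl
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal-component score vector
#' of the module's gene-standardized expression, scaled to unit variance
#' and sign-oriented so that its mean correlation with the module's genes
#' is positive.
#'
#' @param expr Gene x sample matrix.
#' @param labels Named integer vector from [detect_modules()]; label 0 is
#'   ignored.
#' @return List with `me` (sample x module matrix, columns `M1`, `M2`, ...)
#'   and `var_explained` (named numeric, proportion of module variance
#'   carried by the eigengene).
#' @export
eigengenes <- function(expr, labels) {
  labels <- labels[rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) {
    me <- matrix(numeric(0), ncol(expr), 0,
                 dimnames = list(colnames(expr), NULL))
    return(list(me = me, var_explained = stats::setNames(numeric(0),
                                                         character(0))))
  }
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("M", mods)))
  varexp <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (i in seq_along(mods)) {
    x <- expr[labels == mods[i], , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[is.na(xs)] <- 0       # constant gene inside a module carries no signal
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    v <- v / stats::sd(v)
    cors <- suppressWarnings(stats::cor(t(x), v))
    if (mean(cors, na.rm = TRUE) < 0) v <- -v
    me[, i] <- v
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(me = me, var_explained = varexp)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' eigengene. Constant genes yield `NA` with a warning.
#'
#' @param expr Gene x sample matrix.
#' @param me Sample x module eigengene matrix from [eigengenes()].
#' @return Gene x module matrix of correlations in `[-1, 1]`.
#' @export
module_membership <- function(expr, me) {
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) have undefined module membership")
  }
  kme <- suppressWarnings(stats::cor(t(expr), me))
  rownames(kme) <- rownames(expr)
  kme
}

#' Regression of module eigengenes on group
#'
#' Ordinary least squares of each eigengene on an intercept plus group
#' indicator (second factor level minus first). For a two-group design the
#' coefficient is the difference of group means of the eigengene and the
#' t-test equals the pooled-variance two-sample t with `n - 2` df.
#'
#' @param me Sample x module eigengene matrix.
#' @param group Two-level factor/character, length `nrow(me)`.
#' @return Tibble with `module`, `b`, `se`, `p`.
#' @export
me_group_regression <- function(me, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2 || any(table(droplevels(group)) < 2)) {
    stop("design must have two groups with at least 2 samples each", call. = FALSE)
  }
  x <- as.numeric(group == levels(droplevels(group))[2])
  if (!ncol(me)) {
    return(tibble::tibble(module = character(0), b = numeric(0),
                          se = numeric(0), p = numeric(0)))
  }
  purrr::map_dfr(colnames(me), function(m) {
    fit <- stats::lm(me[, m] ~ x)
    cf <- summary(fit)$coefficients
    tibble::tibble(module = m, b = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  })
}

#' Hub genes per module
#'
#' Ranks each module's member genes by absolute module membership
#' (descending; ties broken lexicographically by gene id) and returns the
#' top `top_n`.
#'
#' @param kme Gene x module kME matrix from [module_membership()].
#' @param labels Named integer module labels.
#' @param top_n Hubs per module (default 5).
#' @return Tibble with `module`, `gene`, `kme`, `rank`.
#' @export
hub_genes <- function(kme, labels, top_n = 5) {
  if (top_n < 1) stop("`top_n` must be >= 1", call. = FALSE)
  labels <- labels[intersect(rownames(kme), names(labels))]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) {
    return(tibble::tibble(module = character(0), gene = character(0),
                          kme = numeric(0), rank = integer(0)))
  }
  purrr::map_dfr(mods, function(m) {
    genes <- names(labels)[labels == m]
    col <- paste0("M", m)
    v <- kme[genes, col]
    ord <- order(-abs(v), genes)
    sel <- ord[seq_len(min(top_n, length(ord)))]
    tibble::tibble(module = col, gene = genes[sel], kme = v[sel],
                   rank = seq_along(sel))
  })
}

#' Signed-hybrid co-expression network analysis, end to end
#'
#' Runs the full module pipeline on a count matrix: prevalence filtering,
#' median-of-ratios normalization with log2 transform, optional restriction
#' to the most variable genes, soft-power selection, signed-hybrid
#' adjacency, TOM, module detection, eigengenes, module membership,
#' eigengene-group regression, and hub extraction.
#'
#' @param counts Gene x sample count matrix.
#' @param group Two-level factor/character per sample.
#' @param powers Candidate soft powers.
#' @param rule Power selection rule (see [pick_power()]).
#' @param min_mean_k Mean-connectivity floor for power selection (default
#'   8, the mid-range of the minimal mean connectivities reported for
#'   networks of this size).
#' @param min_module_size,cut_height,method Module detection parameters
#'   (see [detect_modules()]).
#' @param max_genes Keep at most this many genes, ranked by variance of the
#'   log-normalized expression (default 8000); `Inf` keeps all.
#' @param filter Apply the `<15 in more than 75% of samples` prevalence
#'   filter first (default TRUE).
#' @param top_n Hub genes per module.
#' @return An object of class `module_set`: list with `labels`, `me`,
#'   `var_explained`, `kme`, `regression`, `hubs`, `power_scan`, `power`.
#' @export
wgcna_modules <- function(counts, group, powers = 1:20,
                          rule = c("min_k", "smallest"), min_mean_k = 8,
                          min_module_size = 30, cut_height = 0.995,
                          method = c("dynamic_tree", "static"),
                          max_genes = 8000, filter = TRUE, top_n = 5) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  if (filter) counts <- filter_prevalence(counts)
  expr <- log_normalize(counts)
  vars <- apply(expr, 1, stats::var)
  expr <- expr[vars > 0, , drop = FALSE]
  if (is.finite(max_genes) && nrow(expr) > max_genes) {
    keep <- order(-vars[vars > 0])[seq_len(max_genes)]
    expr <- expr[sort(keep), , drop = FALSE]
  }
  scan <- pick_power(expr, powers = powers, rule = rule,
                     min_mean_k = min_mean_k)
  power <- attr(scan, "selected_power")
  adj <- adjacency_signed_hybrid(expr, power)
  tom <- tom_similarity(adj)
  rm(adj); gc(FALSE)
  labels <- detect_modules(tom, min_module_size = min_module_size,
                           cut_height = cut_height, method = method)
  rm(tom); gc(FALSE)
  eg <- eigengenes(expr, labels)
  kme <- module_membership(expr, eg$me)
  reg <- me_group_regression(eg$me, group)
  hubs <- hub_genes(kme, labels, top_n = top_n)
  structure(
    list(labels = labels, me = eg$me, var_explained = eg$var_explained,
         kme = kme, regression = reg, hubs = hubs, power_scan = scan,
         power = power),
    class = "module_set"
  )
}

#' @param x A `module_set` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @rdname wgcna_modules
#' @method print module_set
#' @export
print.module_set <- function(x, ...) {
  n_mod <- sum(unique(x$labels) > 0)
  cat("Co-expression module set:", n_mod, "modules over", length(x$labels),
      "genes (soft power ", x$power, ")\n", sep = "")
  sig <- x$regression[x$regression$p < 0.05, ]
  cat(nrow(sig), "module(s) with eigengene-group regression p < 0.05\n")
  invisible(x)
}
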