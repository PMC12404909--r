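#' Simulation parameters for a two-group Tag-seq experiment
#'
#' Builds and validates the parameter set used by [simulate_experiment()].
#' Defaults emulate a two-week social-stress study design: 20 samples
#' (10 Control, 10 Stressed) per brain region, roughly 11,500 expressed
#' genes, ~250 up- and ~250 down-regulated genes planted at a modest
#' |log2FC|, and a dozen planted co-expression modules, two of which carry
#' a group-shifted latent eigengene.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_per_group Samples per group (Control and Stressed).
#' @param n_de Number of planted differentially expressed genes; split half
#'   up / half down, ties toward up.
#' @param lfc_de Planted absolute log2 fold change (Stressed - Control).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_logmean_range Range (log2 scale) from which per-gene
#'   baseline mean counts are drawn uniformly.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size_range Range of module sizes (genes per module).
#' @param module_cor_strength Loading of module genes on their latent
#'   per-sample eigengene, on the log2 scale; with the default dispersion
#'   this is approximately the pairwise correlation of module genes.
#' @param n_group_shifted_modules Number of modules whose latent eigengene
#'   mean differs between groups.
#' @param module_group_shift Size of that group difference, in SD units of
#'   the latent factor.
#' @param lib_size_range Range of per-sample library scaling factors.
#' @param seed Integer seed; the simulation is fully reproducible given the
#'   same parameters and seed.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 11500,
                       n_per_group = 10,
                       n_de = 500,
                       lfc_de = 0.5,
                       nb_dispersion = 0.1,
                       baseline_logmean_range = c(2, 10),
                       n_modules = 12,
                       module_size_range = c(30, 300),
                       module_cor_strength = 0.7,
                       n_group_shifted_modules = min(2L, n_modules),
                       module_group_shift = 1.5,
                       lib_size_range = c(0.7, 1.3),
                       seed = 1L) {
  chk_count <- function(x, name, min = 0) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
      stop("invalid parameter `", name, "`: must be an integer >= ", min,
           call. = FALSE)
    }
  }
  chk_pos <- function(x, name) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
      stop("invalid parameter `", name, "`: must be a positive number",
           call. = FALSE)
    }
  }
  chk_range <- function(x, name) {
    if (length(x) != 2 || !is.numeric(x) || anyNA(x) || x[1] > x[2]) {
      stop("invalid parameter `", name, "`: must be an ordered (low, high) pair",
           call. = FALSE)
    }
  }
  chk_count(n_genes, "n_genes", min = 1)
  chk_count(n_per_group, "n_per_group", min = 1)
  chk_count(n_de, "n_de")
  chk_pos(lfc_de, "lfc_de")
  chk_pos(nb_dispersion, "nb_dispersion")
  chk_range(baseline_logmean_range, "baseline_logmean_range")
  chk_count(n_modules, "n_modules")
  chk_range(module_size_range, "module_size_range")
  if (module_size_range[1] < 1) {
    stop("invalid parameter `module_size_range`: sizes must be >= 1", call. = FALSE)
  }
  if (length(module_cor_strength) != 1 || !is.numeric(module_cor_strength) ||
      is.na(module_cor_strength) || module_cor_strength <= 0 || module_cor_strength >= 1) {
    stop("invalid parameter `module_cor_strength`: must be in (0, 1)", call. = FALSE)
  }
  chk_count(n_group_shifted_modules, "n_group_shifted_modules")
  if (n_group_shifted_modules > n_modules) {
    stop("invalid parameter `n_group_shifted_modules`: exceeds n_modules",
         call. = FALSE)
  }
  if (length(module_group_shift) != 1 || !is.numeric(module_group_shift) ||
      is.na(module_group_shift) || module_group_shift < 0) {
    stop("invalid parameter `module_group_shift`: must be >= 0", call. = FALSE)
  }
  chk_range(lib_size_range, "lib_size_range")
  if (lib_size_range[1] <= 0) {
    stop("invalid parameter `lib_size_range`: factors must be positive", call. = FALSE)
  }
  if (n_de > n_genes) {
    stop("invalid parameter `n_de`: exceeds n_genes", call. = FALSE)
  }
  if (n_modules * module_size_range[2] > 0 &&
      n_modules * module_size_range[1] > n_genes) {
    stop("invalid parameter `n_modules`: minimum total module size exceeds n_genes",
         call. = FALSE)
  }
  chk_count(seed, "seed")
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_per_group = as.integer(n_per_group),
      n_de = as.integer(n_de),
      lfc_de = lfc_de,
      nb_dispersion = nb_dispersion,
      baseline_logmean_range = baseline_logmean_range,
      n_modules = as.integer(n_modules),
      module_size_range = as.integer(module_size_range),
      module_cor_strength = module_cor_strength,
      n_group_shifted_modules = as.integer(n_group_shifted_modules),
      module_group_shift = module_group_shift,
      lib_size_range = lib_size_range,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# Deterministic per-gene sub-seed so a gene's counts can be regenerated
# without replaying the whole stream. Kept below 2^31 - 1.
.gene_seed <- function(seed, g) {
  (as.double(seed %% 65521L) * 48271 + as.double(g) * 16807) %% 2147483647
}

#' Simulate a two-group Tag-seq count matrix with planted structure
#'
#' Draws gene-wise negative-binomial counts with a log link. Planted DE genes
#' have group-specific means differing by exactly `lfc_de` on the log2 scale;
#' planted module genes share a latent per-sample factor added to the
#' log2 mean with loading `module_cor_strength`; group-shifted modules have a
#' latent factor whose mean differs between groups by `module_group_shift`
#' SD. Per-sample library scaling factors multiply all means of a sample.
#'
#' @param params A [sim_params()] object.
#'
#' @return A list with components:
#' \describe{
#'   \item{counts}{integer gene x sample matrix with gene/sample dimnames.}
#'   \item{samples}{tibble with `sample_id` and `group`
#'     (`Control`/`Stressed`).}
#'   \item{truth}{list with `de_genes` (tibble: gene, planted log2FC),
#'     `module_assignment` (tibble: gene, module; 0 = background),
#'     `group_shifted_modules` (integer labels) and `lib_factors`.}
#' }
#' @export
#' @examples
#' sim <- simulate_experiment(sim_params(n_genes = 200, n_modules = 2,
#'                                       module_size_range = c(10, 20),
#'                                       n_de = 20, seed = 1))
#' dim(sim$counts)
simulate_experiment <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  n_samples <- 2L * p$n_per_group
  gene_ids <- sprintf("g%05d", seq_len(p$n_genes))
  sample_ids <- c(sprintf("Control_%02d", seq_len(p$n_per_group)),
                  sprintf("Stressed_%02d", seq_len(p$n_per_group)))
  group <- rep(c("Control", "Stressed"), each = p$n_per_group)
  stressed <- group == "Stressed"

  set.seed(p$seed)
  base_log2 <- stats::runif(p$n_genes, p$baseline_logmean_range[1],
                            p$baseline_logmean_range[2])

  # planted modules: sizes, then gene membership without replacement
  module_of <- integer(p$n_genes)
  shifted <- integer(0)
  if (p$n_modules > 0) {
    size_choices <- seq(p$module_size_range[1], p$module_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), p$n_modules,
                                     replace = TRUE)]
    total <- sum(sizes)
    if (total > p$n_genes) {
      sizes <- pmax(p$module_size_range[1],
                    floor(sizes * p$n_genes / total))
      if (sum(sizes) > p$n_genes) {
        stop("invalid parameter `n_modules`: total module size exceeds n_genes",
             call. = FALSE)
      }
    }
    members <- sample(p$n_genes, sum(sizes))
    module_of[members] <- rep(seq_len(p$n_modules), times = sizes)
    if (p$n_group_shifted_modules > 0) {
      shifted <- sort(sample(p$n_modules, p$n_group_shifted_modules))
    }
  }

  # planted DE genes, half up / half down (ties toward up)
  de_sign <- numeric(0)
  de_idx <- integer(0)
  if (p$n_de > 0) {
    de_idx <- sort(sample(p$n_genes, p$n_de))
    n_up <- ceiling(p$n_de / 2)
    de_sign <- rep(c(1, -1), c(n_up, p$n_de - n_up))[order(order(stats::runif(p$n_de)))]
  }

  # latent module eigengenes (per sample), group shift in SD units
  z <- NULL
  if (p$n_modules > 0) {
    z <- matrix(stats::rnorm(p$n_modules * n_samples), p$n_modules, n_samples)
    if (length(shifted)) {
      z[shifted, ] <- z[shifted, ] +
        rep(ifelse(stressed, p$module_group_shift / 2, -p$module_group_shift / 2),
            each = length(shifted))
    }
  }

  lib_factors <- stats::runif(n_samples, p$lib_size_range[1], p$lib_size_range[2])

  # per-gene log2 mean per sample
  log2mu <- matrix(rep(base_log2, n_samples), p$n_genes, n_samples)
  if (length(de_idx)) {
    half <- p$lfc_de / 2
    log2mu[de_idx, stressed] <- log2mu[de_idx, stressed] + de_sign * half
    log2mu[de_idx, !stressed] <- log2mu[de_idx, !stressed] - de_sign * half
  }
  if (p$n_modules > 0) {
    in_mod <- module_of > 0
    log2mu[in_mod, ] <- log2mu[in_mod, ] +
      p$module_cor_strength * z[module_of[in_mod], , drop = FALSE]
  }
  mu <- sweep(2^log2mu, 2, lib_factors, `*`)

  counts <- matrix(0L, p$n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  size <- 1 / p$nb_dispersion
  for (g in seq_len(p$n_genes)) {
    set.seed(.gene_seed(p$seed, g))
    counts[g, ] <- stats::rnbinom(n_samples, mu = mu[g, ], size = size)
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    de_genes = tibble::tibble(
      gene = gene_ids[de_idx],
      log2fc = if (length(de_idx)) de_sign * p$lfc_de else numeric(0)
    ),
    module_assignment = tibble::tibble(gene = gene_ids, module = module_of),
    group_shifted_modules = shifted,
    lib_factors = stats::setNames(lib_factors, sample_ids)
  )
  list(
    counts = counts,
    samples = tibble::tibble(sample_id = sample_ids, group = group),
    truth = truth
  )
}

#' Group summary table emulating the study's phenotype reporting
#'
#' Mean/SD per group for the metabolic measures (body weight at P42 in g,
#' weight gain percent, fat mass in g, food efficiency) and the subjugation
#' behaviours recorded in the Stressed group only (attacks received per day,
#' tail-up displays per day, resident scent marks per day). Metabolic values
#' follow the published group summaries; behaviour summaries are set inside
#' the reported per-day ranges (0-2 attacks, 1-3 tail-ups, 0-1 other marks).
#'
#' @return A tibble with columns `measure`, `group`, `mean`, `sd`, `nonneg`
#'   (whether the quantity is a mass/count truncated at zero).
#' @export
hamster_group_summaries <- function() {
  tibble::tribble(
    ~measure,           ~group,     ~mean,  ~sd,   ~nonneg,
    "body_weight_p42",  "Control",  83.8,   7.66,  TRUE,
    "body_weight_p42",  "Stressed", 91.8,   11.9,  TRUE,
    "weight_gain_pct",  "Control",  48.89,  7.08,  FALSE,
    "weight_gain_pct",  "Stressed", 59.38,  7.01,  FALSE,
    "fat_mass",         "Control",  5.21,   1.13,  TRUE,
    "fat_mass",         "Stressed", 6.83,   2.25,  TRUE,
    "food_efficiency",  "Control",  0.162,  0.025, FALSE,
    "food_efficiency",  "Stressed", 0.191,  0.028, FALSE,
    "attacks_received", "Stressed", 1.0,    0.5,   TRUE,
    "tail_ups",         "Stressed", 2.0,    0.6,   TRUE,
    "scent_marks",      "Stressed", 0.5,    0.3,   TRUE
  )
}

#' Simulate a per-sample phenotype sheet from group summaries
#'
#' Each measure is drawn independently from a normal distribution with the
#' given group mean and SD; draws for non-negative quantities (masses,
#' behaviour counts) are truncated at zero. Measures without a summary for a
#' group are `NA` for that group's samples (e.g. behaviours are only defined
#' for Stressed animals).
#'
#' @param group_summaries Tibble/data frame with columns `measure`, `group`,
#'   `mean`, `sd` and optionally `nonneg` (default `TRUE`).
#'   See [hamster_group_summaries()].
#' @param n_per_group Samples per group (>= 2).
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id`, `group`, and one column per measure.
#' @export
#' @examples
#' simulate_phenotypes(hamster_group_summaries(), n_per_group = 10, seed = 1)
simulate_phenotypes <- function(group_summaries = hamster_group_summaries(),
                                n_per_group = 10, seed = 1L) {
  gs <- tibble::as_tibble(group_summaries)
  req <- c("measure", "group", "mean", "sd")
  if (!all(req %in% names(gs))) {
    stop("`group_summaries` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"nonneg" %in% names(gs)) gs$nonneg <- TRUE
  if (any(!is.finite(gs$sd) | gs$sd <= 0)) {
    stop("invalid parameter `sd`: all group SDs must be positive", call. = FALSE)
  }
  if (n_per_group < 2) {
    stop("invalid parameter `n_per_group`: must be >= 2", call. = FALSE)
  }
  groups <- c("Control", "Stressed")
  sheet <- tibble::tibble(
    sample_id = c(sprintf("Control_%02d", seq_len(n_per_group)),
                  sprintf("Stressed_%02d", seq_len(n_per_group))),
    group = rep(groups, each = n_per_group)
  )
  set.seed(seed)
  for (m in unique(gs$measure)) {
    vals <- rep(NA_real_, nrow(sheet))
    for (grp in groups) {
      row <- gs[gs$measure == m & gs$group == grp, ]
      if (nrow(row) == 0) next
      x <- stats::rnorm(n_per_group, row$mean[1], row$sd[1])
      if (isTRUE(row$nonneg[1])) x <- pmax(x, 0)
      vals[sheet$group == grp] <- x
    }
    sheet[[m]] <- vals
  }
  sheet
}
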