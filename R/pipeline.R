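#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' mirroring the study design: three hypothalamic regions (LH, DMH, ARC),
#' 10 Control / 10 Stressed samples each, differential expression with a
#' permutation eFDR, signed-hybrid module analysis, over-representation
#' analysis, and phenotype statistics. Every entry can be overridden, and a
#' YAML file with the same structure can be passed to [run_pipeline()]
#' directly.
#'
#' @param seed Integer master seed (mandatory when any stochastic stage is
#'   enabled; region- and stage-level seeds are derived from it).
#' @param outdir Output directory for serialized intermediates (`NULL`
#'   disables writing).
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  list(
    seed = seed,
    outdir = outdir,
    regions = c("LH", "DMH", "ARC"),
    stages = list(simulate = TRUE, preprocess = TRUE, de = TRUE,
                  wgcna = TRUE, ora = TRUE, pheno = TRUE),
    paths = list(counts = NULL, samples = NULL, gmt = NULL, phenotypes = NULL),
    simulate = list(),                  # overrides for sim_params()
    preprocess = list(min_count = 10, markers = NULL),
    de = list(n_perm = 500, lfc_threshold = 0.2, efdr_threshold = 0.05),
    wgcna = list(powers = 1:20, rule = "min_k", min_mean_k = 8,
                 min_module_size = 30,
                 cut_height = 0.995, method = "dynamic_tree",
                 max_genes = 8000),
    ora = list(min_overlap = 1),
    pheno = list(k_each = 5, behaviors = c("attacks_received", "tail_ups",
                                           "scent_marks"))
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.write_tsv <- function(df, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess,
#' differential expression with permutation eFDR, co-expression modules,
#' over-representation analysis, phenotype statistics — serializing every
#' intermediate to `outdir` (when set) and returning a structured report.
#' Identical configuration and seed give an identical report. A stage error
#' aborts with the stage name; outputs of completed stages remain on disk.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure. Partial lists are merged over
#'   the defaults.
#' @return An object of class `run_report`: list with per-region DEG
#'   counts, module regression stats, enrichment summaries, phenotype
#'   tests, behaviour correlations, stage timings, the configuration hash
#'   and package version.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  stages <- cfg$stages
  stochastic <- isTRUE(stages$simulate) || isTRUE(stages$de)
  if (stochastic && (is.null(cfg$seed) || !is.finite(cfg$seed))) {
    stop("a seed is mandatory when stochastic stages are enabled", call. = FALSE)
  }
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
  }
  report <- list(
    # hash the scientific configuration; where outputs land is not part of it
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "outdir")]),
    version = as.character(utils::packageVersion("stresshypo")),
    timings = tibble::tibble(stage = character(), seconds = numeric())
  )
  class(report) <- "run_report"
  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$timings <<- dplyr::bind_rows(
      report$timings,
      tibble::tibble(stage = stage, seconds = proc.time()[["elapsed"]] - t0)
    )
    res
  }

  counts <- list()
  truths <- list()
  samples <- NULL
  gene_sets <- NULL

  if (isTRUE(stages$simulate)) {
    sims <- timer("simulate", {
      purrr::imap(stats::setNames(seq_along(cfg$regions), cfg$regions),
                  function(i, region) {
        args <- cfg$simulate
        args$seed <- cfg$seed + i - 1L
        simulate_experiment(do.call(sim_params, args))
      })
    })
    counts <- purrr::map(sims, "counts")
    truths <- purrr::map(sims, "truth")
    samples <- sims[[1]]$samples
    if (!is.null(cfg$outdir)) {
      for (r in names(counts)) {
        write_counts(counts[[r]], file.path(cfg$outdir,
                                            paste0("counts_", r, ".tsv")))
        jsonlite::write_json(
          list(de_genes = truths[[r]]$de_genes,
               group_shifted_modules = truths[[r]]$group_shifted_modules),
          file.path(cfg$outdir, paste0("truth_", r, ".json"))
        )
      }
      utils::write.csv(samples, file.path(cfg$outdir, "samples.csv"),
                       row.names = FALSE)
    }
    # planted modules double as a self-contained gene-set collection
    gene_sets <- .truth_gene_sets(truths[[1]])
  } else if (isTRUE(stages$preprocess) || isTRUE(stages$de) ||
             isTRUE(stages$wgcna)) {
    if (is.null(cfg$paths$counts)) {
      stop("pipeline stage 'input' failed: no counts paths configured and simulate disabled",
           call. = FALSE)
    }
    counts <- purrr::map(cfg$paths$counts, read_counts)
    samples <- tibble::as_tibble(utils::read.csv(cfg$paths$samples))
  }
  if (!is.null(cfg$paths$gmt)) gene_sets <- read_gmt(cfg$paths$gmt)

  group <- NULL
  norm <- list()
  if (isTRUE(stages$preprocess) && length(counts)) {
    group <- factor(samples$group, levels = c("Control", "Stressed"))
    pre <- timer("preprocess", purrr::map(counts, function(cm) {
      filtered <- filter_min_count(cm, min_count = cfg$preprocess$min_count)
      nm <- voom_transform(filtered, group)
      pca <- pca_samples(nm)
      markers <- if (!is.null(cfg$preprocess$markers)) {
        validate_markers(filtered, cfg$preprocess$markers)
      }
      list(norm = nm, pca = pca, markers = markers, filtered = filtered)
    }))
    norm <- purrr::map(pre, "norm")
    if (!is.null(cfg$outdir)) {
      for (r in names(norm)) {
        nm <- norm[[r]]
        .write_tsv(data.frame(gene = rownames(nm$logcpm), nm$logcpm,
                              check.names = FALSE),
                   cfg$outdir, paste0("logcpm_", r, ".tsv"))
        .write_tsv(data.frame(gene = rownames(nm$weights), nm$weights,
                              check.names = FALSE),
                   cfg$outdir, paste0("weights_", r, ".tsv"))
        jsonlite::write_json(nm$trend,
                             file.path(cfg$outdir, paste0("trend_", r, ".json")))
      }
    }
    report$pca_outliers <- purrr::imap_dfr(pre, function(p, region) {
      tibble::tibble(region = region, n_outliers = sum(p$pca$outlier))
    })
    report$markers <- purrr::imap_dfr(pre, function(p, region) {
      if (is.null(p$markers)) return(NULL)
      dplyr::mutate(p$markers, region = region, .before = 1)
    })
    counts_filtered <- purrr::map(pre, "filtered")
  }

  de_results <- list()
  if (isTRUE(stages$de) && length(norm)) {
    de_results <- timer("de", purrr::imap(norm, function(nm, region) {
      run_de(nm, n_perm = cfg$de$n_perm,
             seed = cfg$seed + 100L + match(region, cfg$regions),
             lfc_threshold = cfg$de$lfc_threshold,
             efdr_threshold = cfg$de$efdr_threshold)
    }))
    report$deg_counts <- purrr::imap_dfr(de_results, function(de, region) {
      tibble::tibble(region = region, n_up = attr(de, "n_up"),
                     n_down = attr(de, "n_down"),
                     n_tested = attr(de, "n_tested"))
    })
    if (length(de_results) >= 2) {
      report$cross_region <- cross_region_tables(de_results)
    }
    if (!is.null(cfg$outdir)) {
      for (r in names(de_results)) {
        .write_tsv(de_results[[r]], cfg$outdir, paste0("de_", r, ".tsv"))
        jsonlite::write_json(
          list(n_perm = attr(de_results[[r]], "n_perm"),
               seed = attr(de_results[[r]], "seed"),
               d0 = attr(de_results[[r]], "d0"),
               s02 = attr(de_results[[r]], "s02")),
          file.path(cfg$outdir, paste0("de_", r, "_meta.json")),
          auto_unbox = TRUE
        )
      }
    }
  }

  modules <- list()
  if (isTRUE(stages$wgcna) && length(counts)) {
    modules <- timer("wgcna", purrr::map(counts, function(cm) {
      wgcna_modules(cm, group, powers = cfg$wgcna$powers,
                    rule = cfg$wgcna$rule, min_mean_k = cfg$wgcna$min_mean_k,
                    min_module_size = cfg$wgcna$min_module_size,
                    cut_height = cfg$wgcna$cut_height,
                    method = cfg$wgcna$method,
                    max_genes = cfg$wgcna$max_genes)
    }))
    report$modules <- purrr::imap_dfr(modules, function(ms, region) {
      sizes <- table(ms$labels[ms$labels > 0])
      dplyr::mutate(ms$regression, region = region,
                    n_genes = as.integer(sizes[sub("^M", "", .data$module)]),
                    power = ms$power, .before = 1)
    })
    if (!is.null(cfg$outdir)) {
      for (r in names(modules)) {
        ms <- modules[[r]]
        .write_tsv(tibble::tibble(gene = names(ms$labels), module = ms$labels),
                   cfg$outdir, paste0("modules_", r, ".tsv"))
        .write_tsv(data.frame(sample = rownames(ms$me), ms$me),
                   cfg$outdir, paste0("eigengenes_", r, ".tsv"))
        .write_tsv(ms$regression, cfg$outdir, paste0("me_regression_", r, ".tsv"))
        .write_tsv(ms$hubs, cfg$outdir, paste0("hubs_", r, ".tsv"))
      }
    }
  }

  if (isTRUE(stages$ora) && length(de_results) && !is.null(gene_sets)) {
    report$enrichment <- timer("ora", purrr::imap_dfr(
      de_results,
      function(de, region) {
        degs <- de$gene[de$call != "ns"]
        if (!length(degs)) return(NULL)
        dplyr::mutate(
          ora(degs, de$gene, gene_sets, min_overlap = cfg$ora$min_overlap),
          region = region, .before = 1
        )
      }
    ))
    if (!is.null(cfg$outdir) && !is.null(report$enrichment)) {
      .write_tsv(report$enrichment, cfg$outdir, "enrichment.tsv")
    }
  }

  if (isTRUE(stages$pheno)) {
    ph <- timer("pheno", {
      sheet <- if (!is.null(cfg$paths$phenotypes)) {
        tibble::as_tibble(utils::read.csv(cfg$paths$phenotypes))
      } else {
        simulate_phenotypes(n_per_group = if (!is.null(samples)) {
          sum(samples$group == "Control")
        } else 10, seed = cfg$seed + 500L)
      }
      measures <- setdiff(names(sheet), c("sample_id", "group",
                                          cfg$pheno$behaviors))
      welch <- purrr::map_dfr(measures, function(m) {
        x <- sheet[[m]][sheet$group == "Control"]
        y <- sheet[[m]][sheet$group == "Stressed"]
        if (all(is.na(x)) || all(is.na(y))) return(NULL)
        generics::tidy(welch_test_raw(x[!is.na(x)], y[!is.na(y)],
                                      labels = c("Control", "Stressed"))) |>
          dplyr::mutate(measure = m, .before = 1)
      })
      cors <- NULL
      if (length(de_results) && length(norm)) {
        beh <- t(as.matrix(sheet[sheet$group == "Stressed",
                                 cfg$pheno$behaviors, drop = FALSE]))
        colnames(beh) <- sheet$sample_id[sheet$group == "Stressed"]
        tabs <- purrr::imap(de_results, function(de, region) {
          genes <- top_degs(de, k_each = cfg$pheno$k_each)
          if (!length(genes)) return(NULL)
          expr <- norm[[region]]$logcpm[genes, , drop = FALSE]
          dplyr::mutate(spearman_holm(expr, beh), region = region, .before = 1)
        })
        tabs <- purrr::compact(tabs)
        if (length(tabs)) {
          cors <- dplyr::bind_rows(tabs)
          tested <- !is.na(cors$p_raw)
          # Holm family pooled across regions x genes x behaviours
          cors$p_holm[tested] <- holm_adjust(cors$p_raw[tested])
        }
      }
      list(sheet = sheet, welch = welch, cors = cors)
    })
    report$phenotypes <- ph$welch
    report$behavior_correlations <- ph$cors
    if (!is.null(cfg$outdir)) {
      utils::write.csv(ph$sheet, file.path(cfg$outdir, "phenotypes.csv"),
                       row.names = FALSE)
      .write_tsv(ph$welch, cfg$outdir, "phenotype_welch.tsv")
      if (!is.null(ph$cors)) {
        .write_tsv(ph$cors, cfg$outdir, "behavior_correlations.tsv")
      }
    }
  }

  report
}

.truth_gene_sets <- function(truth) {
  ma <- truth$module_assignment
  mods <- sort(unique(ma$module[ma$module > 0]))
  if (!length(mods)) return(NULL)
  tibble::new_tibble(
    tibble::tibble(
      set = paste0("planted_module_", mods),
      description = "planted co-expression module",
      genes = purrr::map(mods, ~ ma$gene[ma$module == .x])
    ),
    class = "gene_sets"
  )
}

#' @param x A `run_report` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @rdname run_pipeline
#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat("stresshypo run report (v", x$version, ")\n", sep = "")
  if (!is.null(x$deg_counts)) {
    cat("DEG counts:\n")
    print(x$deg_counts)
  }
  if (!is.null(x$modules)) {
    cat(nrow(x$modules), "modules across regions;",
        sum(x$modules$p < 0.05), "with group regression p < 0.05\n")
  }
  if (nrow(x$timings)) {
    cat("stage timings (s):",
        paste(sprintf("%s=%.1f", x$timings$stage, x$timings$seconds),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Volcano plotting table
#'
#' Produces the table needed for a volcano plot: log2 fold change,
#' `-log10(eFDR)` with zero eFDR values capped at the resolution of the
#' permutation null (`1 / (2 n_perm)`; `1e-4` when the permutation count is
#' unknown), and the call. Fold-change guide values (0.2, 0.75, 1.5) are
#' attached as the `guides` attribute.
#'
#' @param de A `deg_results` tibble.
#' @return A tibble with `gene`, `log2fc`, `neg_log10_efdr`, `call`, with
#'   attributes `guides` and `efdr_floor`.
#' @export
make_volcano_table <- function(de) {
  n_perm <- attr(de, "n_perm")
  floor_ <- if (!is.null(n_perm)) 1 / (2 * n_perm) else 1e-4
  out <- tibble::tibble(
    gene = de$gene,
    log2fc = de$log2fc,
    neg_log10_efdr = -log10(pmax(de$efdr, floor_)),
    call = de$call
  )
  attr(out, "guides") <- c(0.2, 0.75, 1.5)
  attr(out, "efdr_floor") <- floor_
  out
}
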