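#' Volcano plot of DEG results
#'
#' Log2 fold change against `-log10(eFDR)` with the DEG calls coloured and
#' the fold-change guides (0.2, 0.75, 1.5) and eFDR threshold drawn as
#' dashed lines.
#'
#' @param object A `deg_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_results <- function(object, ...) {
  tab <- make_volcano_table(object)
  guides <- attr(tab, "guides")
  thr <- attr(object, "efdr_threshold")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_efdr,
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-guides, guides), linetype = "dashed",
                        linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed",
                        linewidth = 0.3, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (Stressed - Control)",
                  y = "-log10 eFDR", colour = "call") +
    ggplot2::theme_minimal()
}

#' Soft-power selection diagnostics
#'
#' Scale-free fit index and mean connectivity against the candidate soft
#' powers, with the selected power highlighted.
#'
#' @param object A `power_scan` object from [pick_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_scan <- function(object, ...) {
  tab <- tidy(object)
  tab_long <- tidyr::pivot_longer(tab, c("r_squared_signed", "mean_k"),
                                  names_to = "metric")
  sel <- attr(object, "selected_power")
  ggplot2::ggplot(tab_long, ggplot2::aes(x = .data$power, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$power == sel), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft-thresholding power", y = NULL) +
    ggplot2::theme_minimal()
}

#' Module eigengene boxplots by group
#'
#' @param object A `module_set` object.
#' @param group Two-level factor/character per sample.
#' @param modules Optional module names (default: modules with regression
#'   p < 0.05, or all if none are significant).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_module_eigengenes <- function(object, group, modules = NULL, ...) {
  if (is.null(modules)) {
    modules <- object$regression$module[object$regression$p < 0.05]
    if (!length(modules)) modules <- colnames(object$me)
  }
  df <- tibble::as_tibble(object$me[, modules, drop = FALSE])
  df$group <- as.factor(group)
  long <- tidyr::pivot_longer(df, -"group", names_to = "module",
                              values_to = "eigengene")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$eigengene,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = NULL, y = "module eigengene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Phenotype boxplots by group
#'
#' @param sheet A phenotype tibble from [simulate_phenotypes()].
#' @param measures Measures to plot (default: all metabolic columns present
#'   for both groups).
#' @return A ggplot object.
#' @export
plot_phenotypes <- function(sheet, measures = NULL) {
  value_cols <- setdiff(names(sheet), c("sample_id", "group"))
  if (is.null(measures)) {
    measures <- value_cols[vapply(value_cols, function(m) {
      all(tapply(!is.na(sheet[[m]]), sheet$group, any))
    }, logical(1))]
  }
  long <- tidyr::pivot_longer(sheet[, c("group", measures)], -"group",
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
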