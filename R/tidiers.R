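#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Welch test
#'
#' @param x A `welch_htest` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `t`, `df`, `p`, `d`.
#' @export
tidy.welch_htest <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, t = x$t, df = x$df, p = x$p, d = x$d)
}

#' @rdname tidy.welch_htest
#' @export
glance.welch_htest <- function(x, ...) tidy(x)

#' Tidy a moderated fit
#'
#' @param x A `moderated_fit` tibble.
#' @param ... Unused.
#' @return The underlying tibble (gene-level statistics).
#' @export
tidy.moderated_fit <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(d0 = attr(x, "d0"), s02 = attr(x, "s02"),
                 n_genes = nrow(x))
}

#' Tidy DEG results
#'
#' @param x A `deg_results` tibble.
#' @param ... Unused.
#' @return The per-gene tibble / the one-row call summary.
#' @export
tidy.deg_results <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.deg_results
#' @export
glance.deg_results <- function(x, ...) {
  tibble::tibble(
    n_up = attr(x, "n_up"), n_down = attr(x, "n_down"),
    n_tested = attr(x, "n_tested"),
    lfc_threshold = attr(x, "lfc_threshold"),
    efdr_threshold = attr(x, "efdr_threshold")
  )
}

#' Tidy a module set
#'
#' @param x A `module_set` object.
#' @param ... Unused.
#' @return The per-module eigengene-group regression tibble with module
#'   sizes / a one-row summary.
#' @export
tidy.module_set <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0])
  dplyr::mutate(x$regression,
                n_genes = as.integer(sizes[sub("^M", "", .data$module)]),
                var_explained = unname(x$var_explained[.data$module]))
}

#' @rdname tidy.module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_modules = sum(unique(x$labels) > 0),
    n_genes = length(x$labels),
    n_unassigned = sum(x$labels == 0),
    power = x$power,
    n_significant = sum(x$regression$p < 0.05)
  )
}

#' Tidy a power scan
#'
#' @param x A `power_scan` object.
#' @param ... Unused.
#' @return The scan tibble / a one-row selection summary.
#' @export
tidy.power_scan <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.power_scan
#' @export
glance.power_scan <- function(x, ...) {
  tibble::tibble(selected_power = attr(x, "selected_power"),
                 flagged = attr(x, "flagged"), rule = attr(x, "rule"))
}
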