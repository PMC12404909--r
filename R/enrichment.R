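#' Read a GMT gene-set collection
#'
#' Each GMT line is tab-separated: set name, description, then one or more
#' member gene ids. Duplicate members within a set are deduplicated.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble of class `gene_sets` with columns `set`, `description`,
#'   `genes` (list column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i,
           ": expected name, description and at least one member", call. = FALSE)
    }
    tibble::tibble(set = f[1], description = f[2], genes = list(unique(f[-(1:2)])))
  })
  out <- dplyr::bind_rows(parsed)
  if (anyDuplicated(out$set)) {
    stop("duplicate set names: ",
         paste(unique(out$set[duplicated(out$set)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::new_tibble(out, class = "gene_sets")
}

#' Write a GMT gene-set collection
#'
#' @param sets A `gene_sets` tibble (see [read_gmt()]) or any tibble with
#'   `set`, `description`, `genes` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set, description, genes, ...) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query within the
#' universe. Sets are intersected with the universe before testing; the
#' p-value is the upper-tail hypergeometric probability of at least the
#' observed overlap; q-values are Benjamini-Hochberg adjusted across the
#' reported sets.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of background gene ids (e.g. all genes
#'   surviving the expression filter).
#' @param sets A `gene_sets` tibble.
#' @param min_overlap Sets with a smaller overlap are excluded from the
#'   table (default 1).
#' @return A tibble with `set`, `overlap`, `set_size` (after universe
#'   intersection), `query_size`, `universe_size`, `p`, `q`, ordered by `p`.
#' @export
ora <- function(query, universe, sets, min_overlap = 1) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("universe is empty", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 3), collapse = ", "),
         call. = FALSE)
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- purrr::pmap_dfr(sets, function(set, description, genes, ...) {
    g <- intersect(genes, universe)
    k <- length(intersect(g, query))
    tibble::tibble(set = set, overlap = k, set_size = length(g))
  })
  rows <- rows[rows$overlap >= min_overlap & rows$set_size > 0, , drop = FALSE]
  rows$query_size <- n_query
  rows$universe_size <- n_univ
  rows$p <- stats::phyper(rows$overlap - 1, rows$set_size,
                          n_univ - rows$set_size, n_query, lower.tail = FALSE)
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  dplyr::arrange(tibble::as_tibble(rows), .data$p, .data$set)
}
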