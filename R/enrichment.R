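#' Per-cell-type K-S enrichment of a DEG set
#'
#' For each cell type, compares the distribution of preferential expression
#' (PEM) values of a differentially expressed gene set against the unchanged
#' background genes with a two-sample Kolmogorov-Smirnov test. A cell type in
#' which the DEG set sits at systematically higher PEM than the background is
#' "enriched" for that set. P-values are Benjamini-Hochberg adjusted across
#' the cell types tested in this call (class and subclass levels form
#' separate families), and an enrichment score `-log10(padj)` is reported
#' for plotting.
#'
#' The `alternative` is stated from the DEG set's point of view:
#' `"greater"` tests whether DEG PEM values are stochastically greater than
#' the background (enrichment); `"two-sided"` detects any distributional
#' difference, with the direction reported separately in `shift_sign` (the
#' sign of the DEG-minus-background median PEM difference).
#'
#' @param pem A `pem_matrix` from [compute_pem()].
#' @param deg_set Character vector of DEG identifiers.
#' @param background_set Character vector of unchanged genes; must be
#'   disjoint from `deg_set`.
#' @param alternative `"two-sided"` (default, conservative) or `"greater"`.
#' @param exact Logical passed to the K-S test; `FALSE` (asymptotic p) by
#'   default.
#' @param min_genes Minimum members each set must retain inside the PEM gene
#'   universe for a cell type to be tested (types are shared, so this is
#'   checked once); genes absent from the PEM universe are dropped and
#'   counted.
#' @return A tibble of class `enrichment_result`: one row per cell type with
#'   columns `cell_type`, `n_deg_used`, `n_background_used`, `D`,
#'   `shift_sign`, `p`, `padj`, `score` (-log10 padj), sorted by descending
#'   score.
#' @export
ks_enrichment <- function(pem, deg_set, background_set,
                          alternative = c("two-sided", "greater"),
                          exact = FALSE, min_genes = 10) {
  assert_that(inherits(pem, "pem_matrix"), "`pem` must be a pem_matrix")
  alternative <- match.arg(alternative)
  deg_set <- unique(deg_set)
  background_set <- unique(background_set)
  overlap <- intersect(deg_set, background_set)
  assert_that(length(overlap) == 0,
              paste0("DEG and background sets overlap (",
                     length(overlap), " genes)"))
  universe <- rownames(pem$pem)
  deg_in <- intersect(deg_set, universe)
  bg_in <- intersect(background_set, universe)
  assert_that(length(deg_in) >= min_genes,
              paste0("only ", length(deg_in), " DEG genes in the PEM universe",
                     " (min_genes = ", min_genes, ")"))
  assert_that(length(bg_in) >= min_genes,
              paste0("only ", length(bg_in),
                     " background genes in the PEM universe",
                     " (min_genes = ", min_genes, ")"))
  # R's ks.test states the alternative in terms of the CDF of x: a DEG set
  # shifted toward higher PEM has its ECDF *below* the background's.
  ks_alt <- if (alternative == "greater") "less" else "two.sided"
  res <- purrr::map_dfr(colnames(pem$pem), function(ct) {
    x <- pem$pem[deg_in, ct]
    y <- pem$pem[bg_in, ct]
    kt <- suppressWarnings(stats::ks.test(x, y, alternative = ks_alt,
                                          exact = exact))
    tibble::tibble(
      cell_type = ct,
      n_deg_used = length(x),
      n_background_used = length(y),
      D = unname(kt$statistic),
      shift_sign = sign(stats::median(x) - stats::median(y)),
      p = kt$p.value
    )
  })
  res$padj <- adjust_bh(res$p)
  res$score <- -log10(pmax(res$padj, .Machine$double.xmin))
  res <- dplyr::arrange(res, dplyr::desc(.data$score), .data$p)
  attr(res, "alternative") <- alternative
  attr(res, "level") <- pem$level
  attr(res, "n_deg_dropped") <- length(deg_set) - length(deg_in)
  attr(res, "n_background_dropped") <- length(background_set) - length(bg_in)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_cell_types = nrow(x),
    n_significant = sum(x$padj < 0.05),
    top_cell_type = x$cell_type[1],
    alternative = attr(x, "alternative") %||% NA_character_,
    level = attr(x, "level") %||% NA_character_
  )
}

#' Bar chart of cell-type enrichment scores
#'
#' @param object An `enrichment_result`.
#' @param alpha Significance threshold drawn as a dashed reference line at
#'   `-log10(alpha)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$cell_type <- factor(df$cell_type, levels = rev(df$cell_type))
  df$direction <- factor(ifelse(df$shift_sign >= 0, "higher in DEGs",
                                "lower in DEGs"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$cell_type,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p (enrichment score)"),
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
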