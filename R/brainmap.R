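#' Spatial score of a gene module over an expression volume
#'
#' The spatial expression of a gene set ("module") at a voxel is the sum of
#' the ISH energies of the module genes available in the volume's panel.
#' Genes absent from the panel are dropped and counted, never imputed (they
#' would contribute no energy either way).
#'
#' @param volume An `expression_volume` from [simulate_ish_volume()] or
#'   [read_volume()].
#' @param genes Character vector of module gene identifiers.
#' @param name Optional module name carried in the result.
#' @return A tibble of class `module_map`: one row per voxel with columns
#'   `x`, `y`, `z`, `region`, `score`. Attributes: `module`,
#'   `n_genes_available`, `n_genes_requested`, `missing_genes`, `grid_dim`.
#' @export
module_spatial_score <- function(volume, genes, name = "module") {
  assert_that(inherits(volume, "expression_volume"),
              "`volume` must be an expression_volume")
  genes <- unique(genes)
  present <- intersect(genes, volume$genes)
  if (length(present) == 0) {
    stop_decomap(paste0("no module gene is present in the volume's panel; ",
                        "missing: ", paste(head(genes, 10), collapse = ", "),
                        if (length(genes) > 10) ", ..." else ""),
                 class = "decomap_input_error")
  }
  score <- rowSums(volume$energy[, present, drop = FALSE])
  out <- volume$voxels
  out$score <- score
  attr(out, "module") <- name
  attr(out, "n_genes_available") <- length(present)
  attr(out, "n_genes_requested") <- length(genes)
  attr(out, "missing_genes") <- setdiff(genes, present)
  attr(out, "grid_dim") <- volume$dim
  class(out) <- c("module_map", class(out))
  out
}

#' Per-region summary of a module map
#'
#' Aggregates the voxel-wise module score by region: voxel count, total and
#' mean score, ranked by mean. Regions with no voxels never appear (the
#' partition assigns every voxel to one region).
#'
#' @param map A `module_map` from [module_spatial_score()].
#' @return Tibble with columns `region`, `n_voxels`, `total_score`,
#'   `mean_score`, sorted by decreasing mean.
#' @export
region_summary <- function(map) {
  assert_that(inherits(map, "module_map"), "`map` must be a module_map")
  tibble::as_tibble(map) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     total_score = sum(.data$score),
                     mean_score = mean(.data$score),
                     .by = "region") |>
    dplyr::arrange(dplyr::desc(.data$mean_score))
}

#' Regional contrast between two module maps
#'
#' Per region, the log2 ratio of the first map's mean score to the second's
#' (with a pseudocount), for contrasting e.g. an up-regulated against a
#' down-regulated module. Both maps must share the voxel grid.
#'
#' @param map_a,map_b `module_map` objects on the same grid.
#' @param pseudocount Added to both means before the ratio.
#' @return Tibble with `region`, `mean_a`, `mean_b`, `log2_ratio`, sorted by
#'   decreasing ratio.
#' @export
region_contrast <- function(map_a, map_b, pseudocount = 1e-6) {
  assert_that(inherits(map_a, "module_map") && inherits(map_b, "module_map"),
              "both arguments must be module_map objects")
  assert_that(identical(as.data.frame(map_a)[c("x", "y", "z", "region")],
                        as.data.frame(map_b)[c("x", "y", "z", "region")]),
              "the two maps are not on the same voxel grid",
              class = "decomap_input_error")
  a <- region_summary(map_a)[, c("region", "mean_score")]
  b <- region_summary(map_b)[, c("region", "mean_score")]
  names(a)[2] <- "mean_a"
  names(b)[2] <- "mean_b"
  dplyr::inner_join(a, b, by = "region") |>
    dplyr::mutate(log2_ratio = log2((.data$mean_a + pseudocount) /
                                      (.data$mean_b + pseudocount))) |>
    dplyr::arrange(dplyr::desc(.data$log2_ratio))
}

#' Extract a 2-D section from a module map
#'
#' Returns the score and region-label planes at a fixed coordinate along one
#' axis, with no interpolation. Coordinates are 0-based; the z axis runs
#' lateral to medial, so sweeping `z` from 0 upward walks sagittal sections
#' from the lateral surface to the midline.
#'
#' @param map A `module_map`.
#' @param axis One of `"x"`, `"y"`, `"z"` (default `"z"`, sagittal).
#' @param index 0-based plane index along `axis`.
#' @return List with `score` and `region` matrices over the two remaining
#'   axes (rows = first remaining axis, ascending), plus `axis` and `index`.
#' @export
extract_section <- function(map, axis = c("z", "x", "y"), index = 0L) {
  assert_that(inherits(map, "module_map"), "`map` must be a module_map")
  axis <- match.arg(axis)
  dims <- attr(map, "grid_dim")
  names(dims) <- c("x", "y", "z")
  assert_that(is_count(index) && index < dims[[axis]],
              paste0("`index` must lie in [0, ", dims[[axis]] - 1, "]"))
  sel <- map[[axis]] == index
  others <- setdiff(c("x", "y", "z"), axis)
  sub <- map[sel, , drop = FALSE]
  ord <- order(sub[[others[2]]], sub[[others[1]]])
  sub <- sub[ord, ]
  shape <- c(dims[[others[1]]], dims[[others[2]]])
  list(
    score = matrix(sub$score, nrow = shape[1], ncol = shape[2]),
    region = matrix(sub$region, nrow = shape[1], ncol = shape[2]),
    axis = axis, index = as.integer(index)
  )
}

#' Heatmap of one section of a module map
#'
#' @param object A `module_map`.
#' @param axis,index Section selector as in [extract_section()].
#' @param ... Unused.
#' @return A ggplot object (tiles colored by score, region boundaries by
#'   text label omitted for clarity).
#' @exportS3Method ggplot2::autoplot
autoplot.module_map <- function(object, axis = "z", index = 0L, ...) {
  dims <- attr(object, "grid_dim")
  names(dims) <- c("x", "y", "z")
  df <- tibble::as_tibble(object)
  df <- df[df[[axis]] == index, ]
  others <- setdiff(c("x", "y", "z"), axis)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[others[1]]],
                                   y = .data[[others[2]]],
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(attr(object, "module") %||% "module",
                                 " (", axis, " = ", index, ")")) +
    ggplot2::theme_minimal()
}
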