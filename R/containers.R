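#' Bulk gene-count container
#'
#' Bundles a genes x samples matrix of non-negative integer counts with its
#' per-sample metadata (condition, sex, batch). This is the bulk input every
#' downstream stage consumes.
#'
#' @param counts Numeric matrix, genes x samples, non-negative integers, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param metadata Data frame with one row per sample and columns
#'   `sample_id`, `condition` (exactly two levels), `sex`, `batch`.
#' @return An object of class `gene_counts`: a list with elements `counts`
#'   (integer matrix) and `metadata` (tibble, ordered as the columns of
#'   `counts`).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:4),
#'                  condition = rep(c("control", "stress"), 2),
#'                  sex = rep(c("M", "F"), 2), batch = "b1")
#' gc <- gene_counts(m, md)
#' @export
gene_counts <- function(counts, metadata) {
  assert_that(is.matrix(counts) && is.numeric(counts),
              "`counts` must be a numeric matrix")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` must have gene rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(counts)),
              "duplicate gene identifiers in `counts`")
  assert_that(!anyDuplicated(colnames(counts)),
              "duplicate sample identifiers in `counts`")
  assert_that(all(is.finite(counts)) && all(counts >= 0) &&
                all(counts == floor(counts)),
              "`counts` must contain non-negative integers")
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "condition", "sex", "batch")
  assert_that(all(need %in% names(metadata)),
              paste("`metadata` must have columns:", paste(need, collapse = ", ")))
  assert_that(setequal(metadata$sample_id, colnames(counts)) &&
                nrow(metadata) == ncol(counts),
              "`metadata` must cover every sample exactly once")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ]
  assert_that(length(unique(metadata$condition)) == 2L,
              "`condition` must have exactly two levels")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, metadata = metadata), class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("<gene_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("conditions:", paste(table(x$metadata$condition), collapse = "/"),
      " sexes:", paste(table(x$metadata$sex), collapse = "/"),
      " batches:", paste(table(x$metadata$batch), collapse = "/"), "\n")
  invisible(x)
}

#' Labeled single-cell reference container
#'
#' A cells x genes count matrix (stored genes x cells) together with per-cell
#' type labels at two granularities (class and subclass), the source of all
#' cell-type expression profiles.
#'
#' @param counts Numeric matrix, genes x cells, non-negative integers.
#' @param cell_metadata Data frame with columns `cell_id`, `class`, and
#'   optionally `subclass` (defaults to `class`).
#' @param profiles Optional genes x cell-types matrix of expected relative
#'   expression (attached by the simulator as ground truth; `NULL` for real
#'   data).
#' @return An object of class `single_cell_reference`.
#' @export
single_cell_reference <- function(counts, cell_metadata, profiles = NULL) {
  assert_that(is.matrix(counts) && is.numeric(counts),
              "`counts` must be a numeric matrix")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` must have gene rownames and cell colnames")
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "`counts` must contain non-negative integers")
  cell_metadata <- tibble::as_tibble(cell_metadata)
  assert_that(all(c("cell_id", "class") %in% names(cell_metadata)),
              "`cell_metadata` needs columns cell_id and class")
  if (!"subclass" %in% names(cell_metadata)) {
    cell_metadata$subclass <- cell_metadata$class
  }
  assert_that(setequal(cell_metadata$cell_id, colnames(counts)) &&
                nrow(cell_metadata) == ncol(counts),
              "`cell_metadata` must cover every cell exactly once")
  cell_metadata <- cell_metadata[match(colnames(counts), cell_metadata$cell_id), ]
  structure(list(counts = counts, cell_metadata = cell_metadata,
                 profiles = profiles),
            class = "single_cell_reference")
}

#' @export
print.single_cell_reference <- function(x, ...) {
  cat("<single_cell_reference> ", nrow(x$counts), " genes x ",
      ncol(x$counts), " cells, ",
      length(unique(x$cell_metadata$class)), " classes / ",
      length(unique(x$cell_metadata$subclass)), " subclasses\n", sep = "")
  invisible(x)
}
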