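#' Read and write count matrices
#'
#' Counts travel either as a TSV with a `gene` column plus one column per
#' sample, or as MatrixMarket (`.mtx`) with `<stem>.rownames.txt` and
#' `<stem>.colnames.txt` sidecar files. Both round-trip exactly (integer
#' counts, names and order preserved).
#'
#' @param path For TSV: the file path. For MTX: the `.mtx` path; sidecars
#'   are derived from it.
#' @param counts A genes x samples integer matrix with dimnames.
#' @param format `"tsv"` or `"mtx"` (inferred from the extension when
#'   reading).
#' @return `read_counts()` returns the integer matrix; writers return the
#'   path invisibly.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
read_counts <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  if (grepl("\\.mtx$", path)) {
    rn_path <- sub("\\.mtx$", ".rownames.txt", path)
    cn_path <- sub("\\.mtx$", ".colnames.txt", path)
    for (p in c(rn_path, cn_path)) {
      assert_that(file.exists(p),
                  paste0("missing MTX sidecar names file: ", p))
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rn_path)
    cn <- readLines(cn_path)
    assert_that(length(rn) == nrow(m) && length(cn) == ncol(m),
                "sidecar name files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    assert_that(names(df)[1] == "gene", "first TSV column must be `gene`")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
  }
  assert_that(!anyDuplicated(rownames(m)), "duplicate gene identifiers")
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample identifiers")
  storage.mode(m) <- "integer"
  m
}

#' @rdname counts_io
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  if (inherits(counts, "gene_counts")) counts <- counts$counts
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), sub("\\.mtx$", ".rownames.txt", path))
    writeLines(colnames(counts), sub("\\.mtx$", ".colnames.txt", path))
  } else {
    df <- tibble::as_tibble(counts, rownames = "gene")
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read / write per-cell type labels
#'
#' Two- or three-column TSV: `cell_id`, `class`, optional `subclass`.
#' @param path File path.
#' @param labels Tibble with at least `cell_id` and `class`.
#' @return `read_labels()` returns a tibble; the writer returns the path
#'   invisibly.
#' @name labels_io
NULL

#' @rdname labels_io
#' @export
read_labels <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("cell_id", "class") %in% names(df)),
              "labels file needs columns cell_id and class")
  assert_that(!anyDuplicated(df$cell_id), "duplicate cell identifiers")
  df
}

#' @rdname labels_io
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Duplicate genes within a set are de-duplicated with a warning (sets are
#' sets).
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return `read_gmt()` returns a named list of character vectors with the
#'   descriptions in attribute `descriptions`; the writer returns the path
#'   invisibly.
#' @name gmt_io
NULL

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_decomap(paste0("malformed GMT line ", i,
                          ": need name, description and >= 1 gene"),
                   class = "decomap_format_error")
    }
    nm <- parts[1]
    if (nm %in% names(sets)) {
      stop_decomap(paste0("duplicate gene-set name at line ", i, ": ", nm),
                   class = "decomap_format_error")
    }
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      rlang::warn(paste0("GMT set '", nm, "': ",
                         sum(duplicated(genes)), " duplicate gene(s) dropped"))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
    descriptions[nm] <- parts[2]
  }
  attr(sets, "descriptions") <- descriptions
  sets
}

#' @rdname gmt_io
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(is.list(sets) && !is.null(names(sets)),
              "`sets` must be a named list")
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", unique(sets[[nm]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write expression volumes as long-format TSV
#'
#' Columns: `x`, `y`, `z` (0-based integer voxel coordinates), `region`,
#' `gene`, `energy`. Every voxel must appear for every gene; the reader
#' reconstructs the dense voxels x genes energy matrix and validates that
#' each voxel carries exactly one region label.
#'
#' @param path File path.
#' @param volume An `expression_volume`.
#' @return `read_volume()` returns an `expression_volume`; the writer
#'   returns the path invisibly.
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume <- function(volume, path) {
  assert_that(inherits(volume, "expression_volume"),
              "`volume` must be an expression_volume")
  long <- tidyr::expand_grid(gene = volume$genes,
                             voxel = seq_len(nrow(volume$voxels)))
  out <- dplyr::bind_cols(
    volume$voxels[long$voxel, ],
    tibble::tibble(gene = long$gene,
                   energy = volume$energy[cbind(long$voxel,
                                                match(long$gene, volume$genes))])
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x", "y", "z", "region", "gene", "energy")
  assert_that(all(need %in% names(df)),
              paste("volume TSV needs columns:", paste(need, collapse = ", ")),
              class = "decomap_format_error")
  assert_that(all(df$energy >= 0), "energies must be non-negative",
              class = "decomap_format_error")
  dims <- c(max(df$x) + 1L, max(df$y) + 1L, max(df$z) + 1L)
  vox <- dplyr::distinct(df, .data$x, .data$y, .data$z, .data$region)
  key <- paste(vox$x, vox$y, vox$z)
  assert_that(!anyDuplicated(key),
              "a voxel carries more than one region label",
              class = "decomap_format_error")
  # x-fastest linear order, matching the simulator
  vox <- vox[order(vox$z, vox$y, vox$x), ]
  genes <- unique(df$gene)
  vidx <- match(paste(df$x, df$y, df$z), paste(vox$x, vox$y, vox$z))
  energy <- matrix(NA_real_, nrow(vox), length(genes),
                   dimnames = list(NULL, genes))
  energy[cbind(vidx, match(df$gene, genes))] <- df$energy
  assert_that(!anyNA(energy), "volume TSV is missing voxel/gene entries",
              class = "decomap_format_error")
  structure(list(dim = dims, voxels = tibble::as_tibble(vox), energy = energy,
                 genes = genes, home_map = NULL),
            class = "expression_volume")
}

#' Read / write sample metadata TSV
#'
#' Columns `sample_id`, `condition`, `sex`, `batch`.
#' @param path File path.
#' @param metadata Tibble of sample metadata.
#' @return `read_metadata()` returns a tibble; the writer returns the path
#'   invisibly.
#' @name metadata_io
NULL

#' @rdname metadata_io
#' @export
read_metadata <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("sample_id", "condition", "sex", "batch") %in% names(df)),
              "metadata needs columns sample_id, condition, sex, batch")
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample identifiers")
  df
}

#' @rdname metadata_io
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}
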