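#' Per-cell-type mean expression profiles
#'
#' Averages single-cell expression within each labeled cell type at the
#' requested granularity. Cells are depth-normalized to counts-per-10k by
#' default before averaging, so types sampled at different depths are
#' comparable; types with fewer than `min_cells` cells are dropped with a
#' warning.
#'
#' @param reference A [single_cell_reference()].
#' @param level `"class"` or `"subclass"` — which label granularity to
#'   average over.
#' @param normalize `"cp10k"` (counts per 10,000 per cell) or `"none"`.
#' @param min_cells Minimum cells a type needs to be retained.
#' @return An object of class `cell_profiles`: list with `X` (genes x types
#'   mean-expression matrix), `S` (named column sums of `X`), `n` (number of
#'   types), `level`, `n_cells` (cells per retained type).
#' @export
pseudobulk_means <- function(reference, level = c("class", "subclass"),
                             normalize = c("cp10k", "none"), min_cells = 3) {
  assert_that(inherits(reference, "single_cell_reference"),
              "`reference` must be a single_cell_reference")
  level <- match.arg(level)
  normalize <- match.arg(normalize)
  labels <- reference$cell_metadata[[level]]
  assert_that(ncol(reference$counts) > 0, "empty reference")
  m <- reference$counts
  if (normalize == "cp10k") {
    depth <- colSums(m)
    depth[depth == 0] <- 1
    m <- sweep(m, 2, depth / 1e4, "/")
  }
  tab <- table(labels)
  keep_types <- names(tab)[tab >= min_cells]
  dropped <- setdiff(names(tab), keep_types)
  if (length(dropped)) {
    rlang::warn(paste0("dropping ", length(dropped), " type(s) with < ",
                       min_cells, " cells: ", paste(dropped, collapse = ", ")))
  }
  assert_that(length(keep_types) >= 2,
              "fewer than 2 cell types retained after filtering")
  X <- vapply(keep_types,
              function(tp) rowMeans(m[, labels == tp, drop = FALSE]),
              numeric(nrow(m)))
  dimnames(X) <- list(rownames(reference$counts), keep_types)
  structure(list(X = X, S = colSums(X), n = ncol(X), level = level,
                 n_cells = as.integer(tab[keep_types])),
            class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("<cell_profiles> ", nrow(x$X), " genes x ", x$n, " ", x$level,
      " types\n", sep = "")
  invisible(x)
}

#' Preferential expression measure (PEM) matrix
#'
#' Normalizes a genes x cell-types mean-expression matrix into preferential
#' expression values. With `X[g, i]` the mean expression of gene g in type i
#' and `S[i] = sum_g X[g, i]` the type's total expression mass, the measure
#' is
#' \deqn{PEM_{g,i} = \log_{10}\!\left(\frac{\sum_{i'} S_{i'}}{S_i}\cdot
#'   \frac{X_{g,i}}{\sum_{i'} X_{g,i'}}\right)}
#' i.e. the log10 ratio of the gene's observed share in type i to the share
#' expected if the gene followed each type's overall expression mass. A
#' value of 0 means no preference; positive values mean enrichment in that
#' type. A pseudocount is added to every entry of `X` before any ratio so
#' the measure is finite for unexpressed genes.
#'
#' The construction conserves mass: for every gene,
#' `sum_i 10^PEM[g, i] * S[i] / sum(S) = 1`.
#'
#' @param profiles A `cell_profiles` object from [pseudobulk_means()], or a
#'   bare genes x types matrix.
#' @param pseudocount Non-negative value added to every entry of `X` first;
#'   zero is admissible when every entry of `X` is already positive (the
#'   finiteness check fails otherwise).
#' @return An object of class `pem_matrix`: list with `pem` (genes x types),
#'   `S` (post-pseudocount column masses), `pseudocount`, `level`.
#' @examples
#' X <- matrix(c(90, 10, 10, 90), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' compute_pem(X, pseudocount = 0)$pem[1, ] # ~ log10(1.8), log10(0.2)
#' @export
compute_pem <- function(profiles, pseudocount = 1e-3) {
  if (inherits(profiles, "cell_profiles")) {
    X <- profiles$X
    level <- profiles$level
  } else {
    assert_that(is.matrix(profiles) && is.numeric(profiles),
                "`profiles` must be cell_profiles or a numeric matrix")
    X <- profiles
    level <- NA_character_
  }
  assert_that(is.numeric(pseudocount) && length(pseudocount) == 1 &&
                pseudocount >= 0,
              "`pseudocount` must be non-negative")
  assert_that(all(X >= 0), "expression means must be non-negative")
  assert_that(ncol(X) >= 2, "need at least 2 cell types")
  Xp <- X + pseudocount
  S <- colSums(Xp)
  row_tot <- rowSums(Xp)
  ee <- sweep(Xp / row_tot, 2, sum(S) / S, "*")
  pem <- log10(ee)
  assert_that(all(is.finite(pem)), "PEM must be finite after pseudocounting")
  structure(list(pem = pem, S = S, pseudocount = pseudocount, level = level),
            class = "pem_matrix")
}

#' @export
print.pem_matrix <- function(x, ...) {
  cat("<pem_matrix> ", nrow(x$pem), " genes x ", ncol(x$pem),
      " types (pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pem_matrix <- function(x, ...) {
  tibble::as_tibble(x$pem, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell_type", values_to = "pem")
}
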