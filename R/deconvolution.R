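#' Build a cell-type signature matrix from PEM-ranked markers
#'
#' Selects, for each cell type, the `k` genes with the highest preferential
#' expression in that type, takes the union (a gene picked by several types
#' appears once, attributed to the type where its PEM is maximal), and
#' returns the corresponding rows of the type-mean expression matrix scaled
#' to counts-per-million columns.
#'
#' @param profiles A `cell_profiles` from [pseudobulk_means()].
#' @param pem A `pem_matrix` from [compute_pem()] aligned with `profiles`.
#' @param k Markers per type (capped, with a warning, at the number of
#'   available genes).
#' @return An object of class `signature_matrix`: list with `X` (signature
#'   genes x types CPM matrix), `selection` (tibble gene, cell_type, pem),
#'   `k`.
#' @export
build_signature <- function(profiles, pem, k = 50) {
  assert_that(inherits(profiles, "cell_profiles"),
              "`profiles` must be cell_profiles")
  assert_that(inherits(pem, "pem_matrix"), "`pem` must be a pem_matrix")
  assert_that(is_count(k) && k >= 1, "`k` must be a positive integer")
  assert_that(identical(rownames(profiles$X), rownames(pem$pem)) &&
                identical(colnames(profiles$X), colnames(pem$pem)),
              "`profiles` and `pem` must be aligned (same genes and types)")
  if (k > nrow(pem$pem)) {
    rlang::warn(paste0("k = ", k, " exceeds the ", nrow(pem$pem),
                       " available genes; capped"))
    k <- nrow(pem$pem)
  }
  picked <- unique(unlist(lapply(colnames(pem$pem), function(ct) {
    rownames(pem$pem)[order(pem$pem[, ct], decreasing = TRUE)[seq_len(k)]]
  })))
  # attribute each gene to the type where its PEM is maximal
  best_type <- colnames(pem$pem)[apply(pem$pem[picked, , drop = FALSE], 1,
                                       which.max)]
  cpm <- sweep(profiles$X, 2, colSums(profiles$X), "/") * 1e6
  X <- cpm[picked, , drop = FALSE]
  keep <- rowSums(X) > 0
  X <- X[keep, , drop = FALSE]
  structure(list(
    X = X,
    selection = tibble::tibble(gene = picked[keep],
                               cell_type = best_type[keep],
                               pem = pem$pem[cbind(picked[keep],
                                                   best_type[keep])]),
    k = k
  ), class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("<signature_matrix> ", nrow(x$X), " genes x ", ncol(x$X),
      " types (top ", x$k, " per type by PEM)\n", sep = "")
  invisible(x)
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' Per sample, regresses the bulk counts-per-million vector over the
#' signature genes on the signature's type columns under a non-negativity
#' constraint, then renormalizes the coefficients to sum to one. Mixtures
#' are linear in linear (not log) space, so both sides are CPM-normalized
#' over their full gene universes before restriction to signature genes.
#'
#' Genes are precision-weighted: under an overdispersed count model the
#' variance of a gene's CPM grows as `mu + tau * mu^2`, so each gene enters
#' the fit with weight `1 / (mu + tau * mu^2)` (`mu` = its mean CPM across
#' samples). This keeps a handful of highly expressed genes from dominating
#' the fit; `tau = 0` reduces to Poisson weighting and `weighted = FALSE` to
#' ordinary NNLS. Exact mixtures are recovered exactly under any weighting.
#'
#' @param bulk A [gene_counts()] object, or a genes x samples numeric matrix
#'   (e.g. a noiseless constructed mixture).
#' @param signature A `signature_matrix` from [build_signature()].
#' @param weighted Apply inverse-variance gene weights (default TRUE).
#' @param tau Extra-Poisson coefficient of variation squared used in the
#'   weights.
#' @return An object of class `fraction_table`: list with `fractions`
#'   (samples x types matrix, rows sum to 1), `residuals` (named per-sample
#'   residual norms, on the weighted scale when `weighted`), `metadata`
#'   (tibble or NULL).
#' @export
estimate_fractions <- function(bulk, signature, weighted = TRUE, tau = 0.05) {
  assert_that(inherits(signature, "signature_matrix"),
              "`signature` must be a signature_matrix")
  if (inherits(bulk, "gene_counts")) {
    m <- bulk$counts
    md <- bulk$metadata
  } else {
    assert_that(is.matrix(bulk) && is.numeric(bulk) && !is.null(rownames(bulk)),
                "`bulk` must be gene_counts or a named numeric matrix")
    m <- bulk
    md <- NULL
  }
  S <- signature$X
  assert_that(nrow(S) >= ncol(S),
              "need at least as many signature genes as cell types")
  qr_s <- qr(S)
  if (qr_s$rank < ncol(S)) {
    dropped <- colnames(S)[qr_s$pivot[(qr_s$rank + 1):ncol(S)]]
    stop_decomap(paste0("signature is rank deficient; collinear type(s): ",
                        paste(dropped, collapse = ", ")),
                 class = "decomap_design_error")
  }
  shared <- intersect(rownames(S), rownames(m))
  assert_that(length(shared) >= ncol(S),
              "too few signature genes present in the bulk matrix")
  depth <- colSums(m)
  assert_that(all(depth > 0), "bulk sample with zero total counts")
  cpm <- sweep(m, 2, depth, "/") * 1e6
  B <- cpm[shared, , drop = FALSE]
  Ss <- S[shared, , drop = FALSE]
  if (weighted) {
    mu <- rowMeans(B)
    w <- 1 / (mu + tau * mu^2)
    w[!is.finite(w)] <- 0
    sw <- sqrt(w)
    B <- B * sw
    Ss <- Ss * sw
  }
  qr_ss <- qr(Ss)
  fits <- lapply(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    # when the unconstrained solution already satisfies the constraints
    # (e.g. exact mixtures) it is the NNLS solution; the active-set solver
    # is only needed when a non-negativity constraint binds
    ols <- qr.coef(qr_ss, b)
    if (all(ols >= -1e-10)) {
      x <- pmax(ols, 0)
      list(x = x, resid.norm = sqrt(sum((b - Ss %*% x)^2)))
    } else {
      pracma::lsqnonneg(Ss, b)
    }
  })
  coefs <- do.call(rbind, lapply(fits, `[[`, "x"))
  sums <- rowSums(coefs)
  assert_that(all(sums > 0), "a sample fitted all-zero fractions")
  fr <- coefs / sums
  dimnames(fr) <- list(colnames(m), colnames(S))
  resid <- vapply(fits, `[[`, numeric(1), "resid.norm")
  names(resid) <- colnames(m)
  structure(list(fractions = fr, residuals = resid, metadata = md),
            class = "fraction_table")
}

#' @export
print.fraction_table <- function(x, ...) {
  cat("<fraction_table> ", nrow(x$fractions), " samples x ",
      ncol(x$fractions), " types\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fraction_table <- function(x, ...) {
  out <- tibble::as_tibble(x$fractions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "fraction")
  if (!is.null(x$metadata)) {
    out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  }
  out
}

#' Compare estimated cell fractions between condition groups
#'
#' Per cell type, a two-sided unpaired Welch t-test of the stress group's
#' fractions against the control group's, with mean and SEM per group. No
#' multiplicity correction is applied (each cell type is reported on its
#' own, as in a per-type bar chart).
#'
#' @param fractions A `fraction_table` from [estimate_fractions()].
#' @param metadata Optional sample metadata (tibble with `sample_id` and
#'   `condition`); defaults to the metadata carried by `fractions`.
#' @return A tibble of class `fraction_comparison`: one row per cell type
#'   with `mean_control`, `sem_control`, `mean_stress`, `sem_stress`,
#'   `difference` (stress - control), `t`, `p`.
#' @export
compare_fractions <- function(fractions, metadata = NULL) {
  assert_that(inherits(fractions, "fraction_table"),
              "`fractions` must be a fraction_table")
  md <- metadata %||% fractions$metadata
  assert_that(!is.null(md) && all(c("sample_id", "condition") %in% names(md)),
              "need sample metadata with sample_id and condition")
  md <- md[match(rownames(fractions$fractions), md$sample_id), ]
  assert_that(!anyNA(md$sample_id), "metadata must cover every sample")
  conds <- unique(md$condition)
  assert_that(length(conds) == 2, "`condition` must have exactly two groups")
  grp <- md$condition == "stress"
  if (!any(grp)) grp <- md$condition == conds[2] # generic two-group fallback
  assert_that(sum(grp) >= 2 && sum(!grp) >= 2,
              "need at least 2 samples per group")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- purrr::map_dfr(colnames(fractions$fractions), function(ct) {
    a <- fractions$fractions[!grp, ct] # control
    b <- fractions$fractions[grp, ct]  # stress
    tt <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else {
      stats::t.test(b, a, var.equal = FALSE)
    }
    tibble::tibble(cell_type = ct,
                   mean_control = mean(a), sem_control = sem(a),
                   mean_stress = mean(b), sem_stress = sem(b),
                   difference = mean(b) - mean(a),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  class(out) <- c("fraction_comparison", class(out))
  out
}

#' Grouped bar chart of cell fractions (mean +/- SEM)
#'
#' @param object A `fraction_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fraction_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_control", "mean_stress"),
                        names_to = "group", values_to = "mean",
                        names_prefix = "mean_")
  df$sem <- ifelse(df$group == "control", df$sem_control, df$sem_stress)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
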