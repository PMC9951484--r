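#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over genes expressed in
#' every sample, of the ratio of the sample's count to the gene's geometric
#' mean across samples. This is the standard count-normalization used before
#' model fitting.
#'
#' @param counts A [gene_counts()] object or a genes x samples count matrix.
#' @return Named numeric vector of strictly positive factors, one per sample.
#' @examples
#' m <- matrix(c(1, 2, 4, 8, 3, 6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' estimate_size_factors(m) # s2 counts are exactly double: factors 1/sqrt(2), sqrt(2)
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "gene_counts")) counts$counts else counts
  assert_that(is.matrix(m) && all(m >= 0), "`counts` must be a non-negative matrix")
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop_decomap(
      "no gene has nonzero counts in every sample; size factors undefined",
      class = "decomap_degenerate_input"
    )
  }
  mm <- m[usable, , drop = FALSE]
  log_geo <- rowMeans(log(mm))
  sf <- apply(mm, 2, function(col) exp(stats::median(log(col) - log_geo)))
  assert_that(all(sf > 0), "computed non-positive size factor")
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, returned in
#' the input order.
#'
#' @param pvalues Numeric vector with all values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  assert_that(is.numeric(pvalues), "`pvalues` must be numeric")
  assert_that(!anyNA(pvalues) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Newton inversion of the trigamma function (for the variance-prior df)
trigamma_inverse <- function(x) {
  if (x > trigamma(1e-6)) return(1e-6)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# empirical-Bayes variance moderation: squeeze per-gene residual variances
# toward a common prior fitted by the method of moments on log s^2 (scaled
# chi-square model), returning posterior variances and augmented df
moderate_variances <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(s2 = s2, df = rep(df, length(s2))))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  post <- s2
  if (is.finite(d0)) {
    post[ok] <- (d0 * s02 + df * s2[ok]) / (d0 + df)
    post[!ok] <- s02 * d0 / (d0 + df) # no residual information at all
  } else {
    post[] <- s02
  }
  list(s2 = post, df = rep(df + d0, length(s2)), d0 = d0, s02 = s02)
}

# internal: identify collinear design columns for a clear error message
check_design_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_decomap(
      paste0("design is rank deficient; collinear column(s): ",
             paste(dropped, collapse = ", "),
             " (condition confounded with a covariate?)"),
      class = "decomap_design_error"
    )
  }
  invisible(TRUE)
}

#' Covariate-adjusted differential expression
#'
#' Per-gene Gaussian linear model on `log2(normalized count + 1)` with sex,
#' batch and condition in the design; the condition coefficient (stress vs
#' control) is reported as the log2 fold change with a two-sided t-test
#' p-value and Benjamini-Hochberg adjustment across all tested genes. This
#' is a deliberately transparent stand-in for a negative binomial Wald fit:
#' its job is to produce calibrated DEG and background sets for the
#' downstream cell-type and spatial analyses, not to reproduce any
#' particular NB machinery. The fit runs on counts standardized to a fixed
#' pseudo-depth (1e6) after median-of-ratios normalization, which makes every
#' log2FC exactly invariant to rescaling a sample's library.
#' Genes below a minimal mean-expression filter are
#' excluded before testing (and from the BH family); genes with zero
#' variance across samples get p = 1 and log2FC = 0.
#'
#' @param counts A [gene_counts()] object.
#' @param alpha Significance threshold on the adjusted p-value used to label
#'   the `set` column (strict inequality: `padj < alpha`).
#' @param min_mean Minimal mean normalized count for a gene to be tested.
#' @param subset Optional named list restricting samples before fitting,
#'   e.g. `list(sex = "M")` for a sex-stratified reanalysis; covariates left
#'   with a single level are dropped from the design.
#' @param moderate Squeeze per-gene residual variances toward a common prior
#'   by empirical Bayes (scaled chi-square model fitted by moments on
#'   `log s^2`), testing with the augmented degrees of freedom. Substantially
#'   stabilizes the t-statistics at small sample sizes; `FALSE` gives plain
#'   per-gene t-tests.
#' @return A tibble of class `deg_table` with columns `gene`, `base_mean`
#'   (mean normalized count), `log2FC`, `p`, `padj`, `set` (up / down /
#'   background), ordered as the input genes (filtered genes omitted).
#'   Attributes: `alpha`, `n_filtered`, `design`.
#' @export
differential_expression <- function(counts, alpha = 0.05, min_mean = 1,
                                    subset = NULL, moderate = TRUE) {
  assert_that(inherits(counts, "gene_counts"), "`counts` must be gene_counts")
  md <- counts$metadata
  m <- counts$counts
  if (!is.null(subset)) {
    keep <- rep(TRUE, nrow(md))
    for (nm in names(subset)) {
      assert_that(nm %in% names(md), paste("unknown subset variable:", nm))
      keep <- keep & md[[nm]] %in% subset[[nm]]
    }
    md <- md[keep, , drop = FALSE]
    m <- m[, keep, drop = FALSE]
  }
  assert_that(all(table(md$condition) >= 2),
              "need at least 2 samples per condition")

  sf <- estimate_size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  base_mean <- rowMeans(norm)
  tested <- base_mean >= min_mean
  assert_that(any(tested), "no gene passes the expression filter")
  norm <- norm[tested, , drop = FALSE]
  # standardize to a fixed pseudo-depth of 1e6 before the log transform so
  # the +1 offset is applied on a scale independent of sequencing depth;
  # rescaling any sample's counts then leaves the fitted matrix (and hence
  # every log2FC) unchanged, not just unchanged up to the offset
  geo_depth <- exp(mean(log(colSums(norm))))
  norm_fit <- norm * (1e6 / geo_depth)

  md$condition <- factor(md$condition)
  md$condition <- stats::relevel(md$condition, ref = "control")
  covars <- c("sex", "batch")
  covars <- covars[vapply(covars, function(v) length(unique(md[[v]])) > 1,
                          logical(1))]
  fml <- stats::reformulate(c(covars, "condition"))
  X <- stats::model.matrix(fml, data = md)
  check_design_rank(X)

  Y <- t(log2(norm_fit + 1)) # samples x genes
  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, Y)
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  assert_that(df >= 1, "not enough residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  t_df <- rep(df, length(sigma2))
  if (moderate) {
    mod <- moderate_variances(sigma2, df)
    sigma2 <- mod$s2
    t_df <- mod$df
  }
  xtxi <- solve(crossprod(X))
  cond_col <- grep("^condition", colnames(X))
  se <- sqrt(sigma2 * xtxi[cond_col, cond_col])
  lfc <- coefs[cond_col, ]

  zero_var <- apply(Y, 2, function(y) stats::var(y) == 0)
  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = t_df)
  p[zero_var] <- 1
  lfc[zero_var] <- 0
  p[!zero_var & se == 0] <- 0 # perfect non-constant fit: unambiguous effect
  padj <- adjust_bh(p)

  tab <- tibble::tibble(
    gene = rownames(norm),
    base_mean = base_mean[tested],
    log2FC = unname(lfc),
    p = unname(p),
    padj = unname(padj),
    set = dplyr::case_when(
      padj < alpha & lfc > 0 ~ "up",
      padj < alpha & lfc < 0 ~ "down",
      .default = "background"
    )
  )
  attr(tab, "alpha") <- alpha
  attr(tab, "n_filtered") <- sum(!tested)
  attr(tab, "design") <- deparse(fml)
  class(tab) <- c("deg_table", class(tab))
  tab
}

#' Split a DEG table into up, down and background gene sets
#'
#' Partition rule: `padj < alpha` and positive log2FC is up, negative is
#' down; everything else (including `padj` exactly equal to `alpha`) is
#' background.
#'
#' @param table A `deg_table` from [differential_expression()].
#' @param alpha Significance threshold (strict `<`).
#' @return Named list of character vectors: `up`, `down`, `background`.
#' @export
split_by_direction <- function(table, alpha = 0.05) {
  assert_that(is.data.frame(table) &&
                all(c("gene", "log2FC", "padj") %in% names(table)),
              "`table` must have columns gene, log2FC, padj")
  sig <- table$padj < alpha
  list(
    up = table$gene[sig & table$log2FC > 0],
    down = table$gene[sig & table$log2FC < 0],
    background = table$gene[!(sig & table$log2FC != 0)]
  )
}

#' @exportS3Method generics::glance
glance.deg_table <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble::tibble(
    n_tested = nrow(x),
    n_filtered = attr(x, "n_filtered") %||% NA_integer_,
    n_up = sum(x$set == "up"),
    n_down = sum(x$set == "down"),
    alpha = alpha,
    design = attr(x, "design") %||% NA_character_
  )
}
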