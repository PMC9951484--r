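test_that("size factors follow the median-of-ratios definition", {
  # sample2 exactly doubles sample1: factors 1/sqrt(2), sqrt(2)
  m <- matrix(c(1, 2, 4, 2, 4, 8), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # identical samples: all factors equal (1)
  m2 <- cbind(s1 = c(3, 7, 1), s2 = c(3, 7, 1), s3 = c(3, 7, 1))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)), rep(1, 3))
  # an all-zero gene is excluded; remaining genes drive the factors
  m3 <- matrix(c(0, 10, 40, 0, 20, 80), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  # usable genes: (10,20) and (40,80); ratios per sample are constant
  expect_equal(unname(estimate_size_factors(m3)),
               c(exp(stats::median(log(c(10, 40)) - log(c(sqrt(200), sqrt(3200))))),
                 exp(stats::median(log(c(20, 80)) - log(c(sqrt(200), sqrt(3200)))))),
               tolerance = 1e-12)
  # degenerate input: no gene covered in all samples
  m4 <- matrix(c(0, 5, 5, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(m4), class = "decomap_degenerate_input")
})

test_that("adjust_bh matches an independent step-up implementation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_stepup_oracle(p), tolerance = 1e-12)
    # monotonicity: adjusted values preserve the raw order
    expect_true(all(diff(adjust_bh(p)[order(p)]) >= -1e-15))
  }
  expect_error(adjust_bh(c(0.1, 1.2)))
  expect_error(adjust_bh(c(-0.1, 0.5)))
})

test_that("differential expression recovers planted global effects with correct sign", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- null_config(
      seed = seed,
      de_spec = tibble::tibble(cell_type = NA_character_, n_genes = 20L,
                               lfc = 1)
    )
    ref <- simulate_reference(cfg)
    sim <- simulate_bulk_cohort(cfg, ref)
    deg <- differential_expression(sim$bulk)
    planted <- sim$truth$true_de_genes$gene
    sub <- deg[deg$gene %in% planted & deg$base_mean >= 20, ]
    # estimated log2FC is unbiased around 1 on well-expressed genes
    expect_lt(abs(stats::median(sub$log2FC) - 1), 0.3)
    hits <- hits + (mean(sub$padj < 0.05 & sub$log2FC > 0) >= 0.5)
  }
  expect_gte(hits, 4L)
})

test_that("a gene with identical counts in every sample gets p = 1 and log2FC = 0", {
  # fully identical samples: every gene is constant after normalization
  m3 <- matrix(rep(c(5L, 9L, 100L, 3L, 80L, 40L, 17L, 55L, 21L, 8L, 33L, 12L),
                   8), ncol = 8,
               dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:8)))
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                       condition = rep(c("control", "stress"), each = 4),
                       sex = rep(c("M", "F"), 4),
                       batch = rep(c("b1", "b2", "b2", "b1"), 2))
  deg <- differential_expression(gene_counts(m3, md))
  expect_true(all(deg$p == 1))
  expect_true(all(deg$log2FC == 0))
  expect_true(all(deg$set == "background"))
})

test_that("scaling one sample's counts leaves log2FC unchanged", {
  cfg <- tiny_config(seed = 13)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  deg1 <- differential_expression(sim$bulk)
  m <- sim$bulk$counts
  m[, 1] <- m[, 1] * 3L
  deg2 <- differential_expression(gene_counts(m, sim$bulk$metadata))
  shared <- intersect(deg1$gene, deg2$gene)
  expect_equal(deg1$log2FC[match(shared, deg1$gene)],
               deg2$log2FC[match(shared, deg2$gene)], tolerance = 1e-6)
})

test_that("a condition-confounded design fails naming the collinear columns", {
  cfg <- tiny_config(seed = 3,
                     batch_assignment = rep(c("b1", "b2"), each = 5))
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  expect_error(differential_expression(sim$bulk),
               regexp = "collinear", class = "decomap_design_error")
})

test_that("sex-stratified subset reuses the fit with the sex term dropped", {
  cfg <- tiny_config(seed = 7,
                     n_samples_per_group = c(control = 6L, stress = 6L),
                     sex_assignment = rep(c("M", "F"), 6),
                     batch_assignment = rep(c("b1", "b1", "b2", "b2"), 3))
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  deg_m <- differential_expression(sim$bulk, subset = list(sex = "M"))
  expect_match(attr(deg_m, "design"), "batch \\+ condition")
  expect_false(grepl("sex", attr(deg_m, "design")))
  expect_gt(nrow(deg_m), 0)
})

test_that("split_by_direction applies the strict threshold rule", {
  tab <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                        log2FC = c(2, 2, -1, 0.5),
                        padj = c(0.01, 0.20, 0.049, 0.05))
  s <- split_by_direction(tab, alpha = 0.05)
  expect_identical(s$up, "g1")
  expect_identical(s$down, "g3")
  # padj exactly at alpha goes to background; up/down/background partition
  expect_setequal(s$background, c("g2", "g4"))
  expect_length(intersect(s$up, s$down), 0)
  # empty significant set
  tab$padj <- rep(0.9, 4)
  s2 <- split_by_direction(tab)
  expect_length(s2$up, 0)
  expect_setequal(s2$background, tab$gene)
})

test_that("the moderated fit agrees with an independent moderated-t implementation", {
  skip_if_not_installed("limma")
  cfg <- null_config(seed = 5, n_genes = 800L,
                     de_spec = tibble::tibble(cell_type = NA_character_,
                                              n_genes = 20L, lfc = 1))
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  deg <- differential_expression(sim$bulk)
  # reproduce the transformed matrix and hand it to limma
  m <- sim$bulk$counts
  md <- sim$bulk$metadata
  sf <- estimate_size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  keep <- rowMeans(norm) >= 1
  normf <- norm[keep, ] * (1e6 / exp(mean(log(colSums(norm[keep, ])))))
  md$condition <- stats::relevel(factor(md$condition), "control")
  X <- stats::model.matrix(~ sex + batch + condition, md)
  fit <- limma::eBayes(limma::lmFit(log2(normf + 1), X))
  i <- match(deg$gene, rownames(normf))
  expect_equal(deg$log2FC, unname(fit$coefficients[i, "conditionstress"]),
               tolerance = 1e-12)
  expect_equal(deg$p, unname(fit$p.value[i, "conditionstress"]),
               tolerance = 1e-10)
})
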