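test_that("signature selection picks true markers and de-duplicates", {
  cfg <- tiny_config(seed = 19, marker_frac = 0.4, n_cells_per_type = 60L)
  ref <- simulate_reference(cfg)
  prof <- pseudobulk_means(ref, "class")
  pm <- compute_pem(prof)
  # 0.4 * 300 genes / 4 types = 30 markers per type; ask for 25
  sig <- build_signature(prof, pm, k = 25)
  truth <- attr(ref, "marker_table")
  sel <- sig$selection
  joined <- merge(sel, truth, by = "gene")
  frac_true <- nrow(joined) / nrow(sel)
  expect_gte(frac_true, 0.95)
  # attributed type agrees with the planted home type for true markers
  expect_gte(mean(joined$cell_type.x == joined$cell_type.y), 0.95)
  # no duplicated genes even though types could share top genes
  expect_false(anyDuplicated(sig$selection$gene) > 0)
  expect_warning(build_signature(prof, pm, k = 1e6), regexp = "capped")
})

test_that("noiseless mixtures are recovered to numerical precision", {
  cfg <- tiny_config(seed = 23)
  ref <- simulate_reference(cfg)
  prof <- pseudobulk_means(ref, "class")
  pm <- compute_pem(prof)
  sig <- build_signature(prof, pm, k = 25)
  cpm_full <- sweep(prof$X, 2, colSums(prof$X), "/") * 1e6
  f_true <- rbind(c(0.6, 0.4, 0, 0), c(0.1, 0.2, 0.3, 0.4),
                  c(0, 0, 0, 1), c(0.25, 0.25, 0.25, 0.25))
  colnames(f_true) <- colnames(prof$X)
  bulk <- cpm_full %*% t(f_true)
  colnames(bulk) <- paste0("mix", 1:4)
  fr <- estimate_fractions(bulk, sig)
  expect_lt(max(abs(fr$fractions - f_true)), 1e-6)
  # a pure type profile yields fraction 1 for that type
  expect_equal(unname(fr$fractions[3, ]), c(0, 0, 0, 1), tolerance = 1e-9)
  # rows sum to one, non-negative
  expect_equal(unname(rowSums(fr$fractions)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(fr$fractions >= 0))
})

test_that("fraction estimates are invariant to bulk library scaling", {
  cfg <- tiny_config(seed = 29)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  prof <- pseudobulk_means(ref, "class")
  sig <- build_signature(prof, compute_pem(prof), k = 25)
  f1 <- estimate_fractions(sim$bulk$counts, sig)
  m2 <- sim$bulk$counts * 7L
  f2 <- estimate_fractions(m2, sig)
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-9)
})

test_that("NB-noised mixtures at generator defaults are recovered accurately", {
  maes <- numeric(3)
  for (seed in 1:3) {
    cfg <- simulation_config(seed = seed)
    ref <- simulate_reference(cfg)
    sim <- simulate_bulk_cohort(cfg, ref)
    prof <- pseudobulk_means(ref, "class")
    sig <- build_signature(prof, compute_pem(prof), k = 50)
    fr <- estimate_fractions(sim$bulk, sig)
    truth <- sim$truth$true_fractions[rownames(fr$fractions),
                                      colnames(fr$fractions)]
    maes[seed] <- mean(abs(fr$fractions - truth))
  }
  expect_lt(mean(maes), 0.05)
})

test_that("a rank-deficient signature fails naming the collinear types", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(5, 1, 0, 2))
  rownames(X) <- paste0("g", 1:4)
  sig <- structure(list(X = X, selection = NULL, k = 1),
                   class = "signature_matrix")
  bulk <- matrix(c(10, 20, 30, 40), ncol = 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
  expect_error(estimate_fractions(bulk, sig), regexp = "collinear",
               class = "decomap_design_error")
})

test_that("group comparison flags shifted types and not identical groups", {
  # identical groups: t = 0, p = 1
  fr <- structure(list(
    fractions = matrix(rep(c(0.6, 0.4), each = 6), 6, 2,
                       dimnames = list(paste0("s", 1:6), c("A", "B"))),
    residuals = setNames(rep(0, 6), paste0("s", 1:6)),
    metadata = tibble::tibble(sample_id = paste0("s", 1:6),
                              condition = rep(c("control", "stress"), 3))
  ), class = "fraction_table")
  cmp <- compare_fractions(fr)
  expect_equal(cmp$p, c(1, 1))
  expect_equal(cmp$t, c(0, 0))
  # single-sample group errors
  bad_md <- tibble::tibble(sample_id = paste0("s", 1:6),
                           condition = c("control", rep("stress", 5)))
  expect_error(compare_fractions(fr, metadata = bad_md),
               regexp = "2 samples")
  # planted neuroblast shift at defaults is detected
  cfg <- simulation_config(seed = 31)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  prof <- pseudobulk_means(ref, "class")
  sig <- build_signature(prof, compute_pem(prof), k = 50)
  est <- estimate_fractions(sim$bulk, sig)
  cmp2 <- compare_fractions(est)
  nb <- cmp2[cmp2$cell_type == "neuroblast", ]
  expect_lt(nb$p, 0.05)
  expect_gt(nb$difference, 0)
})

test_that("tidy() joins fractions with sample metadata", {
  cfg <- tiny_config(seed = 37)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  prof <- pseudobulk_means(ref, "class")
  sig <- build_signature(prof, compute_pem(prof), k = 10)
  fr <- estimate_fractions(sim$bulk, sig)
  td <- tidy(fr)
  expect_true(all(c("sample_id", "cell_type", "fraction", "condition")
                  %in% names(td)))
  expect_equal(nrow(td), nrow(fr$fractions) * ncol(fr$fractions))
})
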