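test_that("generators are deterministic: identical seed and config give bit-identical output", {
  cfg <- tiny_config(seed = 11)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$cell_metadata, r2$cell_metadata)
  b1 <- simulate_bulk_cohort(cfg, r1)
  b2 <- simulate_bulk_cohort(cfg, r2)
  expect_identical(b1$bulk$counts, b2$bulk$counts)
  expect_identical(b1$truth$true_de_genes, b2$truth$true_de_genes)
  v1 <- simulate_ish_volume(cfg)
  v2 <- simulate_ish_volume(cfg)
  expect_identical(v1$energy, v2$energy)
  # a different seed changes the draws
  expect_false(identical(simulate_reference(tiny_config(seed = 12))$counts,
                         r1$counts))
})

test_that("reference carries all configured classes and non-negative integer counts", {
  cfg <- simulation_config(seed = 2, n_genes = 200, n_cells_per_type = 5)
  ref <- simulate_reference(cfg)
  expect_setequal(unique(ref$cell_metadata$class), cfg$cell_types)
  expect_length(unique(ref$cell_metadata$class), 16L)
  expect_true(all(ref$counts >= 0))
  expect_true(all(ref$counts == floor(ref$counts)))
})

test_that("marker_fold = 1 plants no signal: PEM is ~0 everywhere", {
  cfg <- tiny_config(seed = 5, marker_fold = 1, n_cells_per_type = 200L)
  ref <- simulate_reference(cfg)
  pem <- compute_pem(pseudobulk_means(ref, "class", min_cells = 1))
  # only sampling noise remains; genes with decent expression sit near 0
  expressed <- rowMeans(ref$counts) > 5
  expect_lt(max(abs(pem$pem[expressed, ])), 0.25)
  expect_lt(stats::median(abs(pem$pem[expressed, ])), 0.05)
})

test_that("per-type empirical means recover the configured profiles", {
  cfg <- simulation_config(
    seed = 8, n_genes = 400, n_cell_types = 3,
    cell_types = c("a", "b", "c"),
    base_fractions = c(a = 0.3, b = 0.3, c = 0.4),
    n_cells_per_type = 2000,
    de_spec = tibble::tibble(cell_type = character(), n_genes = integer(),
                             lfc = numeric()),
    fraction_shift = c()
  )
  ref <- simulate_reference(cfg)
  # expected mean count of gene g in type t is profile * mean depth
  expected <- ref$profiles * cfg$cell_depth_mean
  for (tp in cfg$cell_types) {
    obs <- rowMeans(ref$counts[, ref$cell_metadata$class == tp])
    hi <- expected[, tp] >= 1
    rel <- abs(obs[hi] - expected[hi, tp]) / expected[hi, tp]
    expect_lt(stats::quantile(rel, 0.99), 0.05 * 3) # 99% comfortably close
    expect_lt(stats::median(rel), 0.05)
  }
})

test_that("noiseless bulk expectation equals the fraction-weighted profile sum", {
  cfg <- tiny_config(seed = 3)
  ref <- simulate_reference(cfg)
  f <- cfg$base_fractions
  mix <- expected_bulk_mixture(ref, f)
  # independent closed form with explicit loops
  manual <- numeric(nrow(ref$profiles))
  for (t in names(f)) manual <- manual + f[[t]] * ref$profiles[, t]
  manual <- manual / sum(manual)
  expect_equal(unname(mix), unname(manual), tolerance = 1e-12)
})

test_that("cell-type-restricted DE is attenuated toward fraction-weighted bulk fold changes", {
  cfg <- tiny_config(seed = 4)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  de <- sim$truth$true_de_genes
  rg <- de[de$cell_type == "radial_glia", ]
  f <- cfg$base_fractions
  mu_c <- expected_bulk_mixture(ref, f)
  mu_s <- expected_bulk_mixture(ref, f, de_genes = rg, stress = TRUE)
  # undo the sum-to-one normalization so the per-gene fold is exact
  unnorm_c <- as.vector(ref$profiles[, names(f)] %*% f)
  names(unnorm_c) <- rownames(ref$profiles)
  fold_raw <- vapply(rg$gene, function(g) {
    share <- f[["radial_glia"]] * ref$profiles[g, "radial_glia"]
    rest <- unnorm_c[[g]] - share
    (share * 2^rg$lfc[1] + rest) / (share + rest)
  }, numeric(1))
  extra <- sum(f[["radial_glia"]] * ref$profiles[rg$gene, "radial_glia"] *
                 (2^rg$lfc[1] - 1))
  tot_ratio <- sum(unnorm_c) / (sum(unnorm_c) + extra)
  # planted 2^0.5 within a 10% cell type: bulk fold sits strictly inside
  # (1, 2^0.5), far below the naive fold of 2
  expect_true(all(fold_raw > 1))
  expect_true(all(fold_raw < 2^0.5))
  # and the generator's normalized expectation matches that closed form
  # exactly once the global renormalization is accounted for
  fold_gen <- mu_s[rg$gene] / mu_c[rg$gene]
  expect_equal(unname(fold_gen), unname(fold_raw) * tot_ratio,
               tolerance = 1e-9)
})

test_that("fraction_shift is bookkept exactly in the ground truth", {
  cfg <- tiny_config(seed = 6,
                     fraction_shift = c(neuron = -0.03, neuroblast = 0.03))
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  fr <- sim$truth$true_fractions
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-12)
  shifted <- c(cfg$base_fractions["neuron"] - 0.03,
               cfg$base_fractions["neuroblast"] + 0.03)
  expect_equal(fr["strs_01", c("neuron", "neuroblast")], shifted,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fr["ctrl_01", ], cfg$base_fractions, tolerance = 1e-12)
  # every planted DE gene exists in the bulk matrix
  expect_true(all(sim$truth$true_de_genes$gene %in% rownames(sim$bulk$counts)))
})

test_that("de_spec naming an unknown cell type is a configuration error", {
  expect_error(
    tiny_config(de_spec = tibble::tibble(cell_type = "astrocyte",
                                         n_genes = 5L, lfc = 1)),
    class = "decomap_config_error"
  )
  expect_error(simulation_config(nb_dispersion = 0),
               class = "decomap_config_error")
  expect_error(simulation_config(cell_depth_mean = -1),
               class = "decomap_config_error")
})

test_that("ish volume elevates home-region energy by the configured fold", {
  cfg <- tiny_config(seed = 9)
  cfg$volume$noise_cv <- 0.3
  vol <- simulate_ish_volume(cfg)
  hm <- vol$home_map
  g <- hm$gene[1]
  home <- hm$region[1]
  e <- vol$energy[, match(g, vol$genes)]
  in_home <- vol$voxels$region == home
  ratio <- mean(e[in_home]) / mean(e[!in_home])
  expect_gt(ratio, cfg$volume$fold * 0.8)
  expect_lt(ratio, cfg$volume$fold * 1.2)
  expect_true(all(vol$energy >= 0))
  # fold 1 for all genes: region means equal in expectation
  cfg2 <- tiny_config(seed = 9)
  cfg2$volume$fold <- 1
  cfg2$volume$noise_cv <- 0
  vol2 <- simulate_ish_volume(cfg2)
  expect_equal(max(vol2$energy) - min(vol2$energy), 0)
})

test_that("region voxel counts exceeding the grid are rejected", {
  cfg <- tiny_config(seed = 1)
  cfg$volume$dim <- c(4L, 4L, 4L)
  cfg$volume$regions <- c(a = 40, b = 40) # 80 > 64 voxels
  expect_error(simulate_ish_volume(cfg), class = "decomap_config_error")
})

test_that("yaml config round-trips and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_genes: 120", "n_cell_types: 3",
               "cell_types: [a, b, c]",
               "base_fractions: {a: 0.2, b: 0.3, c: 0.5}",
               "n_samples_per_group: {control: 3, stress: 3}",
               "de_spec:",
               "  - {cell_type: a, n_genes: 5, lfc: 1.0}"), path)
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$n_genes, 120L)
  expect_equal(cfg$de_spec$lfc, 1.0)
  writeLines(c("seed: 5", "frobnicate: yes"), path)
  expect_error(read_simulation_config(path), class = "decomap_config_error")
})
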