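#' Default cell classes of the fetal-brain reference emulation
#'
#' Sixteen major cell classes of the embryonic (E15.5) mouse brain, dominated
#' by neurons, neuroblasts and glioblasts, with radial glia (neural stem
#' cells) a small but pivotal population.
#' @keywords internal
default_cell_types <- function() {
  c("neuron", "neuroblast", "glioblast", "radial_glia",
    "mesenchyme", "ependymal", "microglia", "oligodendrocyte_precursor",
    "cajal_retzius", "choroid_plexus", "vascular", "pericyte",
    "endothelial", "blood", "immune", "olfactory_ensheathing")
}

default_base_fractions <- function(cell_types = default_cell_types()) {
  fr <- setNames(rep(NA_real_, length(cell_types)), cell_types)
  known <- c(neuron = 0.5394, neuroblast = 0.2423, glioblast = 0.1375,
             radial_glia = 0.021)
  known <- known[names(known) %in% cell_types]
  fr[names(known)] <- known
  rest <- is.na(fr)
  fr[rest] <- (1 - sum(known)) / sum(rest)
  fr
}

default_de_spec <- function() {
  tibble::tibble(
    cell_type = c("radial_glia", "neuron", "ependymal"),
    n_genes   = c(40L, 40L, 15L),
    lfc       = c(0.5, -0.5, -0.5)
  )
}

default_volume_spec <- function() {
  list(
    dim = c(20L, 16L, 12L),
    regions = c(cortical_plate = 0.18, hippocampal_formation = 0.10,
                ventral_forebrain = 0.22, thalamus = 0.10,
                midbrain = 0.20, hindbrain = 0.20),
    fold = 10,
    background_energy = 1,
    noise_cv = 0.5,
    n_panel = 40L
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration driving all three synthetic-data
#' generators. Defaults emulate the study design the package targets: a
#' two-batch bulk cohort of 9 control vs 7 stress animals with both sexes, a
#' labeled single-cell reference with 16 cell classes whose fractions are
#' dominated by neurons (53.94%), neuroblasts (24.23%) and glioblasts
#' (13.75%), mild planted condition effects (|log2FC| = 0.5) restricted to
#' the home cell types of the affected genes, and a stress-associated
#' fraction shift from neurons toward neuroblasts.
#'
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output from every generator.
#' @param n_genes Number of genes in the shared gene universe.
#' @param n_cell_types Number of cell classes (>= 2).
#' @param cell_types Character vector of class names (length `n_cell_types`).
#' @param n_cells_per_type Cells simulated per class in the reference.
#' @param base_fractions Named probability vector over `cell_types`; must sum
#'   to 1 (renormalized if within 1e-6).
#' @param n_samples_per_group Named integer vector `c(control=, stress=)`.
#' @param sex_assignment,batch_assignment Optional label vectors over the
#'   samples (control samples first, then stress); defaults interleave sexes
#'   and batches within each condition so the design is full rank.
#' @param marker_frac Fraction of genes made cell-type-specific markers.
#' @param marker_fold Fold elevation of a marker in its home class.
#' @param de_spec Tibble with columns `cell_type` (NA for global,
#'   non-cell-type-restricted differential expression), `n_genes`, `lfc`
#'   (log2 fold change, stress vs control). Cell-type-restricted entries draw
#'   their genes from that class's markers.
#' @param fraction_shift Named numeric vector of additive changes to the
#'   stress group's cell fractions (renormalized after clipping at 0).
#'   Default moves 0.03 from neurons to neuroblasts when those classes
#'   exist; pass `c()` for no shift.
#' @param nb_dispersion Negative binomial dispersion of bulk counts; the
#'   parameterization is mean/dispersion with
#'   variance = mu + mu^2 / dispersion.
#' @param sc_dispersion Same parameterization for single-cell counts.
#' @param library_size_mean,library_size_cv Log-normal model of per-sample
#'   sequencing depth (expected total counts and coefficient of variation).
#' @param cell_depth_mean,cell_depth_cv Log-normal model of per-cell depth.
#' @param batch_effect_sd,sex_effect_sd Standard deviations (natural-log
#'   scale) of the gene-wise nuisance multipliers attached to batch and sex,
#'   independent of condition.
#' @param volume List configuring the voxelized expression volume: `dim`
#'   (3 integers), `regions` (named proportions or voxel counts), `fold`,
#'   `background_energy`, `noise_cv`, `n_panel`.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_cell_types = 16L,
                              cell_types = NULL,
                              n_cells_per_type = 100L,
                              base_fractions = NULL,
                              n_samples_per_group = c(control = 9L, stress = 7L),
                              sex_assignment = NULL,
                              batch_assignment = NULL,
                              marker_frac = 0.4,
                              marker_fold = 8,
                              de_spec = default_de_spec(),
                              fraction_shift = NULL,
                              nb_dispersion = 20,
                              sc_dispersion = 2,
                              library_size_mean = 5e5,
                              library_size_cv = 0.2,
                              cell_depth_mean = 5000,
                              cell_depth_cv = 0.3,
                              batch_effect_sd = 0.1,
                              sex_effect_sd = 0.1,
                              volume = default_volume_spec()) {
  assert_that(is_count(seed), "`seed` must be a non-negative integer")
  assert_that(is_count(n_genes) && n_genes >= 10, "`n_genes` must be >= 10")
  assert_that(is_count(n_cell_types) && n_cell_types >= 2,
              "`n_cell_types` must be >= 2",
              class = "decomap_config_error")
  if (is.null(cell_types)) {
    cell_types <- default_cell_types()
    if (n_cell_types <= length(cell_types)) {
      cell_types <- cell_types[seq_len(n_cell_types)]
    } else {
      cell_types <- c(cell_types,
                      sprintf("type_%02d", seq_len(n_cell_types - length(cell_types))))
    }
  }
  assert_that(length(cell_types) == n_cell_types && !anyDuplicated(cell_types),
              "`cell_types` must be unique and of length `n_cell_types`")
  if (is.null(base_fractions)) base_fractions <- default_base_fractions(cell_types)
  assert_that(is.numeric(base_fractions) &&
                setequal(names(base_fractions), cell_types),
              "`base_fractions` must be named over `cell_types`")
  base_fractions <- base_fractions[cell_types]
  assert_that(all(base_fractions >= 0),
              "`base_fractions` must be non-negative",
              class = "decomap_config_error")
  assert_that(abs(sum(base_fractions) - 1) < 1e-6,
              "`base_fractions` must sum to 1",
              class = "decomap_config_error")
  base_fractions <- base_fractions / sum(base_fractions)

  assert_that(is.numeric(n_samples_per_group) &&
                setequal(names(n_samples_per_group), c("control", "stress")) &&
                all(n_samples_per_group >= 1),
              "`n_samples_per_group` must be c(control=, stress=), each >= 1")
  n_samples_per_group <- as.integer(n_samples_per_group[c("control", "stress")])
  names(n_samples_per_group) <- c("control", "stress")
  n_samples <- sum(n_samples_per_group)
  if (is.null(sex_assignment)) {
    sex_assignment <- c(rep_len(c("M", "F"), n_samples_per_group["control"]),
                        rep_len(c("M", "F"), n_samples_per_group["stress"]))
  }
  if (is.null(batch_assignment)) {
    batch_assignment <- c(rep_len(c("b1", "b2"), n_samples_per_group["control"]),
                          rep_len(c("b2", "b1"), n_samples_per_group["stress"]))
  }
  assert_that(length(sex_assignment) == n_samples,
              "`sex_assignment` must have one label per sample")
  assert_that(length(batch_assignment) == n_samples,
              "`batch_assignment` must have one label per sample")

  assert_that(marker_frac >= 0 && marker_frac <= 1,
              "`marker_frac` must lie in [0, 1]")
  assert_that(marker_fold >= 1, "`marker_fold` must be >= 1")
  de_spec <- tibble::as_tibble(de_spec)
  if (nrow(de_spec)) {
    assert_that(all(c("cell_type", "n_genes", "lfc") %in% names(de_spec)),
                "`de_spec` needs columns cell_type, n_genes, lfc")
    assert_that(all(de_spec$n_genes >= 1), "`de_spec$n_genes` must be >= 1")
    bad <- setdiff(de_spec$cell_type[!is.na(de_spec$cell_type)], cell_types)
    assert_that(length(bad) == 0,
                paste("`de_spec` names unknown cell types:",
                      paste(bad, collapse = ", ")),
                class = "decomap_config_error")
  }
  if (is.null(fraction_shift)) {
    # study-like default: neurons decrease, neuroblasts accumulate
    fraction_shift <- c(neuron = -0.03, neuroblast = 0.03)
    fraction_shift <- fraction_shift[names(fraction_shift) %in% cell_types]
  }
  if (length(fraction_shift)) {
    bad <- setdiff(names(fraction_shift), cell_types)
    assert_that(length(bad) == 0,
                paste("`fraction_shift` names unknown cell types:",
                      paste(bad, collapse = ", ")),
                class = "decomap_config_error")
  }
  for (nm in c("nb_dispersion", "sc_dispersion", "library_size_mean",
               "cell_depth_mean")) {
    assert_that(get(nm) > 0, paste0("`", nm, "` must be positive"),
                class = "decomap_config_error")
  }
  assert_that(library_size_cv >= 0 && cell_depth_cv >= 0 &&
                batch_effect_sd >= 0 && sex_effect_sd >= 0,
              "noise scales must be non-negative",
              class = "decomap_config_error")

  volume <- utils::modifyList(default_volume_spec(), volume %||% list())
  assert_that(length(volume$dim) == 3 && all(volume$dim >= 1),
              "`volume$dim` must be three positive integers")
  assert_that(length(volume$regions) >= 2,
              "`volume$regions` must name at least two regions",
              class = "decomap_config_error")
  assert_that(volume$fold >= 1 && volume$background_energy > 0 &&
                volume$noise_cv >= 0,
              "volume fold/background/noise settings invalid",
              class = "decomap_config_error")

  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_cell_types = as.integer(n_cell_types), cell_types = cell_types,
    n_cells_per_type = as.integer(n_cells_per_type),
    base_fractions = base_fractions,
    n_samples_per_group = n_samples_per_group,
    sex_assignment = sex_assignment, batch_assignment = batch_assignment,
    marker_frac = marker_frac, marker_fold = marker_fold,
    de_spec = de_spec, fraction_shift = fraction_shift,
    nb_dispersion = nb_dispersion, sc_dispersion = sc_dispersion,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    cell_depth_mean = cell_depth_mean, cell_depth_cv = cell_depth_cv,
    batch_effect_sd = batch_effect_sd, sex_effect_sd = sex_effect_sd,
    volume = volume
  ), class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Every field of [simulation_config()] is addressable; unknown keys are
#' rejected.
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  assert_that(file.exists(path), paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")),
              class = "decomap_config_error")
  for (nm in c("base_fractions", "fraction_shift")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$n_samples_per_group)) {
    raw$n_samples_per_group <- unlist(raw$n_samples_per_group)
  }
  if (!is.null(raw$de_spec)) {
    raw$de_spec <- dplyr::bind_rows(lapply(raw$de_spec, function(row) {
      tibble::tibble(cell_type = row$cell_type %||% NA_character_,
                     n_genes = as.integer(row$n_genes), lfc = row$lfc)
    }))
  }
  if (!is.null(raw$volume$regions)) raw$volume$regions <- unlist(raw$volume$regions)
  do.call(simulation_config, raw)
}

# internal: gene ids, marker assignment and relative per-type profiles.
# Deterministic given the RNG state; called under set.seed(config$seed).
build_profiles <- function(config) {
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  base <- stats::rlnorm(config$n_genes, meanlog = log(5), sdlog = 1.2)
  n_marker <- floor(config$marker_frac * config$n_genes)
  marker_idx <- if (n_marker > 0) sort(sample.int(config$n_genes, n_marker)) else integer()
  home <- rep_len(config$cell_types, length(marker_idx))
  # shuffle the round-robin so home types are not tied to gene order
  home <- sample(home)
  P <- matrix(base, nrow = config$n_genes, ncol = config$n_cell_types,
              dimnames = list(genes, config$cell_types))
  if (length(marker_idx)) {
    P[cbind(marker_idx, match(home, config$cell_types))] <-
      base[marker_idx] * config$marker_fold
  }
  marker_table <- tibble::tibble(
    gene = genes[marker_idx],
    cell_type = home
  )
  list(genes = genes, profiles = P, marker_table = marker_table)
}

#' Simulate a labeled single-cell reference
#'
#' Draws negative binomial counts for `n_cells_per_type` cells per class
#' around cell-type expression profiles in which a configurable fraction of
#' genes are markers, elevated `marker_fold`-fold in their home class.
#' Per-cell depth is log-normal; counts are NB(mean = relative profile x
#' depth, dispersion = `sc_dispersion`). Neuron and neuroblast classes are
#' refined into two subclasses each so both label granularities exist.
#'
#' @param config A [simulation_config()].
#' @return A [single_cell_reference()] whose `profiles` element carries the
#'   ground-truth genes x types relative expression profiles and with
#'   attribute `marker_table` (tibble gene, cell_type).
#' @export
simulate_reference <- function(config) {
  assert_that(inherits(config, "simulation_config"),
              "`config` must be a simulation_config")
  set.seed(config$seed)
  pr <- build_profiles(config)
  P_rel <- sweep(pr$profiles, 2, colSums(pr$profiles), "/")
  n_cells <- config$n_cells_per_type * config$n_cell_types
  classes <- rep(config$cell_types, each = config$n_cells_per_type)
  cell_ids <- sprintf("cell_%06d", seq_len(n_cells))
  depth <- rlnorm_mean_cv(n_cells, config$cell_depth_mean, config$cell_depth_cv)
  mu <- sweep(P_rel[, classes, drop = FALSE], 2, depth, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = config$sc_dispersion),
    nrow = config$n_genes,
    dimnames = list(pr$genes, cell_ids)
  )
  split2 <- function(cls, a, b) {
    idx <- classes == cls
    out <- rep(NA_character_, sum(idx))
    out[seq_along(out) %% 2L == 1L] <- a
    out[is.na(out)] <- b
    out
  }
  subclass <- classes
  if ("neuron" %in% classes) {
    subclass[classes == "neuron"] <-
      split2("neuron", "neuron_glutamatergic", "neuron_gabaergic")
  }
  if ("neuroblast" %in% classes) {
    subclass[classes == "neuroblast"] <-
      split2("neuroblast", "neuroblast_dorsal", "neuroblast_ventral")
  }
  ref <- single_cell_reference(
    counts,
    tibble::tibble(cell_id = cell_ids, class = classes, subclass = subclass),
    profiles = P_rel
  )
  attr(ref, "marker_table") <- pr$marker_table
  ref
}

# internal: stress-group fractions after an additive shift, clipped and
# renormalized
shift_fractions <- function(base, shift) {
  f <- base
  if (length(shift)) f[names(shift)] <- f[names(shift)] + shift
  f <- pmax(f, 0)
  f / sum(f)
}

#' Simulate a bulk RNA-seq cohort as a mixture of reference profiles
#'
#' Each sample's expected expression is the fraction-weighted sum of the
#' reference's cell-type profiles, multiplied by gene-wise log-normal batch
#' and sex nuisance effects (independent of condition), with planted
#' condition effects applied to differential genes. Cell-type-restricted
#' differential expression scales only the contribution of the gene's home
#' class, so its bulk fold change is attenuated by that class's fraction —
#' the mild bulk effect sizes (|log2FC| < 1) the design emulates. Counts are
#' negative binomial around the expectation scaled to a log-normal library
#' size.
#'
#' @param config A [simulation_config()].
#' @param reference A [single_cell_reference()] from [simulate_reference()]
#'   (must carry `profiles` covering every configured cell type).
#' @return List with elements `bulk` (a [gene_counts()]) and `truth` (list:
#'   `true_fractions` samples x types matrix with rows summing to 1,
#'   `true_de_genes` tibble gene/cell_type/lfc/direction, `marker_table`).
#' @export
simulate_bulk_cohort <- function(config, reference) {
  assert_that(inherits(config, "simulation_config"),
              "`config` must be a simulation_config")
  assert_that(inherits(reference, "single_cell_reference") &&
                !is.null(reference$profiles),
              "`reference` must be a simulated single_cell_reference with profiles")
  P_rel <- reference$profiles
  assert_that(all(config$cell_types %in% colnames(P_rel)),
              "reference profiles do not cover all configured cell types",
              class = "decomap_config_error")
  P_rel <- P_rel[, config$cell_types, drop = FALSE]
  genes <- rownames(P_rel)
  marker_table <- attr(reference, "marker_table")

  set.seed(config$seed + 1L)
  n_ctrl <- config$n_samples_per_group[["control"]]
  n_strs <- config$n_samples_per_group[["stress"]]
  n_samples <- n_ctrl + n_strs
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(n_ctrl)),
                  sprintf("strs_%02d", seq_len(n_strs)))
  condition <- rep(c("control", "stress"), c(n_ctrl, n_strs))
  metadata <- tibble::tibble(sample_id = sample_ids, condition = condition,
                             sex = config$sex_assignment,
                             batch = config$batch_assignment)

  f_ctrl <- config$base_fractions
  f_strs <- shift_fractions(f_ctrl, config$fraction_shift)
  fr <- rbind(matrix(f_ctrl, n_ctrl, length(f_ctrl), byrow = TRUE),
              matrix(f_strs, n_strs, length(f_strs), byrow = TRUE))
  dimnames(fr) <- list(sample_ids, config$cell_types)

  # pick planted DE genes: restricted entries draw from the home class's
  # markers, global entries (cell_type = NA) from non-marker genes
  taken <- character()
  de_rows <- list()
  if (nrow(config$de_spec)) {
    for (i in seq_len(nrow(config$de_spec))) {
      row <- config$de_spec[i, ]
      if (is.na(row$cell_type)) {
        pool <- setdiff(setdiff(genes, marker_table$gene), taken)
      } else {
        pool <- setdiff(marker_table$gene[marker_table$cell_type == row$cell_type],
                        taken)
      }
      assert_that(length(pool) >= row$n_genes,
                  paste0("de_spec row ", i, ": not enough eligible genes (",
                         length(pool), " < ", row$n_genes, ")"),
                  class = "decomap_config_error")
      chosen <- sample(pool, row$n_genes)
      taken <- c(taken, chosen)
      de_rows[[i]] <- tibble::tibble(
        gene = chosen,
        cell_type = row$cell_type %||% NA_character_,
        lfc = row$lfc,
        direction = ifelse(row$lfc > 0, "up", "down")
      )
    }
  }
  true_de <- if (length(de_rows)) dplyr::bind_rows(de_rows) else
    tibble::tibble(gene = character(), cell_type = character(),
                   lfc = numeric(), direction = character())

  # expected mixture per sample, with condition effects on stress samples
  contrib <- P_rel # genes x types (columns sum to 1)
  batch_levels <- unique(config$batch_assignment)
  sex_levels <- unique(config$sex_assignment)
  batch_mult <- matrix(exp(stats::rnorm(length(genes) * length(batch_levels),
                                        0, config$batch_effect_sd)),
                       nrow = length(genes),
                       dimnames = list(genes, batch_levels))
  sex_mult <- matrix(exp(stats::rnorm(length(genes) * length(sex_levels),
                                      0, config$sex_effect_sd)),
                     nrow = length(genes),
                     dimnames = list(genes, sex_levels))
  lib <- rlnorm_mean_cv(n_samples, config$library_size_mean,
                        config$library_size_cv)

  counts <- matrix(0L, length(genes), n_samples,
                   dimnames = list(genes, sample_ids))
  for (j in seq_len(n_samples)) {
    f <- fr[j, ]
    W <- contrib %*% diag(f, nrow = length(f)) # genes x types contributions
    colnames(W) <- config$cell_types
    if (condition[j] == "stress" && nrow(true_de)) {
      for (k in seq_len(nrow(true_de))) {
        g <- true_de$gene[k]
        fold <- 2^true_de$lfc[k]
        if (is.na(true_de$cell_type[k])) {
          W[g, ] <- W[g, ] * fold
        } else {
          W[g, true_de$cell_type[k]] <- W[g, true_de$cell_type[k]] * fold
        }
      }
    }
    mu <- rowSums(W) * batch_mult[, metadata$batch[j]] * sex_mult[, metadata$sex[j]]
    mu <- mu / sum(mu) * lib[j]
    counts[, j] <- stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion)
  }

  list(
    bulk = gene_counts(counts, metadata),
    truth = list(true_fractions = fr, true_de_genes = true_de,
                 marker_table = marker_table)
  )
}

#' Expected bulk mixture without noise
#'
#' Closed-form expectation of [simulate_bulk_cohort()] for one condition:
#' the fraction-weighted profile sum with planted condition effects applied,
#' no nuisance effects, normalized to relative expression. Used as the
#' mixture-consistency oracle and for constructing noiseless deconvolution
#' inputs.
#'
#' @param reference A simulated [single_cell_reference()].
#' @param fractions Named fraction vector over profile columns.
#' @param de_genes Optional tibble like `truth$true_de_genes`.
#' @param stress Apply the planted effects (TRUE) or not.
#' @return Named numeric vector over genes summing to 1.
#' @export
expected_bulk_mixture <- function(reference, fractions, de_genes = NULL,
                                  stress = FALSE) {
  P_rel <- reference$profiles[, names(fractions), drop = FALSE]
  W <- P_rel %*% diag(fractions, nrow = length(fractions))
  colnames(W) <- names(fractions)
  if (stress && !is.null(de_genes) && nrow(de_genes)) {
    for (k in seq_len(nrow(de_genes))) {
      g <- de_genes$gene[k]
      fold <- 2^de_genes$lfc[k]
      if (is.na(de_genes$cell_type[k])) W[g, ] <- W[g, ] * fold
      else W[g, de_genes$cell_type[k]] <- W[g, de_genes$cell_type[k]] * fold
    }
  }
  mu <- rowSums(W)
  mu / sum(mu)
}

#' Simulate a voxelized ISH-like expression volume
#'
#' Partitions a 3-D voxel grid into labeled brain regions (contiguous blocks
#' in x-fastest linear order) and assigns each panel gene a home region where
#' its expression energy is elevated by a stated fold over background.
#' Energies are gamma-distributed around their mean (strictly positive) with
#' coefficient of variation `volume$noise_cv`; `noise_cv = 0` gives the
#' exact means. The z axis is the lateral-to-medial direction used for
#' sagittal sections.
#'
#' @param config A [simulation_config()]; `config$volume` controls grid,
#'   regions, fold and noise.
#' @param home_map Optional tibble (gene, region, fold) pinning specific
#'   genes to home regions — used by the pipeline to home up- and
#'   down-regulated modules to different regions. When `NULL`, a generic
#'   panel of `volume$n_panel` genes is homed round-robin over the regions.
#' @return An object of class `expression_volume`: list with `dim`, `voxels`
#'   (tibble x, y, z, region; 0-based coordinates), `energy` (voxels x genes
#'   matrix), `genes`, `home_map`.
#' @export
simulate_ish_volume <- function(config, home_map = NULL) {
  assert_that(inherits(config, "simulation_config"),
              "`config` must be a simulation_config")
  vol <- config$volume
  set.seed(config$seed + 2L)
  dims <- as.integer(vol$dim)
  n_vox <- prod(dims)
  regions <- vol$regions
  if (all(regions == floor(regions)) && sum(regions) > 1 + 1e-9) {
    # explicit voxel counts
    assert_that(sum(regions) <= n_vox,
                "region voxel counts exceed the grid size",
                class = "decomap_config_error")
    counts <- as.integer(regions)
    if (sum(counts) < n_vox) {
      counts[length(counts)] <- counts[length(counts)] + (n_vox - sum(counts))
    }
  } else {
    assert_that(abs(sum(regions) - 1) < 1e-6,
                "region proportions must sum to 1",
                class = "decomap_config_error")
    counts <- floor(regions * n_vox)
    rem <- n_vox - sum(counts)
    if (rem > 0) {
      extra <- order(regions * n_vox - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
  }
  region_lab <- rep(names(regions), counts)

  coords <- arrayInd(seq_len(n_vox), .dim = dims)
  voxels <- tibble::tibble(x = coords[, 1] - 1L, y = coords[, 2] - 1L,
                           z = coords[, 3] - 1L, region = region_lab)

  if (is.null(home_map)) {
    genes <- sprintf("panel_g%03d", seq_len(vol$n_panel))
    home_map <- tibble::tibble(
      gene = genes,
      region = rep_len(names(regions), length(genes)),
      fold = vol$fold
    )
  } else {
    home_map <- tibble::as_tibble(home_map)
    assert_that(all(c("gene", "region") %in% names(home_map)),
                "`home_map` needs columns gene and region")
    if (!"fold" %in% names(home_map)) home_map$fold <- vol$fold
    bad <- setdiff(home_map$region[!is.na(home_map$region)], names(regions))
    assert_that(length(bad) == 0,
                paste("home_map names unknown regions:",
                      paste(bad, collapse = ", ")),
                class = "decomap_config_error")
    genes <- home_map$gene
  }
  energy <- matrix(0, n_vox, length(genes),
                   dimnames = list(NULL, genes))
  for (k in seq_along(genes)) {
    base <- rep(vol$background_energy, n_vox)
    if (!is.na(home_map$region[k])) {
      base[region_lab == home_map$region[k]] <-
        vol$background_energy * home_map$fold[k]
    }
    energy[, k] <- rgamma_mean_cv(n_vox, base, vol$noise_cv)
  }
  structure(list(dim = dims, voxels = voxels, energy = energy,
                 genes = genes, home_map = home_map),
            class = "expression_volume")
}

#' @export
print.expression_volume <- function(x, ...) {
  cat("<expression_volume> grid ", paste(x$dim, collapse = " x "),
      " (", nrow(x$voxels), " voxels), ",
      length(unique(x$voxels$region)), " regions, ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}
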