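#' Pipeline configuration
#'
#' Assembles the per-stage parameter blocks for [run_pipeline()]. Stages run
#' in dependency order: simulate -> de -> enrich -> deconv -> brainmap. Any
#' subset can be toggled; a stage that does not find its inputs in memory
#' (because an upstream stage was toggled off) reads them from the paths in
#' `inputs`, and fails early if they do not exist.
#'
#' @param sim A [simulation_config()] for the simulate stage.
#' @param stages Character vector of stages to run.
#' @param alpha DEG significance threshold (adjusted p, strict `<`).
#' @param min_mean Expression filter for the DE stage.
#' @param level Cell-type label granularity for enrichment/deconvolution.
#' @param pseudocount PEM pseudocount.
#' @param alternative K-S alternative for the enrichment stage.
#' @param k Markers per type for the deconvolution signature.
#' @param gene_sets Where the enrichment/brainmap stages take their DEG sets
#'   from: `"auto"` uses the DE-derived up/down sets when both have at least
#'   `min_set_size` members and otherwise falls back to the generator's
#'   planted modules (recorded as a warning in the manifest); `"de"` and
#'   `"truth"` force one source.
#' @param min_set_size Minimum members for a usable DE-derived set.
#' @param inputs Named list of file paths used by stages whose upstream
#'   stage is toggled off: `counts`, `metadata`, `reference_counts`
#'   (MTX/TSV), `labels`, `deg_gmt`, `volume`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c("simulate", "de", "enrich",
                                       "deconv", "brainmap"),
                            alpha = 0.05, min_mean = 1,
                            level = "class", pseudocount = 1e-3,
                            alternative = "greater", k = 50,
                            gene_sets = c("auto", "de", "truth"),
                            min_set_size = 10,
                            inputs = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  gene_sets <- match.arg(gene_sets)
  assert_that(inherits(sim, "simulation_config"),
              "`sim` must be a simulation_config")
  structure(list(sim = sim, stages = stages, alpha = alpha,
                 min_mean = min_mean, level = level,
                 pseudocount = pseudocount, alternative = alternative,
                 k = k, gene_sets = gene_sets, min_set_size = min_set_size,
                 inputs = inputs),
            class = "pipeline_config")
}

# internal: md5 checksums of the files a stage wrote
manifest_files <- function(paths) {
  tibble::tibble(path = unname(paths),
                 md5 = unname(tools::md5sum(unname(paths))))
}

#' Run the integrative analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every output
#' in its documented text format under `out_dir`, and returns a run manifest
#' (also written as `manifest.yaml`) listing the package version, a config
#' hash, per-file md5 checksums, timestamps and warnings. Reruns with an
#' identical config and seed reproduce all outputs bit-identically. If a
#' stage fails, the manifest records the failing stage and message, is still
#' written, and the error is re-raised; downstream stages do not run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly: a list with `version`, `config_hash`,
#'   `started`, `finished`, `stages_run`, `files` (path + md5 tibble),
#'   `warnings`, `status`, and on failure `failed_stage` / `error`.
#' @export
run_pipeline <- function(config, out_dir) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("decomap")),
    config_hash = rlang::hash(config),
    seed = config$sim$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages_run = character(), files = NULL, warnings = character(),
    status = "ok"
  )
  files <- character()
  note <- function(msg) manifest$warnings <<- c(manifest$warnings, msg)
  state <- new.env(parent = emptyenv())

  need_input <- function(key) {
    p <- config$inputs[[key]]
    assert_that(!is.null(p) && file.exists(p),
                paste0("stage input not available: '", key,
                       "' (no upstream stage ran and no existing file ",
                       "configured in `inputs`)"),
                class = "decomap_pipeline_error")
    p
  }

  get_bulk <- function() {
    if (!is.null(state$bulk)) return(state$bulk)
    state$bulk <- gene_counts(read_counts(need_input("counts")),
                              read_metadata(need_input("metadata")))
    state$bulk
  }
  get_reference <- function() {
    if (!is.null(state$reference)) return(state$reference)
    labs <- read_labels(need_input("labels"))
    state$reference <- single_cell_reference(
      read_counts(need_input("reference_counts")), labs)
    state$reference
  }
  get_sets <- function() {
    if (!is.null(state$sets)) return(state$sets)
    if (config$gene_sets != "truth" && !is.null(state$deg)) {
      sets <- split_by_direction(state$deg, config$alpha)
      ok <- length(sets$up) >= config$min_set_size &&
        length(sets$down) >= config$min_set_size
      if (ok || config$gene_sets == "de") {
        if (!ok) note("DE-derived gene sets are below min_set_size")
        state$sets <- sets
        return(sets)
      }
      note(paste0("DE-derived sets too small (up = ", length(sets$up),
                  ", down = ", length(sets$down),
                  "); falling back to the generator's planted modules"))
    }
    if (!is.null(state$truth)) {
      de <- state$truth$true_de_genes
      bg <- setdiff(rownames(get_bulk()$counts), de$gene)
      state$sets <- list(up = de$gene[de$direction == "up"],
                         down = de$gene[de$direction == "down"],
                         background = bg)
      return(state$sets)
    }
    gmt <- read_gmt(need_input("deg_gmt"))
    assert_that(all(c("up", "down", "background") %in% names(gmt)),
                "deg_gmt must contain sets named up, down, background")
    state$sets <- gmt[c("up", "down", "background")]
    state$sets
  }
  get_volume <- function() {
    if (!is.null(state$volume)) return(state$volume)
    state$volume <- read_volume(need_input("volume"))
    state$volume
  }

  run_stage <- list(
    simulate = function() {
      state$reference <- simulate_reference(config$sim)
      sim <- simulate_bulk_cohort(config$sim, state$reference)
      state$bulk <- sim$bulk
      state$truth <- sim$truth
      de <- sim$truth$true_de_genes
      home_map <- NULL
      if (nrow(de)) {
        regions <- names(config$sim$volume$regions)
        dorsal <- intersect(c("cortical_plate", "hippocampal_formation"),
                            regions)
        ventral <- intersect(c("midbrain", "hindbrain", "ventral_forebrain"),
                             regions)
        if (!length(dorsal)) dorsal <- regions[1]
        if (!length(ventral)) ventral <- regions[length(regions)]
        up <- de$gene[de$direction == "up"]
        down <- de$gene[de$direction == "down"]
        home_map <- tibble::tibble(
          gene = c(up, down),
          region = c(rep_len(dorsal, length(up)),
                     rep_len(ventral, length(down))),
          fold = config$sim$volume$fold
        )
      }
      state$volume <- simulate_ish_volume(config$sim, home_map = home_map)
      p <- file.path(out_dir, c("bulk_counts.tsv", "sample_metadata.tsv",
                                "reference_counts.mtx", "cell_labels.tsv",
                                "true_fractions.tsv", "true_de_genes.tsv",
                                "volume.tsv"))
      write_counts(state$bulk, p[1])
      write_metadata(state$bulk$metadata, p[2])
      write_counts(state$reference$counts, p[3], format = "mtx")
      write_labels(state$reference$cell_metadata, p[4])
      readr::write_tsv(tibble::as_tibble(state$truth$true_fractions,
                                         rownames = "sample_id"), p[5],
                       progress = FALSE)
      readr::write_tsv(state$truth$true_de_genes, p[6], progress = FALSE)
      write_volume(state$volume, p[7])
      c(p, file.path(out_dir, c("reference_counts.rownames.txt",
                                "reference_counts.colnames.txt")))
    },
    de = function() {
      state$deg <- differential_expression(get_bulk(), alpha = config$alpha,
                                           min_mean = config$min_mean)
      sets <- split_by_direction(state$deg, config$alpha)
      p <- file.path(out_dir, c("deg_table.tsv", "deg_sets.gmt"))
      readr::write_tsv(tibble::as_tibble(state$deg), p[1], progress = FALSE)
      write_gmt(sets, p[2],
                descriptions = c(up = "padj<alpha, log2FC>0",
                                 down = "padj<alpha, log2FC<0",
                                 background = "padj>=alpha"))
      p
    },
    enrich = function() {
      prof <- pseudobulk_means(get_reference(), level = config$level)
      state$profiles <- prof
      state$pem <- compute_pem(prof, pseudocount = config$pseudocount)
      sets <- get_sets()
      p <- file.path(out_dir, c("pem_matrix.tsv", "enrichment_up.tsv",
                                "enrichment_down.tsv"))
      readr::write_tsv(tibble::as_tibble(state$pem$pem, rownames = "gene"),
                       p[1], progress = FALSE)
      for (dir in c("up", "down")) {
        enr <- ks_enrichment(state$pem, sets[[dir]], sets$background,
                             alternative = config$alternative)
        readr::write_tsv(tibble::as_tibble(enr),
                         file.path(out_dir,
                                   paste0("enrichment_", dir, ".tsv")),
                         progress = FALSE)
      }
      p
    },
    deconv = function() {
      if (is.null(state$profiles)) {
        state$profiles <- pseudobulk_means(get_reference(),
                                           level = config$level)
        state$pem <- compute_pem(state$profiles,
                                 pseudocount = config$pseudocount)
      }
      sig <- build_signature(state$profiles, state$pem, k = config$k)
      fr <- estimate_fractions(get_bulk(), sig)
      cmp <- compare_fractions(fr)
      p <- file.path(out_dir, c("fractions.tsv", "fraction_comparison.tsv"))
      readr::write_tsv(tibble::as_tibble(fr$fractions,
                                         rownames = "sample_id"),
                       p[1], progress = FALSE)
      readr::write_tsv(tibble::as_tibble(cmp), p[2], progress = FALSE)
      p
    },
    brainmap = function() {
      vol <- get_volume()
      sets <- get_sets()
      shared <- vapply(sets[c("up", "down")],
                       function(s) length(intersect(s, vol$genes)),
                       integer(1))
      note(paste0("brainmap gene intersection with volume panel: up = ",
                  shared[1], ", down = ", shared[2]))
      up_map <- module_spatial_score(vol, sets$up, name = "up")
      down_map <- module_spatial_score(vol, sets$down, name = "down")
      p <- file.path(out_dir, c("region_summary_up.tsv",
                                "region_summary_down.tsv",
                                "region_contrast.tsv"))
      readr::write_tsv(region_summary(up_map), p[1], progress = FALSE)
      readr::write_tsv(region_summary(down_map), p[2], progress = FALSE)
      readr::write_tsv(region_contrast(up_map, down_map), p[3],
                       progress = FALSE)
      p
    }
  )

  order <- c("simulate", "de", "enrich", "deconv", "brainmap")
  for (stage in intersect(order, config$stages)) {
    out <- withCallingHandlers(
      tryCatch(run_stage[[stage]](), error = function(e) e),
      warning = function(w) {
        note(paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(out, "error")) {
      manifest$status <- "failed"
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(out)
      manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      manifest$files <- manifest_files(files)
      write_manifest(manifest, out_dir)
      stop_decomap(paste0("pipeline stage '", stage, "' failed: ",
                          conditionMessage(out)),
                   class = "decomap_pipeline_error")
    }
    files <- c(files, out)
    manifest$stages_run <- c(manifest$stages_run, stage)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$files <- manifest_files(files)
  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  m <- manifest
  m$files <- if (!is.null(m$files)) {
    setNames(as.list(m$files$md5), m$files$path)
  }
  yaml::write_yaml(m, file.path(out_dir, "manifest.yaml"))
  invisible(NULL)
}
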