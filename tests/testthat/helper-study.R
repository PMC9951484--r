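# One run of the emulated study at its default conditions, memoised per
# seed so several test files can share it without re-simulating. Only the
# small derived objects are kept (profiles, PEM, bulk, ground truth) — the
# cell-level reference counts are dropped after averaging.
.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- simulation_config(seed = seed)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk_cohort(cfg, ref)
  prof <- pseudobulk_means(ref, "class")
  out <- list(
    config = cfg,
    profiles = prof,
    pem = compute_pem(prof),
    bulk = sim$bulk,
    truth = sim$truth
  )
  .study_cache[[key]] <- out
  out
}
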