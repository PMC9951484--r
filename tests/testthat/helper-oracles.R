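# Independent reference implementations used as oracles. These deliberately
# use naive loops / enumeration so they share no code path with the package.

# step-up BH by literal definition: q_i = min_{j >= i} p_(j) * m / j, capped
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# two-sample K-S statistic by brute force: sup over all pooled points of the
# |ECDF difference| (two-sided) or the signed difference (one-sided)
ks_d_oracle <- function(x, y, alternative = "two-sided") {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  switch(alternative,
         "two-sided" = max(abs(fx - fy)),
         # x stochastically greater than y: its ECDF sits below y's
         "greater" = max(fy - fx),
         stop("unknown alternative"))
}

# PEM by literal elementwise evaluation of the definition
pem_oracle <- function(X, pseudocount) {
  Xp <- X + pseudocount
  S <- numeric(ncol(Xp))
  for (i in seq_len(ncol(Xp))) S[i] <- sum(Xp[, i])
  out <- matrix(NA_real_, nrow(Xp), ncol(Xp), dimnames = dimnames(X))
  for (g in seq_len(nrow(Xp))) {
    for (i in seq_len(ncol(Xp))) {
      out[g, i] <- log10((sum(S) / S[i]) * (Xp[g, i] / sum(Xp[g, ])))
    }
  }
  out
}

# small, fast simulation configs shared across test files
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_genes = 300L, n_cell_types = 4L,
    cell_types = c("radial_glia", "neuron", "neuroblast", "glioblast"),
    base_fractions = c(radial_glia = 0.1, neuron = 0.5,
                       neuroblast = 0.25, glioblast = 0.15),
    n_cells_per_type = 30L,
    n_samples_per_group = c(control = 5L, stress = 5L),
    marker_frac = 0.4, marker_fold = 8,
    de_spec = tibble::tibble(cell_type = c("radial_glia", "neuron"),
                             n_genes = c(15L, 15L), lfc = c(0.5, -0.5)),
    library_size_mean = 1e5
  )
  args <- defaults
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(simulation_config, args)
}

null_config <- function(seed = 1L, n_genes = 1000L, n_per_group = 8L, ...) {
  defaults <- list(
    seed = seed, n_genes = n_genes, n_cell_types = 16L,
    n_cells_per_type = 2L,
    n_samples_per_group = c(control = n_per_group, stress = n_per_group),
    de_spec = tibble::tibble(cell_type = character(), n_genes = integer(),
                             lfc = numeric()),
    fraction_shift = c(neuron = 0)
  )
  args <- defaults
  dots <- list(...)
  for (nm in names(dots)) args[[nm]] <- dots[[nm]]
  do.call(simulation_config, args)
}
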