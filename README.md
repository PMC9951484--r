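# decomap

Cell-type and brain-region decomposition of bulk RNA-seq against a labeled
single-cell reference.

## The problem

A bulk RNA-seq contrast on a heterogeneous tissue — here, the embryonic
mouse brain under prenatal stress — mixes the transcriptional responses of
many cell populations. Given a list of differentially expressed genes
(DEGs) from such a contrast and a labeled single-cell reference of the same
tissue, three questions follow:

1. **Which cell types carry the signal?** Up- and down-regulated DEG sets
   can preferentially belong to different populations (e.g. proliferating
   radial glia vs differentiated neurons).
2. **Did the cellular composition itself change?** A shift in cell-type
   fractions (e.g. accumulation of neuroblasts) is invisible to per-gene
   statistics but recoverable by deconvolution.
3. **Where in the tissue does each DEG set live?** Mapping gene sets onto a
   voxelized in situ hybridization (ISH) atlas localizes the signal to
   anatomical regions (e.g. dorsal forebrain vs ventral mid/hindbrain).

`decomap` implements this integrative analysis as composable, tested R
functions, together with a negative binomial synthetic-data generator that
emulates the study design (a two-batch, mixed-sex cohort of 9 control vs 7
stressed animals; 16 reference cell classes dominated by neurons ~54%,
neuroblasts ~24%, glioblasts ~14%; mild planted effects, |log2FC| ≈ 0.5,
restricted to the affected genes' home cell types), so every stage is
verifiable end to end without any external download.

## The statistics at its core

**Preferential expression measure (PEM).** With `X[g,i]` the mean
expression of gene *g* in cell type *i* (cells averaged within labels) and
`S[i] = Σ_g X[g,i]` the type's total expression mass,

```
PEM[g,i] = log10( (Σ_i' S[i'] / S[i]) · (X[g,i] / Σ_i' X[g,i']) )
```

is the log10 ratio of the gene's observed share in type *i* to the share
expected if the gene followed the overall expression mass of each type.
0 means no preference; the construction conserves mass:
`Σ_i 10^PEM[g,i] · S[i]/ΣS = 1` for every gene.

**K-S enrichment.** Per cell type, a two-sample Kolmogorov–Smirnov test
compares the PEM distribution of a DEG set against the unchanged background
genes (adjusted p > 0.05 in the bulk contrast); Benjamini–Hochberg
adjustment runs across the cell types of one call, and `-log10(padj)` is
the enrichment score.

**Deconvolution.** Per-sample cell-type fractions are estimated by
precision-weighted non-negative least squares of the bulk CPM vector on a
signature of PEM-top-k marker genes, renormalized to sum to one, and
compared between condition groups with unpaired Welch t-tests.

**Spatial mapping.** A gene set's spatial score at a voxel is the sum of
the ISH energies of its available genes; per-region means rank regions, and
an up-vs-down contrast emits per-region log2 ratios.

The differential expression feeding all of this is a transparent
covariate-adjusted stand-in: a Gaussian linear model on depth-standardized
`log2(normalized count + 1)` with `~ sex + batch + condition`, moderated-t
p-values, BH adjustment, and strict `padj < 0.05` splitting into up / down /
background.

## Worked example

```r
library(decomap)

cfg <- simulation_config(seed = 7)          # the emulated study design
ref <- simulate_reference(cfg)              # 2000 genes x 1600 labeled cells
sim <- simulate_bulk_cohort(cfg, ref)       # 9 control vs 7 stress samples

# cell-type enrichment of the planted up-regulated module
prof <- pseudobulk_means(ref, "class")
pem  <- compute_pem(prof)
de   <- sim$truth$true_de_genes
bg   <- setdiff(rownames(sim$bulk$counts), de$gene)
ks_enrichment(pem, de$gene[de$direction == "up"], bg, alternative = "greater")
#> # A tibble: 16 x 8 (top rows)
#>   cell_type   n_deg_used n_background_used     D shift_sign        p     padj score
#>   radial_glia         40              1905 0.995          1 0        0        308.
#>   neuron              40              1905 0.0562        -1 0.781    1.00       0.00000938
#>   ...
```

The planted radial-glia module is recovered with D ≈ 1 and an enrichment
score of ~308; every other type is flat — the Fig.-3-style readout that up-
regulated genes sit in neural stem cells.

```r
# fractions and group comparison
sig <- build_signature(prof, pem, k = 50)
fr  <- estimate_fractions(sim$bulk, sig)
cmp <- compare_fractions(fr)
cmp[cmp$cell_type %in% c("neuron", "neuroblast"), c("cell_type", "mean_control", "mean_stress", "p")]
#>   cell_type  mean_control mean_stress       p
#>   neuroblast        0.215       0.273 0.0013
#>   neuron            0.506       0.371 0.0016
```

The planted composition shift (neurons down, neuroblasts up in the stress
group) is detected. `autoplot(cmp)` draws the mean ± SEM bar chart;
`autoplot()` methods also exist for enrichment results and spatial maps.

The whole chain — simulate → DE → PEM/K-S enrichment → deconvolution →
region mapping — runs as one call:

```r
man <- run_pipeline(pipeline_config(sim = simulation_config(seed = 3)), "out/")
readr::read_tsv("out/region_contrast.tsv")
#>   region                mean_a mean_b log2_ratio
#>   hippocampal_formation  222.4   54.8       2.02
#>   cortical_plate         220.0   54.9       2.00
#>   ...
#>   midbrain                39.9  225.8      -2.50
```

positive log2 ratios localize the up-regulated module to the dorsal
forebrain regions, negative ones the down-regulated module to the ventral
mid/hindbrain — with a manifest (`manifest.yaml`) recording versions,
checksums and warnings, bit-identical across reruns at a fixed seed.

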