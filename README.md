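# ascna

Allele-specific somatic copy-number alteration (CNA) inference from
single-cell RNA-seq count data.

Most expression-based CNA callers for scRNA-seq track only total read depth,
so they can say *that* a region changed copy number but not *which parental
haplotype* was lost or duplicated — and they cannot see copy-neutral loss of
heterozygosity (CNLOH) at all. `ascna` combines two orthogonal signals per
gene per cell:

* the **read-depth ratio (RDR)** — expression relative to a designated
  diploid reference cell group, modelled as a negative-binomial mixture over
  absolute copy states with mean `l_c · X_ref,g · C_k` (cell library factor,
  reference profile, state ratio `C ∈ {0.5, 1, 1.5}` or data-driven) and
  per-gene dispersion `φ_g` fitted on reference cells;
* the **phased B-allele frequency (BAF)** — allelic UMI counts at
  heterozygous SNPs, aggregated to gene bins after a three-level phasing
  (reference panel → EM gene-bin phasing → dynamic-programming arm phasing),
  modelled as a beta-binomial mixture `BB(a | d, ρ_k, τ)` over five
  allelic-bias states with theoretical frequencies `{0, 1/3, 1/2, 2/3, 1}`.

Each module's state probabilities are smoothed across transcriptomic
neighbours (KNN graph) and along the genome (forward-backward HMM,
cross-state transition `10⁻⁶`), then combined into four final states —
**loss, neutral, gain, LOH** — with a haplotype-resolved detail layer and a
warning system for whole-genome duplication (copy loss with balanced alleles
cannot happen against a truly diploid baseline). A haplotype-aware count
simulator with ground-truth masks and an AUROC/ARI benchmarking harness are
included.

See `vignettes/ascna-methods.Rmd` for the full model description, parameter
defaults, and design rationale.

## Worked example

Simulate the subclonal allele-specific-loss scenario — two tumour subclones
that are transcriptomically identical and differ only in *which* haplotype
of chromosome 3 they lost, on top of a shared background of gains, losses
and CNLOH — then run the full pipeline and benchmark against the simulated
truth:

```r
library(ascna)

ps  <- scenario_preset("subclonal_allele_loss", seed = 7,
                       n_ref_cells = 60, n_tumor_cells = 80)
ps$config$genes_per_chrom <- 250L
sim <- simulate_cna(ps$profile, ps$config)
sim
#> <cna_sim> 140 cells x 2000 genes; clones: reference, clone1, clone2

res <- run_cna_pipeline(sim$dataset, truth = sim$truth)
res
#> <cna_pipeline> 140 cells, 1352 retained genes; modules: rdr+baf
#> # A tibble: 3 × 4
#>   state auroc auprc      n
#>   <chr> <dbl> <dbl>  <int>
#> 1 loss  0.999 0.994 189280
#> 2 gain  1     1     189280
#> 3 LOH   0.894 0.771 189280

glance(res$rdr)
#> # A tibble: 1 × 6
#>   n_cells n_genes C_loss C_neutral C_gain platform
#> 1     140    1352  0.415      1.10   1.71 droplet

kmeans_subclones(res$combined, k = 3, true_labels = sim$clone)$ari
#> [1] 1
```

The benchmark rows are entry-level AUROCs over the flattened cell-by-gene
probability matrices for each CNA state against the planted truth masks
(1 = perfect ranking). `C_loss/C_neutral/C_gain` are the guided copy-number
ratios extracted from the smoothed read-depth ratio (theoretical values
0.5 / 1 / 1.5); the adjusted Rand index of 1 means K-means on the
haplotype-resolved posterior recovered the reference group and both
subclones exactly. At this reduced size each chromosome arm holds only one
or two gene bins, which limits LOH localisation (AUROC 0.89); at the full
benchmark size (400 cells × 3000 genes) all three states reach ≥ 0.99.

`autoplot(res$combined, cells = sim$dataset$cells)` draws the cell-by-gene
call heatmap; `tidy(res$baf)` returns the per-bin allelic-state frequencies;
`write_dataset()` / `load_dataset()` round-trip the matrix-market layout.
A thin command-line wrapper with `simulate` / `run` / `benchmark`
subcommands is installed at `inst/scripts/ascna-cli.R`.

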