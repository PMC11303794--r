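---
title: "Allele-specific CNA inference from scRNA-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific CNA inference from scRNA-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Somatic copy-number alterations (CNAs) — gains, losses and copy-neutral loss
of heterozygosity (CNLOH) — shape tumour evolution, but most scRNA-seq CNA
callers only track total expression and therefore cannot distinguish which
parental haplotype was lost or duplicated. `ascna` infers allele-specific CNA
states per gene per cell by combining two orthogonal signals:

* **RDR (read-depth ratio)** — a cell's expression relative to a designated
  diploid reference group, a proxy for absolute copy number;
* **BAF (B-allele frequency)** — the fraction of allelic UMIs supporting the
  phased B haplotype at heterozygous SNPs, 0.5 under allelic balance.

The final output is a cell-by-gene posterior over four states (loss, neutral,
gain, LOH) with a haplotype-resolved detail layer and a warning system for
whole-genome duplication (WGD).

# Data model and preprocessing

Counting starts from per-SNP allelic read records (cell barcode, UMI, SNP,
gene, allele). Reads with MAPQ < 20, aligned length < 30 nt, or a SAM FLAG
above 255 are discarded. Within each (cell, gene), every UMI counts at most
once: a UMI spanning several SNPs is resolved by majority vote over its
unambiguous calls, and an exact REF/ALT tie or an all-ambiguous UMI is
dropped from both the B-allele count (AD) and the total allelic depth (DP).
The counting logic itself does not state how within-UMI conflicts should be
resolved in general; majority-with-tie-drop is this package's documented
choice, kept symmetric so no allele is favoured.

# Three-level phasing

Reference-panel phasing orients individual SNPs but drifts over multi-gene
distances. Two additional levels repair this:

1. **Local (gene to gene-bin) phasing.** Consecutive genes on one chromosome
   arm are grouped into bins (100 genes by default), all genes in a bin are
   assumed to share one allelic state per cell, and a per-gene flip indicator
   is treated as latent. With per-cell bin allele frequency `theta_c` and
   flips `f_g`, `AD' = f_g (DP - AD) + (1 - f_g) AD ~ Binomial(DP, theta_c)`;
   an EM algorithm alternates the flip posterior with the `theta_c` update
   until `max |delta theta| < 1e-6` (at most 100 iterations). The marginal
   log-likelihood is non-decreasing by construction and is asserted in tests.

   *Initialisation.* All genes start unflipped, so the first M-step estimates
   each cell's observed bin allele frequency and genes are subsequently
   flipped relative to the bin's majority orientation. This was a deliberate
   design choice over initialising from the sign of each gene's pooled
   deviation from 0.5: the sign-based start orients *every* imbalanced bin
   onto the same allele side, which makes the genome-wide smoothed BAF
   one-sided, starves half of the allelic-bias states, and destabilises the
   downstream Gaussian-mixture estimate of the state frequencies. Keeping the
   natural (reference-phasing) orientation preserves both allele sides and
   keeps haplotype-specific subclones distinguishable. When every cell's
   observed bin frequency is exactly 0.5 — a perfectly antisymmetric flip
   mix, which makes the unflipped start a saddle point — the initialiser
   falls back to the pooled-frequency sign to break the symmetry; in a truly
   balanced bin the likelihood is flat in the flips and all genes are
   reported unflipped by convention.

2. **Global (bin to arm) phasing.** Bins along one arm are oriented by
   minimising the summed Euclidean distance between consecutive oriented bin
   BAF vectors across cells (computed on the WMA/KNN-smoothed bin BAF). The
   two orientation states per bin admit an exact O(bins) dynamic program,
   verified in tests against exhaustive enumeration. Both levels exploit the
   genomic auto-correlation of BAF deviation from 0.5; in a fully balanced
   genome the phasing is arbitrary, and deliberately so — it cannot affect
   balanced-state posteriors.

Flipping exchanges `AD <-> DP - AD` and leaves DP invariant; bins with no
allelic depth pass through unflipped and are excluded from the arm chain.

# Smoothing operators

Both modules share two linear smoothing operators applied as
`X_smooth = M X W`:

* **W (horizontal, weighted moving average).** The raw weight from gene `j`
  to gene `g` at ordinal distance `d` on the same arm is `t - |d|` for
  `0 < |d| < t`, `2t` for `d = 0`, zero otherwise; columns are normalised to
  one. Default windows: `t = 40` (gene-scale RDR), `t = 101` (bin-scale BAF).
  W never mixes chromosome arms.
* **M (vertical, KNN graph).** Counts are normalised to 10,000 per cell,
  log1p-transformed and reduced to 50 principal components (fewer if the
  dataset is smaller); each cell connects to its `k = 10` nearest neighbours,
  a self-connection at the row's maximum neighbour weight is added, and rows
  are normalised. The exact connectivity kernel is an implementation detail
  on purpose: only the row-stochastic contract and the elevated self weight
  are relied upon.

The raw RDR is `log((RD/l_c) / X_ref)` with zero normalised counts floored at
a small constant (0.1 by default) so the log stays finite; non-zero entries
are exact.

# Expression module (absolute copy number)

Genes are filtered on the reference mean count (0.5 droplet, 1.8 smart-seq)
and the top 15 marker genes of every annotated cell group (one-vs-rest
rank-sum test on log-normalised counts) are removed. Counts then follow a
negative-binomial mixture over three states `k` (loss, neutral, gain):

`X_cg | z_cgk = 1  ~  NB(l_c * X_ref_g * C_k, phi_g)`

* `l_c` — cell library factor: total count over the mean reference total;
* `X_ref_g` — reference mean count per gene;
* `phi_g` — per-gene NB dispersion, fitted by bounded 1-D maximum likelihood
  (`[1e-8, 100]` on the log scale) on reference cells only, with failures
  floored and flagged;
* `C_k` — copy-number ratio per state: theoretical `(0.5, 1, 1.5)`, or the
  guided estimate: arms ranked by mean smoothed ratio; the lowest, median and
  highest arms anchor loss/neutral/gain; `C_k` is the 0.0001 / 0.96 / 0.99
  quantile of the anchor arm's smoothed ratio entries over non-reference
  cells. Quantiles are taken on the linear-ratio scale — identical to
  exponentiating the same quantile of the log ratio, since quantiles commute
  with monotone transforms — but the *smoothing* is done on the linear ratio:
  averaging the per-entry log of sparse counts is biased low by the
  zero-floor, which we measured to misplace all three ratios by 30–50% under
  droplet sparsity, while linear-scale averaging is unbiased. Non-increasing
  guided estimates, or fewer than three arms, fall back to the theoretical
  ratios with a warning.

Normalising the three NB densities per entry yields the cell-by-gene-by-state
emission tensor.

# Allelic module (B-allele frequency)

Phased bin counts follow a beta-binomial mixture over five allelic states
(A-strong, A-minor, balanced, B-minor, B-strong) with theoretical B-allele
frequencies `(0, 1/3, 1/2, 2/3, 1)`:

`a_cg | d_cg, z_cgk = 1  ~  BetaBinomial(d_cg, rho_gk, tau)`

`tau = 100` by default for droplet data (a technical concentration shared by
all bins); for smart-seq data a per-bin `tau` can be fitted on reference
cells (floored at 5). The balanced-state `rho` per bin is the reference-cell
mean of the smoothed BAF, or 0.5 when fewer than 20 reference cells are
available. The four biased-state frequencies come from a 5-component 1-D
Gaussian mixture over all smoothed BAF entries (components matched to states
by sorted means, minor states clipped to `[0.01, 0.99]`); a degenerate or
failed mixture falls back to the theoretical frequencies with a warning. A
3-state mode (A-bias, balanced, B-bias at `0, 0.5, 1`) is available for
comparison. Entries with `d = 0` are uniform over states.

# Posterior smoothing: KNN + HMM

Each module's emission tensor is smoothed vertically across cells and then
horizontally along the genome by a forward-backward HMM per cell:

* **Vertical.** Every state slice is left-multiplied by the effective
  connectivity `0.5 I + 0.5 M` and rows are renormalised. The equal
  self-blend is a deliberate design choice: plain probability-space averaging
  caps a cell's own evidence at one row-mass share, so a `k = 10` neighbour
  majority can outvote arbitrarily strong per-cell likelihoods. With
  transcriptomically identical subclones that differ only in *which*
  haplotype is lost, the neighbour draw is a coin flip and roughly the
  binomial tail `P(Binom(10, 1/2) >= 6) ~ 38%` of cells would have their
  haplotype sign inverted — a structural ceiling on subclone recovery that no
  downstream clustering can repair. Keeping half the mass on the cell's own
  emission preserves the sign of strong evidence while still letting the
  neighbourhood dominate exactly where the cell's own evidence is weak
  (sparse counts), which is the purpose of the smoothing.
* **Horizontal.** A homogeneous HMM with cross-state transition probability
  `t = 1e-6` (stay probability `1 - (K-1) t`) and start probabilities
  `(0.1, 0.8, 0.1)` (droplet RDR), `(0.3, 0.4, 0.3)` (smart-seq RDR) and
  `(0.2, 0.15, 0.3, 0.15, 0.2)` (BAF). Exact smoothing posteriors are
  computed in log space with log-sum-exp, vectorised across cells. Chains
  reset at chromosome boundaries — not at arms, which bound only the WMA and
  phasing; the choice of chromosome-level chains is documented here because
  the boundary policy is otherwise open. Hard calls take the posterior
  argmax with ties broken toward the neutral/balanced state.

# Combination, WGD warning and denoising

The BAF posterior is mapped from bins back to genes (each gene inherits its
bin's row; genes without a bin are balanced-filled and flagged), then the
joint `q(r, b) = P_rdr(r) P_baf(b)` is routed through a rule table kept as
plain data:

| expression \ allelic | A-bias | balanced | B-bias |
|---|---|---|---|
| loss | loss (B lost) | loss + WGD flag | loss (A lost) |
| neutral | LOH (B lost) | neutral | LOH (A lost) |
| gain | gain | gain | gain |

Allele sides follow the B-allele frequency: a bias toward A (BAF near 0)
means haplotype B was lost. The detailed 7-state tensor (loss-A, loss-B,
loss-balanced, neutral, gain, LOH-A, LOH-B) collapses to the four final
states; subclone clustering flattens the detailed tensor so haplotype-mirrored
losses remain separable. Gains are not subdivided by allele in the final
state — the bias direction is still recorded in the detail layer.

**WGD warning.** Copy loss with balanced alleles cannot happen against a
diploid baseline; it is the signature of a duplicated genome whose truly
diploid regions appear as "relative loss" after library normalisation. Per
annotated cluster, a gene is implicated when at least half the cluster's
cells have (loss, balanced) as their dominant joint state; if implicated
genes exceed 5% of the genome the warning fires and lists the regions. Both
thresholds are package choices (none are stated elsewhere) and are
configurable.

**Post-denoise.** Per gene, the aneuploid proportion is the fraction of
cells whose argmax is non-neutral; a 2-component Gaussian mixture over these
proportions identifies a background component whose genes are masked to the
neutral one-hot. A manual threshold mode is available. Denoising is applied
to the BAF-derived posterior by default. When the tumour fraction is very
small the proportions lose bimodality and the mixture can mask genuine CNA
genes — a known limitation discussed below.

# The simulator

`simulate_cna()` generates the study conditions at count level:

* baseline gene means `mu_g ~ LogNormal(log 1.2, 0.8)` (long-tailed; most
  genes pass the droplet expression filter), library factors
  `l_c ~ LogNormal(0, 0.2)`;
* expression `RD ~ NB(l_c mu_g ratio(c, g), phi = 0.1)` with the clone- and
  region-specific copy ratio;
* allele-informative depth `DP ~ Binomial(RD, 0.2)`; allele-ambiguous UMIs
  are dropped from the expression count with probability 0.5;
* B-allele counts `AD ~ BetaBinomial(DP, BAF(c, g), tau = 100)` with the
  state-implied expected BAF (haplotype-A loss gives 1, a 2:1 B gain 2/3,
  CNLOH 0 or 1, WGD 0.5 at ratio 2);
* reference-phasing errors flip `AD <-> DP - AD` for a random 10% of genes,
  consistently across cells.

Ground truth is returned as cell-by-gene masks per final state plus
haplotype-specific loss sub-masks. The default desk-scale genome is 6
chromosomes of 500 genes with arms split at the midpoint; the scenario
presets use 8 chromosomes of 375 genes (3000 genes) so that the full
background profile — gain on two chromosomes, loss on one chromosome plus
one arm, CNLOH on four arms, and the subclonal haplotype-mirrored loss on
chromosome 3 — fits with neutral arms left over for the guided-ratio
anchors. Scenario presets: `subclonal_allele_loss` (150 reference +
two 125-cell subclones), `ref_downsample` (reference reduced to 10 or 5
cells) and `tumor_downsample` (tumour reduced to 22, 10 or 5 cells).

What the simulator does *not* emulate: read-level alignment artefacts,
doublets, ambient RNA, cell-type-specific expression programs beyond the
reference/tumour split, and SNP-level phasing structure (errors are i.i.d.
per gene). Passing the synthetic benchmarks therefore demonstrates the
statistical machinery under the stated generative model, not performance on
any real tissue.

# Numerical choices and problem sizes

* All mixture densities are evaluated in log space and normalised by
  log-sum-exp; degenerate beta-binomial means (`rho` of 0 or 1) are handled
  as point masses; zero emission rows become uniform and are flagged.
* The dispersion optimiser is `stats::optimize` on `log10 phi in [-8, 2]`.
* Gaussian mixtures use `mclust` (deterministic hierarchical initialisation);
  constant input is detected up front and routed to the documented fallbacks.
* Test and benchmark problem sizes were chosen as the smallest at which the
  statistical properties stabilise: the end-to-end benchmark uses 400 cells
  by 3000 genes; parameter-recovery fixtures use 200–500 cells; the
  HMM and phasing oracles enumerate chains of length at most 8 and arms of
  at most 12 bins. The guided-ratio recovery fixture uses low dispersion
  (0.03), a higher expression baseline (`log 5`) and 150 reference cells —
  the "small noise" regime in which the extreme-quantile heuristic is meant
  to land on the CNA plateau; at higher noise the 0.0001/0.99 quantiles
  deliberately dig into the tails and overshoot.

# Known limitations

* **WGD samples.** A genome-doubled clone roughly doubles the library size,
  so its normalised profiles are *less* noisy than the diploid reference's;
  nearest-neighbour graphs are then attracted to the tumour cloud and
  reference cells can inherit tumour emissions. Per-cell calls in
  relatively-diploid regions of a WGD sample are therefore unreliable — the
  WGD warning, which is robust to this mixing, is the intended output for
  such samples.
* **Tiny tumour fractions.** With a handful of tumour cells the aneuploid
  proportions are no longer bimodal and the default denoising can mask true
  CNA genes; the pipeline stays operational (the robustness scenarios assert
  this) but allele-specific sensitivity drops. Disable denoising or set a
  manual threshold in that regime.
* **Identifiability.** Bin orientation is identifiable only up to inversion
  per phasing scope; haplotype labels are consistent within an arm, not
  globally.
* **Miniature genomes.** With fewer than two bins per arm the BAF module
  loses within-arm resolution; LOH localisation needs arms of at least a few
  bins.
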