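STATE_DEFAULTS <- tibble::tribble(
  ~state,      ~rdr_ratio, ~expected_baf,
  "loss_hapA",  0.5,        1,
  "loss_hapB",  0.5,        0,
  "gain_hapA",  1.5,        1/3,
  "gain_hapB",  1.5,        2/3,
  "cnloh_A",    1.0,        0,
  "cnloh_B",    1.0,        1,
  "wgd",        2.0,        0.5)

#' Clone-resolved CNA ground-truth profile
#'
#' @param clones tibble with `clone_id`, `n_cells`.
#' @param events tibble with `clone_id`, `chrom`, `arm` (`"p"`, `"q"` or
#'   `NA` for the whole chromosome), `state` (one of `loss_hapA`,
#'   `loss_hapB`, `gain_hapA`, `gain_hapB`, `cnloh_A`, `cnloh_B`, `wgd`),
#'   and optionally `rdr_ratio`, `expected_baf` (state defaults otherwise:
#'   haplotype-A loss has ratio 0.5 and B-allele frequency 1, a 2:1
#'   haplotype-B gain has ratio 1.5 and frequency 2/3, copy-neutral LOH has
#'   ratio 1 and frequency 0 or 1, WGD ratio 2 and frequency 0.5).
#' @return object of class `cna_profile`.
#' @export
cna_profile <- function(clones, events) {
  clones <- tibble::as_tibble(clones)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("clone_id", "n_cells") %in% names(clones)),
            all(c("clone_id", "chrom", "arm", "state") %in% names(events)))
  if (!all(events$state %in% STATE_DEFAULTS$state)) stop("unknown CNA state")
  if (!all(events$clone_id %in% clones$clone_id)) stop("event for unknown clone")
  di <- match(events$state, STATE_DEFAULTS$state)
  if (!"rdr_ratio" %in% names(events)) events$rdr_ratio <- NA_real_
  if (!"expected_baf" %in% names(events)) events$expected_baf <- NA_real_
  events$rdr_ratio <- ifelse(is.na(events$rdr_ratio),
                             STATE_DEFAULTS$rdr_ratio[di], events$rdr_ratio)
  events$expected_baf <- ifelse(is.na(events$expected_baf),
                                STATE_DEFAULTS$expected_baf[di], events$expected_baf)
  stopifnot(all(events$rdr_ratio > 0),
            all(events$expected_baf >= 0 & events$expected_baf <= 1))
  # overlap check: within a clone no two events may share a chromosome arm
  key <- with(events, {
    arms <- ifelse(is.na(arm), "p+q", arm)
    paste(clone_id, chrom, arms)
  })
  expand <- unlist(lapply(seq_len(nrow(events)), function(i) {
    arms <- if (is.na(events$arm[i])) c("p", "q") else events$arm[i]
    paste(events$clone_id[i], events$chrom[i], arms)
  }))
  if (anyDuplicated(expand)) stop("overlapping events within one clone")
  structure(list(clones = clones, events = events), class = "cna_profile")
}

#' Simulator configuration
#'
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_ref_cells reference (diploid) cells (default 150).
#' @param n_chroms,genes_per_chrom synthetic genome layout (default 6 x 500;
#'   p/q arms split at the chromosome midpoint).
#' @param dispersion NB dispersion of expression counts (default 0.1).
#' @param mu_meanlog,mu_sdlog log-normal baseline mean-expression
#'   distribution (default `log(1.2)`, 0.8 - long-tailed, most genes pass
#'   the droplet expression filter).
#' @param lib_sdlog spread of per-cell library factors (default 0.2).
#' @param allelic_depth_rate fraction of expression UMIs carrying clear
#'   het-SNP allele evidence (default 0.2).
#' @param ambig_drop_prob probability an ambiguous (no-allele) UMI is
#'   dropped from the expression count (default 0.5).
#' @param tau beta-binomial concentration of allelic counts (default 100).
#' @param phase_error_rate per-gene probability of a reference-phasing
#'   haplotype flip (default 0.1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_ref_cells = 150L, n_chroms = 6L,
                       genes_per_chrom = 500L, dispersion = 0.1,
                       mu_meanlog = log(1.2), mu_sdlog = 0.8,
                       lib_sdlog = 0.2, allelic_depth_rate = 0.2,
                       ambig_drop_prob = 0.5, tau = 100,
                       phase_error_rate = 0.1) {
  stopifnot(!missing(seed), allelic_depth_rate >= 0, allelic_depth_rate <= 1,
            ambig_drop_prob >= 0, ambig_drop_prob <= 1,
            phase_error_rate >= 0, phase_error_rate <= 1)
  structure(list(seed = as.integer(seed), n_ref_cells = n_ref_cells,
                 n_chroms = n_chroms, genes_per_chrom = genes_per_chrom,
                 dispersion = dispersion, mu_meanlog = mu_meanlog,
                 mu_sdlog = mu_sdlog, lib_sdlog = lib_sdlog,
                 allelic_depth_rate = allelic_depth_rate,
                 ambig_drop_prob = ambig_drop_prob, tau = tau,
                 phase_error_rate = phase_error_rate),
            class = "sim_config")
}

sim_gene_annotation <- function(n_chroms, genes_per_chrom) {
  gene_len <- 1000L; gap <- 9000L
  genes <- dplyr::bind_rows(lapply(seq_len(n_chroms), function(ch) {
    j <- seq_len(genes_per_chrom)
    start <- (j - 1L) * (gene_len + gap) + 1L
    tibble::tibble(gene_id = sprintf("chr%d_g%04d", ch, j),
                   chrom = as.character(ch), start = start,
                   end = start + gene_len - 1L,
                   arm = ifelse(j <= genes_per_chrom / 2, "p", "q"))
  }))
  gene_annotation(genes)
}

#' Simulate clone-structured allele-specific CNAs at count level
#'
#' Generates cell-by-gene RD/AD/DP matrices under a clone-resolved CNA
#' profile. Baseline gene means are long-tailed log-normal; expression
#' counts are `NB(l_c * mu_g * ratio(c, g), phi)`; allele-informative depth
#' is a binomial thinning `DP ~ Binom(RD_raw, allelic_depth_rate)` (the
#' remaining, allele-ambiguous UMIs are dropped from the expression count
#' with probability `ambig_drop_prob`); phased B-allele counts are
#' `AD ~ BetaBinom(DP, expected_baf(c, g), tau)`; and reference-phasing
#' errors flip `AD <-> DP - AD` for random genes (consistently across
#' cells). Ground-truth cell-by-gene masks are returned per final state
#' plus haplotype-specific loss sub-masks.
#'
#' @param profile [cna_profile()].
#' @param config [sim_config()].
#' @return object of class `cna_sim`: list with `dataset` (a
#'   [cna_dataset()]), `truth` (list of logical masks: `loss`, `gain`,
#'   `loh`, `wgd`, `loss_hapA`, `loss_hapB`), `clone` (per-cell clone
#'   label), `phase_flips` (per-gene logical), `expected` (ratio and BAF
#'   matrices), `profile`, `config`.
#' @export
simulate_cna <- function(profile, config) {
  set.seed(config$seed)
  genes <- sim_gene_annotation(config$n_chroms, config$genes_per_chrom)
  G <- nrow(genes)
  clones <- profile$clones
  n_tumor <- sum(clones$n_cells)
  n_cells <- config$n_ref_cells + n_tumor
  clone <- c(rep("reference", config$n_ref_cells),
             rep(clones$clone_id, clones$n_cells))
  cells <- cell_meta(tibble::tibble(
    barcode = sprintf("cell%04d", seq_len(n_cells)),
    cell_type = clone, is_reference = clone == "reference"))
  ratio <- matrix(1, n_cells, G)
  baf <- matrix(0.5, n_cells, G)
  state_m <- matrix("neutral", n_cells, G)
  for (i in seq_len(nrow(profile$events))) {
    ev <- profile$events[i, ]
    in_clone <- clone == ev$clone_id
    in_genes <- genes$chrom == ev$chrom &
      (is.na(ev$arm) | genes$arm == ev$arm)
    ratio[in_clone, in_genes] <- ev$rdr_ratio
    baf[in_clone, in_genes] <- ev$expected_baf
    state_m[in_clone, in_genes] <- ev$state
  }
  mu <- rlnorm(G, config$mu_meanlog, config$mu_sdlog)
  l <- rlnorm(n_cells, 0, config$lib_sdlog)
  RD_raw <- matrix(rnbinom(n_cells * G, size = 1 / config$dispersion,
                           mu = as.vector(outer(l, mu) * ratio)), n_cells, G)
  DP <- matrix(rbinom(n_cells * G, RD_raw, config$allelic_depth_rate),
               n_cells, G)
  kept_ambig <- matrix(rbinom(n_cells * G, RD_raw - DP,
                              1 - config$ambig_drop_prob), n_cells, G)
  RD <- DP + kept_ambig
  AD <- matrix(rbetabinom(n_cells * G, as.vector(DP), as.vector(baf),
                          config$tau), n_cells, G)
  phase_flips <- stats::runif(G) < config$phase_error_rate
  AD[, phase_flips] <- DP[, phase_flips] - AD[, phase_flips]
  dataset <- cna_dataset(RD = RD, AD = AD, DP = DP, genes = genes,
                         cells = cells)
  truth <- list(
    loss = state_m %in% c("loss_hapA", "loss_hapB"),
    gain = state_m %in% c("gain_hapA", "gain_hapB"),
    loh = state_m %in% c("cnloh_A", "cnloh_B"),
    wgd = state_m == "wgd",
    loss_hapA = state_m == "loss_hapA",
    loss_hapB = state_m == "loss_hapB")
  truth <- lapply(truth, function(m) {
    m <- matrix(m, n_cells, G)
    dimnames(m) <- list(cells$barcode, genes$gene_id)
    m
  })
  structure(list(dataset = dataset, truth = truth, clone = clone,
                 phase_flips = phase_flips,
                 expected = list(ratio = ratio, baf = baf),
                 profile = profile, config = config),
            class = "cna_sim")
}

#' @method print cna_sim
#' @export
print.cna_sim <- function(x, ...) {
  cat(sprintf("<cna_sim> %d cells x %d genes; clones: %s\n",
              nrow(x$dataset$RD), ncol(x$dataset$RD),
              paste(unique(x$clone), collapse = ", ")))
  invisible(x)
}

#' Simulation scenario presets
#'
#' Three stress scenarios on a synthetic 8-chromosome genome (375 genes per
#' chromosome, 3000 genes) with a shared tumor CNA background mirroring the
#' seed profile's structure: allele-specific gain on two chromosomes, loss
#' on one chromosome plus one arm, and copy-neutral LOH on four arms.
#'
#' * `subclonal_allele_loss`: two equal tumor subclones (125 + 125 cells by
#'   default) that differ only in which haplotype of chromosome 3 is lost.
#' * `ref_downsample`: the same profile with the reference group downsampled
#'   to `variant` (10 or 5) cells.
#' * `tumor_downsample`: tumor cells downsampled to `variant` (22, 10 or 5)
#'   cells total, split across the two subclones.
#'
#' @param name scenario name.
#' @param variant downsampling size (ignored for `subclonal_allele_loss`).
#' @param seed RNG seed stored in the returned config.
#' @param n_ref_cells,n_tumor_cells base population sizes (defaults 150 and
#'   250).
#' @return list with `profile` ([cna_profile()]) and `config`
#'   ([sim_config()]).
#' @export
scenario_preset <- function(name = c("subclonal_allele_loss", "ref_downsample",
                                     "tumor_downsample"),
                            variant = NULL, seed = 1L,
                            n_ref_cells = 150L, n_tumor_cells = 250L) {
  name <- match.arg(name)
  if (name == "ref_downsample") {
    if (!variant %in% c(10L, 5L)) stop("ref_downsample variant must be 10 or 5")
    n_ref_cells <- as.integer(variant)
  }
  if (name == "tumor_downsample") {
    if (!variant %in% c(22L, 10L, 5L)) {
      stop("tumor_downsample variant must be 22, 10 or 5")
    }
    n_tumor_cells <- as.integer(variant)
  }
  n1 <- ceiling(n_tumor_cells / 2)
  n2 <- n_tumor_cells - n1
  clones <- tibble::tibble(clone_id = c("clone1", "clone2"),
                           n_cells = c(n1, n2))
  shared <- tibble::tribble(
    ~chrom, ~arm, ~state,
    "2",  NA,  "gain_hapB",
    "5",  NA,  "gain_hapA",
    "4",  NA,  "loss_hapA",
    "6",  "p", "loss_hapB",
    "6",  "q", "cnloh_A",
    "7",  "p", "cnloh_B",
    "7",  "q", "cnloh_A",
    "8",  "p", "cnloh_B")
  events <- dplyr::bind_rows(
    dplyr::mutate(shared, clone_id = "clone1"),
    dplyr::mutate(shared, clone_id = "clone2"),
    tibble::tibble(clone_id = c("clone1", "clone2"), chrom = "3",
                   arm = NA_character_,
                   state = c("loss_hapA", "loss_hapB")))
  profile <- cna_profile(clones, events)
  config <- sim_config(seed = seed, n_ref_cells = n_ref_cells,
                       n_chroms = 8L, genes_per_chrom = 375L)
  list(profile = profile, config = config)
}

#' Profile emulating a whole-genome-duplicated clone
#'
#' The tumor clone is WGD (ratio 2, balanced alleles) genome-wide except on
#' `diploid_arms`, which stay at absolute copy number 2. After library-size
#' normalisation those arms appear as relative copy loss with balanced
#' B-allele frequency - the joint signature the WGD warning detects.
#'
#' @param diploid_arms tibble with `chrom`, `arm` rows left diploid
#'   (default: chromosome 1 p and q on the 6-chromosome default genome).
#' @param n_tumor_cells tumor cells (default 150).
#' @param n_chroms genome size (default 6).
#' @return [cna_profile()].
#' @export
wgd_profile <- function(diploid_arms = tibble::tibble(chrom = "1", arm = c("p", "q")),
                        n_tumor_cells = 150L, n_chroms = 6L) {
  all_arms <- tidyr::expand_grid(chrom = as.character(seq_len(n_chroms)),
                                 arm = c("p", "q"))
  wgd_arms <- dplyr::anti_join(all_arms, diploid_arms, by = c("chrom", "arm"))
  clones <- tibble::tibble(clone_id = "tumor", n_cells = n_tumor_cells)
  events <- dplyr::mutate(wgd_arms, clone_id = "tumor", state = "wgd")
  cna_profile(clones, events)
}
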