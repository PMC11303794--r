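logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Local (gene-to-bin) phasing by EM
#'
#' Within one gene bin, reference-based phasing errors appear as per-gene
#' haplotype flips. The model forces a common per-cell allele frequency
#' `theta_c` for all genes in the bin and treats a flip indicator `f_g` per
#' gene as latent: `AD'_{c,g} = f_g (DP - AD) + (1 - f_g) AD`, with
#' `AD'_{c,g} ~ Binomial(DP_{c,g}, theta_c)`. EM alternates the flip
#' posterior (E-step, uniform prior) with `theta_c = sum_g E[AD'] / sum_g DP`
#' (M-step); cells with zero bin depth are excluded from the M-step.
#'
#' Initialisation is deterministic: all genes start unflipped, so the first
#' M-step estimates each cell's observed bin allele frequency and genes are
#' flipped relative to the bin's majority orientation. This keeps the bin's
#' natural (reference-phasing) haplotype orientation rather than forcing
#' every imbalanced bin onto the same allele side. In a fully balanced bin
#' the likelihood is flat in the flips and all genes are returned
#' unflipped.
#'
#' @param AD,DP cell-by-gene count matrices for the genes of one bin.
#' @param max_iter,tol EM stopping rule: stop when `max |delta theta| < tol`
#'   (default `1e-6`) or after `max_iter` (default 100) iterations.
#' @return list with `flips` (logical per gene, posterior > 0.5),
#'   `posterior` (flip posterior per gene), `AD_phased` (flips applied),
#'   `theta` (per-cell bin allele frequency), `loglik` (marginal
#'   log-likelihood trace, non-decreasing), `converged`.
#' @export
local_phase_bin <- function(AD, DP, max_iter = 100L, tol = 1e-6) {
  AD <- as.matrix(AD); DP <- as.matrix(DP)
  stopifnot(all(dim(AD) == dim(DP)), all(AD <= DP), all(AD >= 0))
  G <- ncol(AD)
  if (all(DP == 0)) {
    warning("bin has zero allelic depth everywhere; identity flips returned")
    return(list(flips = rep(FALSE, G), posterior = rep(0.5, G), AD_phased = AD,
                theta = rep(0.5, nrow(AD)), loglik = numeric(0), converged = TRUE))
  }
  # start from the reference-phasing orientation: no flips, so the first
  # M-step theta is each cell's observed bin allele frequency and genes are
  # then flipped relative to the bin majority; keeps the bin's natural
  # haplotype orientation (A- and B-sided bins both occur downstream).
  # When every cell's observed bin frequency is exactly 0.5 (a perfectly
  # antisymmetric flip mix) that start is a saddle point, so fall back to
  # the per-gene pooled-frequency sign to break the symmetry.
  r <- numeric(G)
  theta_obs <- ifelse(rowSums(DP) > 0, rowSums(AD) / rowSums(DP), 0.5)
  if (all(abs(theta_obs - 0.5) < 1e-9)) {
    pooled <- ifelse(colSums(DP) > 0, colSums(AD) / pmax(colSums(DP), 1L), 0.5)
    r <- as.numeric(pooled < 0.5)
  }
  dp_cell <- rowSums(DP)
  D2A <- DP - 2 * AD
  theta <- rep(0.5, nrow(AD))
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step: per-cell theta under current flip posteriors
    EADp <- AD + sweep(DP - 2 * AD, 2, r, `*`)   # E[AD'] = AD + r*(DP-2AD)
    theta_new <- ifelse(dp_cell > 0, rowSums(EADp) / dp_cell, 0.5)
    theta_new <- pmin(pmax(theta_new, 1e-6), 1 - 1e-6)
    # E-step: flip posterior per gene
    lg_odds <- as.numeric(crossprod(D2A, log(theta_new / (1 - theta_new))))
    r <- 1 / (1 + exp(-lg_odds))
    # marginal log-likelihood (flip prior 1/2; binomial coefficients constant)
    l0 <- as.numeric(crossprod(AD, log(theta_new)) + crossprod(DP - AD, log(1 - theta_new)))
    loglik <- c(loglik, sum(logsumexp2(l0, l0 + lg_odds) + log(0.5)))
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (it > 1L && delta < tol) { converged <- TRUE; break }
  }
  flips <- r > 0.5
  AD_phased <- AD
  AD_phased[, flips] <- DP[, flips] - AD[, flips]
  list(flips = flips, posterior = r, AD_phased = AD_phased, theta = theta,
       loglik = loglik, converged = converged)
}

orient_baf <- function(v, flip) if (flip) 1 - v else v

#' Global (bin-to-arm) phasing by dynamic programming
#'
#' Chooses per-bin flips along one chromosome arm that minimise the summed
#' Euclidean distance between consecutive oriented bin BAF vectors across
#' cells, exploiting the genomic auto-correlation of BAF deviation from 0.5.
#' Solved exactly in O(bins) by dynamic programming over the two flip states
#' per bin; the first bin is unflipped by convention.
#'
#' @param baf bins-by-cells matrix of (smoothed) allele frequencies in
#'   `[0, 1]`, rows in arm order.
#' @return list with `flips` (logical per bin) and `cost` (the minimised
#'   total distance).
#' @export
global_phase_arm <- function(baf) {
  baf <- as.matrix(baf)
  B <- nrow(baf)
  if (B <= 1L) return(list(flips = rep(FALSE, B), cost = 0))
  d <- function(u, v) sqrt(sum((u - v)^2))
  # cost[s+1] = best cost ending at current bin with flip state s
  cost <- c(0, Inf)                      # first bin unflipped
  ptr <- matrix(NA_integer_, B, 2)
  for (i in 2:B) {
    new_cost <- c(Inf, Inf)
    for (s in 0:1) {
      vi <- orient_baf(baf[i, ], s == 1)
      cands <- vapply(0:1, function(sp) {
        cost[sp + 1] + d(orient_baf(baf[i - 1, ], sp == 1), vi)
      }, numeric(1))
      new_cost[s + 1] <- min(cands)
      ptr[i, s + 1] <- which.min(cands) - 1L
    }
    cost <- new_cost
  }
  flips <- integer(B)
  flips[B] <- which.min(cost) - 1L
  for (i in B:2) flips[i - 1] <- ptr[i, flips[i] + 1]
  list(flips = flips == 1L, cost = min(cost))
}

#' Three-level phasing of an allelic count dataset to bin scale
#'
#' Runs the local EM phasing per gene bin, sums the phased gene counts into
#' bin-level AD/DP, then applies the global dynamic-programming phasing per
#' chromosome arm on WMA-smoothed (optionally also KNN-smoothed) bin allele
#' frequencies. Flipping exchanges `AD <-> DP - AD`; DP is unchanged.
#'
#' Bins without any allelic depth pass through unflipped and are excluded
#' from the arm distance chain.
#'
#' @param dataset a [cna_dataset()] with AD/DP present.
#' @param binmap [make_bins()] output (restrict beforehand to the genes to
#'   phase, e.g. after marker-gene removal).
#' @param wma_t WMA window (in bins) for the global-phasing input
#'   (default 101).
#' @param M optional cell-by-cell KNN connectivity matrix applied before
#'   global phasing.
#' @return list with `AD` and `DP` (cell-by-bin matrices), `bins`
#'   ([bin_info()] table with `chrom`, `arm`), `local_flips` tibble
#'   (`gene_id`, `flipped`), `global_flips` tibble (`bin_id`, `flipped`),
#'   `baf_smooth` (the smoothed bin BAF after global phasing).
#' @export
phase_dataset <- function(dataset, binmap, wma_t = 101L, M = NULL) {
  stopifnot(!is.null(dataset$AD))
  genes_use <- binmap$gene_id
  AD <- dataset$AD[, genes_use, drop = FALSE]
  DP <- dataset$DP[, genes_use, drop = FALSE]
  bins <- bin_info(binmap)
  n_cells <- nrow(AD)
  AD_bin <- matrix(0, n_cells, nrow(bins),
                   dimnames = list(rownames(AD), paste0("bin", bins$bin_id)))
  DP_bin <- AD_bin
  local_flips <- logical(length(genes_use))
  names(local_flips) <- genes_use
  for (b in seq_len(nrow(bins))) {
    in_bin <- binmap$bin_id == bins$bin_id[b]
    sub_AD <- AD[, in_bin, drop = FALSE]
    sub_DP <- DP[, in_bin, drop = FALSE]
    fit <- if (all(sub_DP == 0)) {
      list(flips = rep(FALSE, sum(in_bin)), AD_phased = sub_AD)
    } else {
      local_phase_bin(sub_AD, sub_DP)
    }
    local_flips[in_bin] <- fit$flips
    AD_bin[, b] <- rowSums(fit$AD_phased)
    DP_bin[, b] <- rowSums(sub_DP)
  }
  # smoothed bin BAF for global phasing
  baf <- AD_bin / DP_bin
  baf[DP_bin == 0] <- 0.5
  bin_anno <- tibble::tibble(gene_id = paste0("bin", bins$bin_id),
                             chrom = bins$chrom, arm = bins$arm,
                             order = seq_len(nrow(bins)) - 1L)
  W <- wma_matrix(bin_anno, t = wma_t)
  baf_s <- baf %*% W
  if (!is.null(M)) baf_s <- as.matrix(M %*% baf_s)
  baf_s <- as.matrix(baf_s)
  global_flips <- logical(nrow(bins))
  arm_key <- paste(bins$chrom, bins$arm)
  informative <- colSums(DP_bin) > 0
  for (a in unique(arm_key)) {
    in_arm <- which(arm_key == a & informative)
    if (length(in_arm) < 2L) next
    fit <- global_phase_arm(t(baf_s[, in_arm, drop = FALSE]))
    global_flips[in_arm] <- fit$flips
  }
  AD_bin[, global_flips] <- DP_bin[, global_flips] - AD_bin[, global_flips]
  baf_s[, global_flips] <- 1 - baf_s[, global_flips]
  list(AD = AD_bin, DP = DP_bin, bins = bins,
       local_flips = tibble::tibble(gene_id = genes_use, flipped = unname(local_flips)),
       global_flips = tibble::tibble(bin_id = bins$bin_id, flipped = global_flips),
       baf_smooth = baf_s)
}

#' Write phasing flip records as TSV
#' @param phased output of [phase_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flip_record <- function(phased, path) {
  rec <- dplyr::bind_rows(
    tibble::tibble(feature_id = phased$local_flips$gene_id, scope = "bin",
                   flipped = phased$local_flips$flipped),
    tibble::tibble(feature_id = paste0("bin", phased$global_flips$bin_id),
                   scope = "arm", flipped = phased$global_flips$flipped))
  readr::write_tsv(rec, path)
  invisible(path)
}
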