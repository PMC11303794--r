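RDR_STATES <- c("loss", "neutral", "gain")

#' Expression-based gene filter
#'
#' Retains genes whose mean raw count over the reference cells reaches the
#' platform threshold (0.5 for droplet/10x, 1.8 for smart-seq) and which are
#' not among the top `n_top_markers` marker genes of any annotated cell
#' group (one-vs-rest rank-sum test on log-normalised counts, ranked by the
#' upregulation z-score). Marker removal is skipped with a warning when only
#' one cell type is annotated.
#'
#' @param dataset a [cna_dataset()].
#' @param platform `"droplet"` or `"smartseq"`.
#' @param n_top_markers markers removed per group (default 15; 0 disables).
#' @return logical mask over `dataset$genes` rows.
#' @export
filter_genes <- function(dataset, platform = c("droplet", "smartseq"),
                         n_top_markers = 15L) {
  platform <- match.arg(platform)
  thr <- c(droplet = 0.5, smartseq = 1.8)[[platform]]
  if (!any(dataset$cells$is_reference)) stop("no reference cells designated")
  ref_mean <- colMeans(dataset$RD[dataset$cells$is_reference, , drop = FALSE])
  keep <- ref_mean >= thr
  if (n_top_markers > 0L) {
    groups <- dataset$cells$cell_type
    if (length(unique(groups)) < 2L) {
      warning("only one cell group annotated; marker removal skipped")
    } else {
      markers <- rank_marker_genes(dataset$RD, groups, n_top_markers)
      keep <- keep & !(dataset$genes$gene_id %in% markers)
    }
  }
  unname(keep)
}

# one-vs-rest Wilcoxon rank-sum z-scores on log-normalised counts;
# returns the union of the top-n upregulated genes per group
rank_marker_genes <- function(RD, groups, n_top) {
  tot <- rowSums(RD)
  tot[tot == 0] <- 1
  X <- log1p(RD / tot * 1e4)
  R <- apply(X, 2, rank)
  n <- nrow(X)
  out <- character(0)
  for (g in unique(groups)) {
    in_g <- groups == g
    n1 <- sum(in_g); n2 <- n - n1
    if (n1 == 0L || n2 == 0L) next
    rank_sum <- colSums(R[in_g, , drop = FALSE])
    u <- rank_sum - n1 * (n1 + 1) / 2
    z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
    out <- union(out, colnames(RD)[order(z, decreasing = TRUE)[seq_len(min(n_top, ncol(RD)))]])
  }
  out
}

#' Cell library-size factors relative to the reference group
#'
#' `l_c` is the ratio of the cell's total count (over the supplied genes) to
#' the mean total of the reference cells.
#'
#' @param RD cell-by-gene count matrix (retained genes only).
#' @param cells cell annotation with `is_reference`.
#' @return numeric vector of per-cell factors.
#' @export
estimate_library_factors <- function(RD, cells) {
  tot <- rowSums(RD)
  if (any(tot == 0)) {
    stop("cells with zero total count: ",
         paste(cells$barcode[tot == 0], collapse = ", "))
  }
  tot / mean(tot[cells$is_reference])
}

nb_neg_loglik <- function(log10_phi, x, mu) {
  -sum(dnbinom(x, size = 10^(-log10_phi), mu = mu, log = TRUE))
}

#' Per-gene negative-binomial dispersion on reference cells
#'
#' Fits the NB dispersion `phi_g` by maximum likelihood with the mean fixed
#' at `l_c * X_ref_g` (the copy-neutral model), gene by gene on the
#' reference cells. The optimisation is bounded on the log scale in
#' `[1e-8, 100]`; failures and boundary fits at the lower bound are floored
#' to `1e-8` and flagged.
#'
#' @param RD cell-by-gene counts (retained genes).
#' @param cells cell annotation (`is_reference` used).
#' @param l library factors from [estimate_library_factors()].
#' @param X_ref per-gene reference mean count.
#' @return tibble with `gene_id`, `phi`, `flagged`.
#' @export
fit_dispersions <- function(RD, cells, l, X_ref) {
  ref <- cells$is_reference
  if (sum(ref) < 2L) stop("need at least 2 reference cells")
  Xr <- RD[ref, , drop = FALSE]
  lr <- l[ref]
  phi <- numeric(ncol(Xr))
  flagged <- logical(ncol(Xr))
  for (g in seq_len(ncol(Xr))) {
    mu <- lr * X_ref[g]
    fit <- tryCatch(
      optimize(nb_neg_loglik, interval = c(-8, 2), x = Xr[, g], mu = mu),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) {
      phi[g] <- 1e-8; flagged[g] <- TRUE
    } else {
      phi[g] <- 10^fit$minimum
      if (phi[g] <= 1e-8 * 1.5) { phi[g] <- 1e-8; flagged[g] <- TRUE }
    }
  }
  tibble::tibble(gene_id = colnames(RD), phi = phi, flagged = flagged)
}

#' Copy-number ratios per state
#'
#' In `theoretical` mode returns the diploid-relative ratios
#' `(0.5, 1, 1.5)` for (loss, neutral, gain). In `guided` mode the
#' chromosome arms are ranked by their mean smoothed read-depth ratio; the
#' lowest, median and highest arms anchor the loss, neutral and gain
#' regions, and `C_k` is the stated quantile (defaults 0.0001, 0.96, 0.99)
#' of that arm's smoothed ratio entries over non-reference cells
#' (identically, the exponential of the same quantile of the log ratio:
#' quantiles commute with monotone transforms; smoothing is done on the
#' linear ratio so that sparse zero counts average out unbiasedly). Falls
#' back to theoretical values (with a warning) when fewer than 3 arms are
#' available or the guided estimates are not strictly increasing.
#'
#' @param ratio_smooth smoothed cell-by-gene read-depth ratio
#'   (linear scale).
#' @param genes annotation of those genes (`chrom`, `arm`).
#' @param cells cell annotation; quantiles use non-reference cells.
#' @param mode `"theoretical"` or `"guided"`.
#' @param quantiles named numeric: `loss`, `neutral`, `gain`.
#' @return named numeric `c(loss=, neutral=, gain=)`.
#' @export
estimate_cna_ratios <- function(ratio_smooth = NULL, genes = NULL, cells = NULL,
                                mode = c("theoretical", "guided"),
                                quantiles = c(loss = 1e-4, neutral = 0.96, gain = 0.99)) {
  mode <- match.arg(mode)
  theo <- c(loss = 0.5, neutral = 1, gain = 1.5)
  if (mode == "theoretical") return(theo)
  arm_key <- paste0(genes$chrom, genes$arm)
  arms <- unique(arm_key)
  if (length(arms) < 3L) {
    warning("fewer than 3 arms; falling back to theoretical CNA ratios")
    return(theo)
  }
  X <- ratio_smooth[!cells$is_reference, , drop = FALSE]
  arm_mean <- vapply(arms, function(a) mean(X[, arm_key == a, drop = FALSE]), numeric(1))
  ord <- order(arm_mean)
  pick <- c(loss = arms[ord[1]],
            neutral = arms[ord[ceiling(length(arms) / 2)]],
            gain = arms[ord[length(arms)]])
  C <- vapply(names(pick), function(s) {
    unname(quantile(X[, arm_key == pick[[s]], drop = FALSE], quantiles[[s]]))
  }, numeric(1))
  names(C) <- names(pick)
  if (!(C[1] < C[2] && C[2] < C[3])) {
    warning("guided CNA ratios not strictly increasing; using theoretical values")
    return(theo)
  }
  C
}

#' Negative-binomial emission tensor for the expression module
#'
#' Evaluates, for each cell, gene and copy state, the NB density
#' `NB(X_{c,g} | l_c * X_ref_g * C_k, phi_g)` and normalises over the three
#' states (loss, neutral, gain).
#'
#' @param RD cell-by-gene counts (retained genes).
#' @param l per-cell library factors.
#' @param X_ref per-gene reference means.
#' @param phi per-gene NB dispersions.
#' @param C state ratios from [estimate_cna_ratios()].
#' @return `state_tensor` (cells x genes x 3) at gene scale.
#' @export
rdr_emission <- function(RD, l, X_ref, phi, C = c(loss = 0.5, neutral = 1, gain = 1.5)) {
  RD <- as.matrix(RD)
  n_c <- nrow(RD); n_g <- ncol(RD)
  mu0 <- outer(l, X_ref)
  size <- matrix(1 / phi, n_c, n_g, byrow = TRUE)
  logd <- array(0, dim = c(n_c, n_g, 3))
  for (k in 1:3) {
    logd[, , k] <- dnbinom(RD, size = size, mu = mu0 * C[k], log = TRUE)
  }
  normalize_log_tensor(logd, RDR_STATES, scale = "gene")
}

# softmax a cells x features x K log-density array into a state_tensor
normalize_log_tensor <- function(logd, states, scale) {
  mx <- pmax(logd[, , 1], logd[, , 2])
  for (k in seq_len(dim(logd)[3])[-(1:2)]) mx <- pmax(mx, logd[, , k])
  mx[!is.finite(mx)] <- 0
  tot <- 0
  for (k in seq_len(dim(logd)[3])) tot <- tot + exp(logd[, , k] - mx)
  P <- array(0, dim = dim(logd))
  zero <- tot == 0
  for (k in seq_len(dim(logd)[3])) {
    slice <- exp(logd[, , k] - mx) / tot
    slice[zero] <- 1 / dim(logd)[3]
    P[, , k] <- slice
  }
  state_tensor(P, states, scale = scale)
}

#' Fit the read-depth-ratio (expression) module
#'
#' End-to-end RDR fit: gene filtering, library factors, reference profile,
#' per-gene NB dispersions on reference cells, guided or theoretical CNA
#' ratios from the smoothed log ratio, and the emission tensor.
#'
#' @param dataset a [cna_dataset()].
#' @param platform `"droplet"` or `"smartseq"`.
#' @param ratio_mode `"guided"` (default) or `"theoretical"`.
#' @param n_top_markers marker genes removed per group (default 15).
#' @param wma_t WMA window for the smoothed ratio (default 40).
#' @param M optional precomputed KNN matrix (computed from `dataset$RD`
#'   when `NULL`).
#' @param knn_k neighbours for the KNN matrix (default 10).
#' @return object of class `rdr_fit`: list with `emission` (state tensor),
#'   `gene_mask`, `genes`, `l`, `X_ref`, `dispersion` (tibble), `C`,
#'   `log_ratio_smooth`, `M`.
#' @export
rdr_fit <- function(dataset, platform = c("droplet", "smartseq"),
                    ratio_mode = c("guided", "theoretical"),
                    n_top_markers = 15L, wma_t = 40L, M = NULL, knn_k = 10L) {
  platform <- match.arg(platform)
  ratio_mode <- match.arg(ratio_mode)
  mask <- filter_genes(dataset, platform, n_top_markers)
  if (!any(mask)) stop("no genes pass the expression filter")
  RD <- dataset$RD[, mask, drop = FALSE]
  genes <- dataset$genes[mask, , drop = FALSE]
  l <- estimate_library_factors(RD, dataset$cells)
  X_ref <- colMeans(RD[dataset$cells$is_reference, , drop = FALSE])
  disp <- fit_dispersions(RD, dataset$cells, l, X_ref)
  if (is.null(M)) M <- knn_matrix(dataset$RD, k = knn_k)
  # guided-C smoothing on the linear ratio (zeros average out unbiasedly);
  # the log of the smoothed ratio is kept for visualisation
  ratio <- sweep(RD / l, 2, X_ref, `/`)
  W <- wma_matrix(genes, t = wma_t)
  ratio_s <- smooth_matrix(ratio, M, W)
  C <- estimate_cna_ratios(ratio_s, genes, dataset$cells, mode = ratio_mode)
  lrs <- log(pmax(ratio_s, 1e-3))
  em <- rdr_emission(RD, l, X_ref, disp$phi, C)
  structure(list(emission = em, gene_mask = mask, genes = genes, l = l,
                 X_ref = X_ref, dispersion = disp, C = C,
                 log_ratio_smooth = lrs, M = M, platform = platform),
            class = "rdr_fit")
}

#' @method print rdr_fit
#' @export
print.rdr_fit <- function(x, ...) {
  cat(sprintf("<rdr_fit> %d cells x %d genes; C = (%.3f, %.3f, %.3f)\n",
              nrow(x$emission), ncol(x$emission), x$C[1], x$C[2], x$C[3]))
  invisible(x)
}
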