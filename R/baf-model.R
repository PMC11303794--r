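BAF_STATES_5 <- c("A_strong", "A_minor", "balanced", "B_minor", "B_strong")
BAF_STATES_3 <- c("A_bias", "balanced", "B_bias")
THEORETICAL_RHO_5 <- c(0, 1/3, 0.5, 2/3, 1)
THEORETICAL_RHO_3 <- c(0, 0.5, 1)

#' Beta-binomial density (mean/concentration parameterisation)
#'
#' `alpha = rho * tau`, `beta = (1 - rho) * tau`. The degenerate means
#' `rho = 0` and `rho = 1` are the point masses at 0 and `size`.
#'
#' @param x successes; @param size trials; @param rho mean success rate;
#' @param tau concentration; @param log return log density.
#' @return density values, recycled over the longest argument.
#' @export
dbetabinom <- function(x, size, rho, tau, log = FALSE) {
  n <- max(length(x), length(size), length(rho), length(tau))
  x <- rep_len(x, n); size <- rep_len(size, n)
  rho <- rep_len(rho, n); tau <- rep_len(tau, n)
  ld <- numeric(n)
  deg0 <- rho <= 0; deg1 <- rho >= 1
  reg <- !deg0 & !deg1
  if (any(reg)) {
    a <- rho[reg] * tau[reg]; b <- (1 - rho[reg]) * tau[reg]
    ld[reg] <- lchoose(size[reg], x[reg]) +
      lbeta(x[reg] + a, size[reg] - x[reg] + b) - lbeta(a, b)
  }
  ld[deg0] <- ifelse(x[deg0] == 0, 0, -Inf)
  ld[deg1] <- ifelse(x[deg1] == size[deg1], 0, -Inf)
  if (log) ld else exp(ld)
}

rbetabinom <- function(n, size, rho, tau) {
  size <- rep_len(size, n); rho <- rep_len(rho, n); tau <- rep_len(tau, n)
  p <- numeric(n)
  reg <- rho > 0 & rho < 1
  p[reg] <- rbeta(sum(reg), rho[reg] * tau[reg], (1 - rho[reg]) * tau[reg])
  p[rho >= 1] <- 1
  rbinom(n, size, p)
}

#' Allelic-bias state frequencies from smoothed BAF
#'
#' The copy-neutral (balanced) expected B-allele frequency per bin is the
#' reference-cell mean of the smoothed BAF (0.5 when fewer than
#' `min_ref_cells` reference cells are available). The four biased-state
#' frequencies come from a 5-component 1-D Gaussian mixture fitted to all
#' smoothed BAF entries, components matched to states by sorted means; the
#' minor-bias components are clipped to `[0.01, 0.99]`. On GMM failure the
#' theoretical frequencies `(0, 1/3, 1/2, 2/3, 1)` are used with a warning.
#'
#' @param baf_smooth cell-by-bin smoothed B-allele frequencies in `[0, 1]`.
#' @param cells cell annotation (`is_reference` used).
#' @param min_ref_cells minimum reference cells for the neutral estimate
#'   (default 20).
#' @param tau beta-binomial concentration (default 100, the droplet
#'   default; supply a per-bin vector for smart-seq).
#' @return object of class `baf_params`: list with `rho` (bin-by-5 matrix),
#'   `tau`, `states`, `theoretical` flag.
#' @export
estimate_rho <- function(baf_smooth, cells, min_ref_cells = 20L, tau = 100) {
  n_bins <- ncol(baf_smooth)
  neutral <- if (sum(cells$is_reference) >= min_ref_cells) {
    colMeans(baf_smooth[cells$is_reference, , drop = FALSE])
  } else rep(0.5, n_bins)
  comp <- tryCatch({
    x <- as.vector(baf_smooth)
    # constant or near-constant input sends the mixture init into all-tie
    # territory; treat as degenerate up front
    if (length(unique(round(x, 8))) < 10L) stop("too few distinct values")
    fit <- mclust::Mclust(x, G = 5, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) stop("mclust failed")
    sort(as.numeric(fit$parameters$mean))
  }, error = function(e) NULL)
  theoretical <- FALSE
  if (is.null(comp) || length(unique(round(comp, 6))) < 5L) {
    warning("GMM on smoothed BAF degenerate; using theoretical allele frequencies")
    comp <- THEORETICAL_RHO_5
    theoretical <- TRUE
  }
  comp[c(2, 4)] <- pmin(pmax(comp[c(2, 4)], 0.01), 0.99)
  rho <- cbind(comp[1], comp[2], neutral, comp[4], comp[5])
  rho <- t(apply(rho, 1, sort))           # enforce non-decreasing state order
  colnames(rho) <- BAF_STATES_5
  structure(list(rho = rho, tau = tau, states = BAF_STATES_5,
                 theoretical = theoretical),
            class = "baf_params")
}

#' Theoretical allelic-bias parameters
#'
#' @param n_bins number of gene bins.
#' @param tau concentration (default 100).
#' @param n_states 5 (default) or 3.
#' @return `baf_params` with the theoretical frequencies
#'   `(0, 1/3, 1/2, 2/3, 1)` (or `(0, 1/2, 1)`).
#' @export
theoretical_baf_params <- function(n_bins, tau = 100, n_states = 5L) {
  if (n_states == 5L) {
    rho <- matrix(THEORETICAL_RHO_5, n_bins, 5, byrow = TRUE,
                  dimnames = list(NULL, BAF_STATES_5))
    states <- BAF_STATES_5
  } else {
    rho <- matrix(THEORETICAL_RHO_3, n_bins, 3, byrow = TRUE,
                  dimnames = list(NULL, BAF_STATES_3))
    states <- BAF_STATES_3
  }
  structure(list(rho = rho, tau = tau, states = states, theoretical = TRUE),
            class = "baf_params")
}

#' Collapse allelic-bias parameters to the 3-state mode
#'
#' Allele-A bias, balance and allele-B bias with theoretical frequencies
#' `(0, 0.5, 1)`; the balanced column keeps the per-bin neutral estimate.
#'
#' @param params `baf_params` (5-state).
#' @return `baf_params` with 3 states.
#' @export
three_state_mode <- function(params) {
  stopifnot(inherits(params, "baf_params"), length(params$states) == 5L)
  rho <- cbind(0, params$rho[, "balanced"], 1)
  colnames(rho) <- BAF_STATES_3
  structure(list(rho = rho, tau = params$tau, states = BAF_STATES_3,
                 theoretical = params$theoretical),
            class = "baf_params")
}

#' Per-bin beta-binomial concentration for smart-seq data
#'
#' Fits `tau` per bin by maximum likelihood on reference cells with the mean
#' fixed at the bin's neutral allele frequency, floored at 5.
#'
#' @param AD,DP cell-by-bin phased counts.
#' @param cells cell annotation.
#' @param rho_neutral per-bin neutral frequency.
#' @return numeric vector of per-bin concentrations.
#' @export
fit_tau <- function(AD, DP, cells, rho_neutral = NULL) {
  ref <- cells$is_reference
  if (is.null(rho_neutral)) rho_neutral <- rep(0.5, ncol(AD))
  vapply(seq_len(ncol(AD)), function(b) {
    a <- AD[ref, b]; d <- DP[ref, b]
    use <- d > 0
    if (sum(use) < 2L) return(100)
    nll <- function(lt) -sum(dbetabinom(a[use], d[use], rho_neutral[b], 10^lt, log = TRUE))
    max(5, 10^optimize(nll, c(log10(5), 4))$minimum)
  }, numeric(1))
}

#' Beta-binomial emission tensor for the allelic module
#'
#' Evaluates `BB(a | d, rho_{g,k}, tau)` per cell, bin and allelic state and
#' normalises over states. Entries with `d = 0` are uniform over states.
#'
#' @param AD,DP cell-by-bin phased allelic counts (`0 <= AD <= DP`).
#' @param params `baf_params`.
#' @return `state_tensor` (cells x bins x K) at `gene_bin` scale.
#' @export
baf_emission <- function(AD, DP, params) {
  AD <- as.matrix(AD); DP <- as.matrix(DP)
  stopifnot(all(AD <= DP), all(AD >= 0))
  K <- length(params$states)
  n_c <- nrow(AD); n_b <- ncol(AD)
  tau <- rep_len(params$tau, n_b)
  logd <- array(0, dim = c(n_c, n_b, K))
  for (k in seq_len(K)) {
    rho_k <- matrix(params$rho[, k], n_c, n_b, byrow = TRUE)
    tau_m <- matrix(tau, n_c, n_b, byrow = TRUE)
    logd[, , k] <- dbetabinom(AD, DP, rho_k, tau_m, log = TRUE)
  }
  normalize_log_tensor(logd, params$states, scale = "gene_bin")
}

#' Fit the B-allele-frequency (allelic) module
#'
#' Phases the allelic counts to bin scale (local EM + global DP), estimates
#' the state allele frequencies from the smoothed bin BAF, and evaluates the
#' beta-binomial emission tensor.
#'
#' @param dataset a [cna_dataset()] with AD/DP.
#' @param binmap [make_bins()] output over the genes to use.
#' @param M optional cell-by-cell KNN matrix (computed from expression when
#'   `NULL`).
#' @param tau concentration (default 100); `"fit"` fits per bin
#'   (smart-seq).
#' @param n_states 5 (default) or 3.
#' @param min_ref_cells see [estimate_rho()].
#' @param wma_t WMA window in bins (default 101).
#' @param knn_k neighbours when computing `M` (default 10).
#' @return object of class `baf_fit`: list with `emission` (bin scale),
#'   `params`, `phased`, `binmap`, `M`.
#' @export
baf_fit <- function(dataset, binmap, M = NULL, tau = 100, n_states = 5L,
                    min_ref_cells = 20L, wma_t = 101L, knn_k = 10L) {
  if (is.null(M)) M <- knn_matrix(dataset$RD, k = knn_k)
  phased <- phase_dataset(dataset, binmap, wma_t = wma_t, M = M)
  if (identical(tau, "fit")) {
    tau <- fit_tau(phased$AD, phased$DP, dataset$cells)
  }
  params <- estimate_rho(phased$baf_smooth, dataset$cells,
                         min_ref_cells = min_ref_cells, tau = tau)
  if (n_states == 3L) params <- three_state_mode(params)
  em <- baf_emission(phased$AD, phased$DP, params)
  structure(list(emission = em, params = params, phased = phased,
                 binmap = binmap, M = M),
            class = "baf_fit")
}

#' @method print baf_fit
#' @export
print.baf_fit <- function(x, ...) {
  cat(sprintf("<baf_fit> %d cells x %d bins; %d allelic states\n",
              nrow(x$emission), ncol(x$emission), length(x$params$states)))
  invisible(x)
}
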