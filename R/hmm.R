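#' HMM configuration for genome smoothing
#'
#' Homogeneous transition model: probability `trans_t` for every cross-state
#' transition and `1 - (K-1) * trans_t` for staying, with a fixed start
#' distribution.
#'
#' @param start probability vector over the K states (sums to 1). Defaults
#'   per module/platform: `c(0.1, 0.8, 0.1)` for the 3-state expression
#'   module on droplet data, `c(0.3, 0.4, 0.3)` on smart-seq, and
#'   `c(0.2, 0.15, 0.3, 0.15, 0.2)` for the 5-state allelic module.
#' @param trans_t cross-state transition probability (default `1e-6`).
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(start, trans_t = 1e-6) {
  stopifnot(abs(sum(start) - 1) < 1e-8, trans_t > 0,
            trans_t < 1 / (length(start) - 1))
  structure(list(start = start, trans_t = trans_t, K = length(start)),
            class = "hmm_config")
}

#' Default HMM start probabilities
#' @param module `"rdr"` or `"baf"`.
#' @param platform `"droplet"` or `"smartseq"` (expression module only).
#' @return numeric start vector.
#' @export
default_hmm_start <- function(module = c("rdr", "baf"),
                              platform = c("droplet", "smartseq")) {
  module <- match.arg(module)
  platform <- match.arg(platform)
  if (module == "baf") return(c(0.2, 0.15, 0.3, 0.15, 0.2))
  if (platform == "droplet") c(0.1, 0.8, 0.1) else c(0.3, 0.4, 0.3)
}

row_logsumexp <- function(M) {
  m <- as.numeric(do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j])))
  finite <- is.finite(m)
  out <- rep(-Inf, nrow(M))
  if (any(finite)) {
    out[finite] <- m[finite] +
      log(rowSums(exp(M[finite, , drop = FALSE] - m[finite])))
  }
  out
}

hmm_log_trans <- function(K, trans_t) {
  logT <- matrix(log(trans_t), K, K)
  diag(logT) <- log(1 - (K - 1) * trans_t)
  logT
}

#' Vertical (KNN) smoothing of a state probability tensor
#'
#' Left-multiplies every state slice by the effective row-stochastic cell
#' connectivity matrix `self_blend * I + (1 - self_blend) * M`, then
#' renormalises each (cell, feature) row over states. The self-blend keeps
#' at least `self_blend` of the mass on the cell's own emission, so a
#' neighbourhood majority cannot override strong per-cell evidence (e.g.
#' haplotype-specific states in transcriptomically identical subclones);
#' neighbours dominate exactly where the cell's own evidence is weak.
#'
#' @param tensor `state_tensor`.
#' @param M row-stochastic cell-by-cell matrix.
#' @param self_blend own-emission mass in `[0, 1)` (default 0.5; 0
#'   reproduces plain `M` smoothing).
#' @return smoothed `state_tensor`.
#' @export
smooth_emission <- function(tensor, M, self_blend = 0.5) {
  K <- dim(tensor)[3]
  out <- array(0, dim = dim(tensor))
  for (k in seq_len(K)) {
    out[, , k] <- self_blend * tensor[, , k] +
      (1 - self_blend) * as.matrix(M %*% tensor[, , k])
  }
  tot <- 0
  for (k in seq_len(K)) tot <- tot + out[, , k]
  for (k in seq_len(K)) out[, , k] <- out[, , k] / tot
  state_tensor(out, tensor_states(tensor), scale = attr(tensor, "scale"))
}

#' Forward-backward smoothing for one chain
#'
#' Exact posterior state probabilities (gamma) for a single cell along one
#' chromosome under the homogeneous transition model, computed in log space
#' with log-sum-exp. Zero emission rows are replaced by uniform rows with a
#' flag.
#'
#' @param emission features-by-K matrix of (unnormalised) emission
#'   probabilities, features in genome order.
#' @param config [hmm_config()].
#' @return list with `gamma` (features-by-K posteriors), `loglik`,
#'   `zero_rows` (indices replaced by uniform).
#' @export
forward_backward <- function(emission, config) {
  emission <- as.matrix(emission)
  L <- nrow(emission); K <- ncol(emission)
  stopifnot(K == config$K)
  zero_rows <- which(rowSums(emission) == 0)
  if (length(zero_rows) > 0L) emission[zero_rows, ] <- 1 / K
  logem <- log(emission)
  logT <- hmm_log_trans(K, config$trans_t)
  la <- matrix(-Inf, L, K)
  la[1, ] <- log(config$start) + logem[1, ]
  if (L > 1L) {
    for (i in 2:L) {
      for (k in seq_len(K)) {
        v <- la[i - 1, ] + logT[, k]
        m <- max(v)
        la[i, k] <- m + log(sum(exp(v - m))) + logem[i, k]
      }
    }
  }
  lb <- matrix(0, L, K)
  if (L > 1L) {
    for (i in (L - 1):1) {
      for (j in seq_len(K)) {
        v <- logT[j, ] + logem[i + 1, ] + lb[i + 1, ]
        m <- max(v)
        lb[i, j] <- m + log(sum(exp(v - m)))
      }
    }
  }
  lg <- la + lb
  gamma <- exp(lg - row_logsumexp(lg))
  mL <- max(la[L, ])
  list(gamma = gamma, loglik = mL + log(sum(exp(la[L, ] - mL))),
       zero_rows = zero_rows)
}

# forward-backward vectorised over cells for one chromosome:
# logem is cells x L x K; returns cells x L x K posterior array
fb_multi <- function(logem, start, trans_t) {
  n_c <- dim(logem)[1]; L <- dim(logem)[2]; K <- dim(logem)[3]
  logT <- hmm_log_trans(K, trans_t)
  la <- array(-Inf, dim(logem))
  la[, 1, ] <- matrix(log(start), n_c, K, byrow = TRUE) + logem[, 1, ]
  if (L > 1L) {
    for (i in 2:L) {
      prev <- la[, i - 1, , drop = TRUE]
      if (n_c == 1L) prev <- matrix(prev, 1, K)
      for (k in seq_len(K)) {
        la[, i, k] <- row_logsumexp(sweep(prev, 2, logT[, k], `+`)) + logem[, i, k]
      }
    }
  }
  lb <- array(0, dim(logem))
  if (L > 1L) {
    for (i in (L - 1):1) {
      nxt <- logem[, i + 1, , drop = TRUE] + lb[, i + 1, , drop = TRUE]
      if (n_c == 1L) nxt <- matrix(nxt, 1, K)
      for (j in seq_len(K)) {
        lb[, i, j] <- row_logsumexp(sweep(nxt, 2, logT[j, ], `+`))
      }
    }
  }
  lg <- la + lb
  for (i in seq_len(L)) {
    sl <- lg[, i, , drop = TRUE]
    if (n_c == 1L) sl <- matrix(sl, 1, K)
    lg[, i, ] <- exp(sl - row_logsumexp(sl))
  }
  lg
}

#' Genome-wide HMM state inference
#'
#' KNN-smooths the emission tensor across cells, then runs the
#' forward-backward algorithm along genome coordinates for every cell, with
#' independent chains per chromosome (chains reset at chromosome
#' boundaries, not at arms). Hard calls take the posterior argmax, ties
#' broken toward the neutral/balanced state.
#'
#' @param tensor emission `state_tensor` (cells x features x K).
#' @param M row-stochastic KNN matrix (or `NULL` to skip vertical
#'   smoothing).
#' @param config [hmm_config()].
#' @param feature_chrom chromosome of each feature (genome order).
#' @param neutral_state label used for tie-breaking.
#' @param self_blend own-emission mass kept during vertical smoothing (see
#'   [smooth_emission()]).
#' @return list with `posterior` (`state_tensor`) and `calls`
#'   (cell-by-feature factor matrix of state labels).
#' @export
infer_states <- function(tensor, M, config, feature_chrom,
                         neutral_state = "neutral", self_blend = 0.5) {
  states <- tensor_states(tensor)
  stopifnot(length(feature_chrom) == dim(tensor)[2],
            neutral_state %in% states)
  if (!is.null(M)) tensor <- smooth_emission(tensor, M, self_blend)
  K <- dim(tensor)[3]
  post <- array(0, dim = dim(tensor))
  feature_chrom <- as.character(feature_chrom)
  for (chrom in unique(feature_chrom)) {
    idx <- which(feature_chrom == chrom)
    logem <- log(tensor[, idx, , drop = FALSE])
    logem[!is.finite(logem)] <- -745   # log(.Machine$double.xmin) floor
    post[, idx, ] <- fb_multi(logem, config$start, config$trans_t)
  }
  post <- state_tensor(post, states, scale = attr(tensor, "scale"))
  calls <- apply_argmax(post, which(states == neutral_state))
  list(posterior = post, calls = calls)
}

# argmax over states with ties to `neutral_index`
apply_argmax <- function(tensor, neutral_index) {
  states <- tensor_states(tensor)
  K <- length(states)
  n_c <- dim(tensor)[1]; n_f <- dim(tensor)[2]
  best <- matrix(neutral_index, n_c, n_f)
  best_p <- tensor[, , neutral_index, drop = TRUE]
  if (n_c == 1L || n_f == 1L) best_p <- matrix(best_p, n_c, n_f)
  for (k in seq_len(K)) {
    if (k == neutral_index) next
    pk <- tensor[, , k, drop = TRUE]
    if (n_c == 1L || n_f == 1L) pk <- matrix(pk, n_c, n_f)
    better <- pk > best_p
    best[better] <- k
    best_p[better] <- pk[better]
  }
  calls <- matrix(states[best], n_c, n_f,
                  dimnames = dimnames(tensor)[1:2])
  calls
}
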