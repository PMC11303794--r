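#' Area under the ROC curve (rank statistic)
#'
#' Exact AUROC via the Mann-Whitney U statistic with midranks for ties;
#' equivalent to the trapezoidal area under the full ROC curve.
#'
#' @param score numeric prediction scores.
#' @param truth logical (or 0/1) labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- as.numeric(sum(truth)); n0 <- as.numeric(sum(!truth))
  if (n1 == 0 || n0 == 0) stop("truth needs at least one positive and one negative")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated (average-precision) AUPRC.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(score, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) stop("truth needs both classes")
  ord <- order(score, decreasing = TRUE)
  t_sorted <- truth[ord]
  tp <- cumsum(t_sorted)
  prec <- tp / seq_along(tp)
  sum(prec[t_sorted]) / sum(truth)
}

roc_curve_points <- function(score, truth, n_points = 200L) {
  truth <- as.logical(truth)
  ord <- order(score, decreasing = TRUE)
  t_sorted <- truth[ord]
  tpr <- cumsum(t_sorted) / sum(truth)
  fpr <- cumsum(!t_sorted) / sum(!truth)
  keep <- unique(c(1L, round(seq(1, length(tpr), length.out = n_points)),
                   length(tpr)))
  tibble::tibble(threshold = score[ord][keep], fpr = fpr[keep], tpr = tpr[keep])
}

#' Entry-level ROC evaluation of a per-state probability matrix
#'
#' Flattens the cell-by-gene prediction and ground-truth matrices and sweeps
#' the score cutoff to obtain TPR/FPR, AUROC and AUPRC. At `scale = "arm"`
#' both matrices are first averaged per (cell, chromosome arm); the arm
#' truth is the majority label.
#'
#' @param prob cell-by-gene probability (or signal) matrix for one CNA
#'   state.
#' @param truth cell-by-gene logical ground-truth matrix (same dims).
#' @param scale `"gene"` (default) or `"arm"`.
#' @param genes gene annotation (required for `scale = "arm"`).
#' @return object of class `benchmark_result`: tibble-backed list with
#'   `auroc`, `auprc`, `curve`, `scale`, `n` (entries evaluated).
#' @export
roc_per_state <- function(prob, truth, scale = c("gene", "arm"), genes = NULL) {
  scale <- match.arg(scale)
  stopifnot(all(dim(prob) == dim(truth)))
  if (scale == "arm") {
    stopifnot(!is.null(genes), nrow(genes) == ncol(prob))
    arm_key <- paste0(genes$chrom, genes$arm)
    arms <- unique(arm_key)
    agg <- function(M) {
      vapply(arms, function(a) rowMeans(M[, arm_key == a, drop = FALSE]),
             numeric(nrow(M)))
    }
    prob <- agg(prob)
    truth <- agg(truth) > 0.5
  }
  s <- as.vector(prob); t <- as.vector(truth)
  structure(list(auroc = auroc(s, t), auprc = auprc(s, t),
                 curve = roc_curve_points(s, t), scale = scale,
                 n = length(s)),
            class = "benchmark_result")
}

#' @method print benchmark_result
#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s scale, n=%d: AUROC %.4f, AUPRC %.4f\n",
              x$scale, x$n, x$auroc, x$auprc))
  invisible(x)
}

#' Subclone reconstruction by K-means on CNA posteriors
#'
#' Flattens the detailed (haplotype-resolved) per-gene state probabilities
#' into a cell-by-feature matrix and clusters cells with K-means (10
#' restarts). When true labels are supplied, the adjusted Rand index is
#' reported.
#'
#' @param combined `cna_calls` from [combine_modules()] (its `detailed`
#'   tensor is used so haplotype-specific losses can separate subclones), or
#'   any `state_tensor`.
#' @param k number of clusters.
#' @param true_labels optional vector of reference labels per cell.
#' @param seed RNG seed for the restarts (default 1).
#' @return list with `labels` (integer cluster per cell) and `ari` (`NA`
#'   without true labels).
#' @export
kmeans_subclones <- function(combined, k, true_labels = NULL, seed = 1L) {
  tensor <- if (inherits(combined, "cna_calls")) combined$detailed else combined
  n_c <- dim(tensor)[1]
  if (k > n_c) stop("k exceeds the number of cells")
  X <- matrix(as.vector(tensor), nrow = n_c)
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = 10L)
  ari <- if (is.null(true_labels)) NA_real_ else
    mclust::adjustedRandIndex(km$cluster, true_labels)
  list(labels = km$cluster, ari = ari)
}
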