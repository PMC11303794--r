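#' Weighted-moving-average (horizontal) smoothing operator
#'
#' Builds the feature-by-feature WMA matrix over ordinal gene distance. The
#' raw weight from gene `j` to query gene `g` is `t - |d|` for ordinal
#' distance `0 < |d| < t`, `2t` for `d = 0`, and 0 for `|d| >= t` or when
#' the genes lie on different chromosome arms; columns are normalised to
#' sum to 1. With `t = 1` the operator is the identity.
#'
#' @param annotation feature annotation with columns `chrom`, `arm`,
#'   `order` (features sorted by `order`).
#' @param t window size in features (default 40; use 101 for bin-scale BAF).
#' @return sparse column-stochastic feature-by-feature matrix `W`.
#' @export
wma_matrix <- function(annotation, t = 40L) {
  stopifnot(t >= 1L)
  n <- nrow(annotation)
  ord <- order(annotation$order)
  stopifnot(identical(ord, seq_len(n)))
  arm_key <- paste(annotation$chrom, annotation$arm)
  runs <- rle(arm_key)
  starts <- cumsum(c(1L, head(runs$lengths, -1L)))
  ii <- jj <- ww <- vector("list", length(runs$lengths))
  for (r in seq_along(runs$lengths)) {
    m <- runs$lengths[r]
    off <- starts[r] - 1L
    d_max <- min(t - 1L, m - 1L)
    js <- gs <- ws <- integer(0)
    for (d in 0:d_max) {
      idx <- seq_len(m - d)
      if (d == 0L) {
        js <- c(js, idx); gs <- c(gs, idx); ws <- c(ws, rep(2L * t, m))
      } else {
        js <- c(js, idx, idx + d)
        gs <- c(gs, idx + d, idx)
        ws <- c(ws, rep(t - d, 2L * length(idx)))
      }
    }
    ii[[r]] <- js + off; jj[[r]] <- gs + off; ww[[r]] <- ws
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n, n))
  colsum <- Matrix::colSums(W)
  W %*% Matrix::Diagonal(n, 1 / colsum)
}

#' KNN (vertical) smoothing operator across cells
#'
#' Standard scRNA-seq neighbour graph: counts are library-size normalised to
#' `target_sum`, log1p-transformed, reduced to the top principal components,
#' and each cell is connected to its `k` nearest neighbours by Euclidean
#' distance. A self-connection at the row's maximum neighbour weight is
#' added, and rows are normalised to sum to 1.
#'
#' @param RD cell-by-gene count matrix.
#' @param k neighbours per cell (default 10); must be `< n_cells`.
#' @param n_pcs number of principal components (default 50, capped at
#'   `n_cells - 1` and the gene count).
#' @param target_sum library-size normalisation target (default 1e4).
#' @return row-stochastic cell-by-cell sparse matrix `M`.
#' @export
knn_matrix <- function(RD, k = 10L, n_pcs = 50L, target_sum = 1e4) {
  RD <- as.matrix(RD)
  n <- nrow(RD)
  if (k >= n) stop("k must be smaller than the number of cells")
  tot <- rowSums(RD)
  tot[tot == 0] <- 1
  X <- log1p(RD / tot * target_sum)
  n_pcs <- min(n_pcs, n - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  D <- as.matrix(dist(pc))
  diag(D) <- Inf
  idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx), x = 1,
                            dims = c(n, n))
  A <- A + Matrix::Diagonal(n, 1)    # self weight = row max neighbour weight (=1)
  rs <- Matrix::rowSums(A)
  Matrix::Diagonal(n, 1 / rs) %*% A
}

#' Apply horizontal and vertical smoothing
#'
#' Computes `M %*% X %*% W`: vertical (across cells) smoothing by the
#' row-stochastic KNN matrix `M`, horizontal (along the genome) smoothing by
#' the column-stochastic WMA matrix `W`. Either operator may be `NULL` to
#' skip that direction.
#'
#' @param X cell-by-feature numeric matrix.
#' @param M cell-by-cell row-stochastic matrix or `NULL`.
#' @param W feature-by-feature column-stochastic matrix or `NULL`.
#' @return smoothed dense matrix of the same dimensions.
#' @export
smooth_matrix <- function(X, M = NULL, W = NULL) {
  X <- as.matrix(X)
  if (!is.null(M)) {
    stopifnot(ncol(M) == nrow(X))
    X <- as.matrix(M %*% X)
  }
  if (!is.null(W)) {
    stopifnot(nrow(W) == ncol(X))
    X <- as.matrix(X %*% W)
  }
  X
}

#' Raw read-depth-ratio (log scale)
#'
#' Normalises each cell's counts by its library size factor, divides by the
#' reference (diploid) cell expression profile, and returns the natural-log
#' ratio. Zero normalised counts are replaced by `zero_fill` before taking
#' the ratio so the log is finite; non-zero entries are untouched.
#'
#' @param dataset a [cna_dataset()] with reference cells designated.
#' @param gene_mask optional logical/character selector of retained genes
#'   (e.g. from [filter_genes()]).
#' @param zero_fill value substituted for zero normalised counts
#'   (default 0.1).
#' @return list with `log_ratio` (cell-by-gene), `l` (library factors),
#'   `X_ref` (reference profile), `genes` (annotation of retained genes).
#' @export
raw_rdr <- function(dataset, gene_mask = NULL, zero_fill = 0.1) {
  if (!any(dataset$cells$is_reference)) stop("no reference cells designated")
  genes <- dataset$genes
  RD <- dataset$RD
  if (!is.null(gene_mask)) {
    RD <- RD[, gene_mask, drop = FALSE]
    genes <- genes[gene_mask, , drop = FALSE]
  }
  l <- estimate_library_factors(RD, dataset$cells)
  Xn <- RD / l
  X_ref <- colMeans(Xn[dataset$cells$is_reference, , drop = FALSE])
  if (any(X_ref <= 0)) stop("reference mean is zero for some retained genes; filter first")
  Xn[Xn == 0] <- zero_fill
  list(log_ratio = log(sweep(Xn, 2, X_ref, `/`)), l = l, X_ref = X_ref,
       genes = genes)
}
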