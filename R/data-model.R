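#' @importFrom rlang .data
#' @import Matrix
#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
#' @importFrom stats dnbinom dbinom optimize prcomp quantile rbinom rbeta
#'   rnbinom rlnorm kmeans sd setNames dist
NULL

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Normalise chromosome names to 1..22, X, Y
#'
#' Strips a leading "chr" prefix and returns a factor ordered by the natural
#' genome order. Unplaced or non-standard contigs become `NA`.
#'
#' @param chrom character vector of chromosome names.
#' @return factor with levels `1..22, X, Y`.
#' @keywords internal
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  factor(x, levels = CHROM_LEVELS)
}

#' Build a validated gene annotation table
#'
#' Genes are sorted into genome order (chromosomes 1..22, X, Y by natural
#' order, then start position), assigned to a chromosome arm, and given a
#' genome-wide rank. Coordinates are 1-based inclusive. Genes on
#' mitochondrial or unplaced contigs are dropped with a message.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `arm`.
#' @param centromeres optional data frame with columns `chrom`,
#'   `centromere` (bp); used to derive `arm` when absent. Genes starting at
#'   or before the centromere position are on the p arm.
#' @return tibble with columns `gene_id`, `chrom`, `arm`, `start`, `end`,
#'   `order` (0-based genome-wide rank), sorted by genome order.
#' @export
gene_annotation <- function(genes, centromeres = NULL) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) == 0L) stop("empty gene annotation")
  genes$chrom <- normalize_chrom(genes$chrom)
  n_drop <- sum(is.na(genes$chrom))
  if (n_drop > 0L) {
    message("dropping ", n_drop, " gene(s) on non-standard contigs")
    genes <- genes[!is.na(genes$chrom), , drop = FALSE]
  }
  if (nrow(genes) == 0L) stop("no genes left after contig filtering")
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (!"arm" %in% names(genes)) {
    if (is.null(centromeres)) stop("need either an 'arm' column or a centromere table")
    cen <- tibble::as_tibble(centromeres)
    cen$chrom <- normalize_chrom(cen$chrom)
    idx <- match(genes$chrom, cen$chrom)
    if (anyNA(idx)) stop("centromere table missing chromosomes")
    genes$arm <- ifelse(genes$start <= cen$centromere[idx], "p", "q")
  }
  if (!all(genes$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  genes <- dplyr::arrange(genes, .data$chrom, .data$start)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  genes$order <- seq_len(nrow(genes)) - 1L
  dplyr::select(genes, "gene_id", "chrom", "arm", "start", "end", "order")
}

#' Build a validated cell annotation table
#'
#' @param cells data frame with columns `barcode`, `cell_type`,
#'   `is_reference` (logical; the designated diploid reference group).
#' @return tibble.
#' @export
cell_meta <- function(cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("barcode", "cell_type", "is_reference") %in% names(cells)))
  if (anyDuplicated(cells$barcode)) stop("duplicate cell barcodes")
  cells$is_reference <- as.logical(cells$is_reference)
  cells
}

#' Assemble a single-cell CNA dataset
#'
#' Bundles the expression matrix and (optionally) the phased allelic count
#' matrices with their gene and cell annotations. Matrices are cell-by-gene;
#' columns are re-ordered to genome order. Genes present in the matrices but
#' absent from the annotation are dropped with a message.
#'
#' @param RD cell-by-gene integer matrix of UMI/read counts (dimnames
#'   optional; columns matched to `genes$gene_id` by name when present,
#'   otherwise by position).
#' @param genes gene annotation as from [gene_annotation()].
#' @param cells cell annotation as from [cell_meta()].
#' @param AD,DP optional cell-by-gene matrices of phased B-allele and total
#'   allelic UMI counts (`0 <= AD <= DP` elementwise).
#' @return object of class `cna_dataset`: a list with elements `RD`, `AD`,
#'   `DP`, `genes`, `cells`.
#' @export
cna_dataset <- function(RD, genes, cells, AD = NULL, DP = NULL) {
  RD <- as.matrix(RD)
  genes <- if (inherits(genes, "tbl_df") && "order" %in% names(genes)) genes else gene_annotation(genes)
  cells <- cell_meta(cells)
  if (nrow(RD) != nrow(cells)) {
    stop(sprintf("matrix has %d cells but annotation has %d", nrow(RD), nrow(cells)))
  }
  align_genes <- function(M, what) {
    if (!is.null(colnames(M))) {
      keep <- intersect(genes$gene_id, colnames(M))
      n_drop <- ncol(M) - length(keep)
      if (n_drop > 0L) message("dropping ", n_drop, " ", what, " column(s) without annotation")
      if (length(keep) < nrow(genes)) {
        stop(sprintf("%s matrix has %d annotated genes but annotation has %d",
                     what, length(keep), nrow(genes)))
      }
      M[, genes$gene_id, drop = FALSE]
    } else {
      if (ncol(M) != nrow(genes)) {
        stop(sprintf("%s matrix has %d genes but annotation has %d",
                     what, ncol(M), nrow(genes)))
      }
      colnames(M) <- genes$gene_id
      M
    }
  }
  RD <- align_genes(RD, "RD")
  rownames(RD) <- cells$barcode
  if (any(RD < 0)) stop("negative expression counts")
  if (xor(is.null(AD), is.null(DP))) stop("AD and DP must be supplied together")
  if (!is.null(AD)) {
    AD <- align_genes(as.matrix(AD), "AD")
    DP <- align_genes(as.matrix(DP), "DP")
    if (!all(dim(AD) == dim(DP))) stop("AD and DP dimensions differ")
    if (nrow(AD) != nrow(cells)) stop("AD rows do not match cell annotation")
    bad <- which(AD > DP, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("AD > DP at (cell %d, gene %d) [first of %d violations]",
                   bad[1, 1], bad[1, 2], nrow(bad)))
    }
    if (any(AD < 0) || any(DP < 0)) stop("negative allelic counts")
    rownames(AD) <- rownames(DP) <- cells$barcode
  }
  structure(list(RD = RD, AD = AD, DP = DP, genes = genes, cells = cells),
            class = "cna_dataset")
}

#' @method print cna_dataset
#' @export
print.cna_dataset <- function(x, ...) {
  cat(sprintf("<cna_dataset> %d cells x %d genes (%d reference cells)%s\n",
              nrow(x$RD), ncol(x$RD), sum(x$cells$is_reference),
              if (is.null(x$AD)) ", expression only" else ", with AD/DP"))
  invisible(x)
}

#' @export
dim.cna_dataset <- function(x) dim(x$RD)

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Load a dataset from matrix-market files
#'
#' Reads `RD.mtx` (and `AD.mtx`/`DP.mtx` when present), `genes.tsv` and
#' `barcodes.tsv` from a directory, together with external gene and cell
#' annotation tables, and returns an aligned [cna_dataset()]. Matrices on
#' disk are gene-by-cell (the 10x convention) and are transposed on load.
#'
#' @param matrix_dir directory holding the `.mtx` and `.tsv` files.
#' @param gene_annotation_file TSV with columns `gene_id`, `chrom`, `start`,
#'   `end` and either `arm` or nothing (then `centromere_file` is required).
#' @param cell_annotation_file TSV with columns `barcode`, `cell_type`,
#'   `is_reference`.
#' @param centromere_file optional TSV with columns `chrom`, `centromere`.
#' @return [cna_dataset()] object.
#' @export
load_dataset <- function(matrix_dir, gene_annotation_file, cell_annotation_file,
                         centromere_file = NULL) {
  gene_ids <- read_tsv_quiet(file.path(matrix_dir, "genes.tsv"),
                             col_names = "gene_id")$gene_id
  barcodes <- read_tsv_quiet(file.path(matrix_dir, "barcodes.tsv"),
                             col_names = "barcode")$barcode
  read_mat <- function(name) {
    p <- file.path(matrix_dir, paste0(name, ".mtx"))
    if (!file.exists(p)) return(NULL)
    M <- as.matrix(Matrix::readMM(p))
    if (nrow(M) != length(gene_ids) || ncol(M) != length(barcodes)) {
      stop(sprintf("%s.mtx is %dx%d but genes.tsv has %d rows and barcodes.tsv %d",
                   name, nrow(M), ncol(M), length(gene_ids), length(barcodes)))
    }
    dimnames(M) <- list(gene_ids, barcodes)
    t(M)
  }
  anno <- read_tsv_quiet(gene_annotation_file)
  cen <- if (!is.null(centromere_file)) read_tsv_quiet(centromere_file) else NULL
  genes <- gene_annotation(anno, centromeres = cen)
  missing_anno <- setdiff(gene_ids, genes$gene_id)
  if (length(missing_anno) > 0L) {
    message("dropping ", length(missing_anno), " feature(s) without annotation")
  }
  genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  genes$order <- seq_len(nrow(genes)) - 1L
  cells <- cell_meta(read_tsv_quiet(cell_annotation_file))
  if (!identical(sort(cells$barcode), sort(barcodes))) {
    stop("cell annotation barcodes do not match barcodes.tsv")
  }
  cells <- cells[match(barcodes, cells$barcode), , drop = FALSE]
  cna_dataset(RD = read_mat("RD"), AD = read_mat("AD"), DP = read_mat("DP"),
              genes = genes, cells = cells)
}

#' Write a dataset as matrix-market files
#'
#' Inverse of [load_dataset()]: writes `RD.mtx` (+ `AD.mtx`, `DP.mtx` when
#' present, gene-by-cell orientation), `genes.tsv`, `barcodes.tsv`,
#' `gene_annotation.tsv` and `cell_annotation.tsv` into `dir`.
#'
#' @param dataset a [cna_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(M, name) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(t(M)), "generalMatrix"),
                                "CsparseMatrix"),
                    file.path(dir, paste0(name, ".mtx")))
  }
  wm(dataset$RD, "RD")
  if (!is.null(dataset$AD)) {
    wm(dataset$AD, "AD")
    wm(dataset$DP, "DP")
  }
  readr::write_tsv(tibble::tibble(x = dataset$genes$gene_id),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = dataset$cells$barcode),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(dataset$genes, file.path(dir, "gene_annotation.tsv"))
  readr::write_tsv(dataset$cells, file.path(dir, "cell_annotation.tsv"))
  invisible(dir)
}

#' Group consecutive genes into fixed-size bins per chromosome arm
#'
#' Bins contain consecutive genes from a single chromosome arm (never
#' spanning the centromere); per arm the genes are split into
#' `ceiling(n/bin_size)` bins and the final bin of an arm may be smaller.
#' Remainder genes at an arm end form their own bin rather than joining the
#' previous one.
#'
#' @param genes gene annotation as from [gene_annotation()].
#' @param bin_size genes per bin (default 100).
#' @return tibble (`bin_map`) with one row per gene: `gene_id`, `chrom`,
#'   `arm`, `bin_id` (1-based, genome order).
#' @export
make_bins <- function(genes, bin_size = 100L) {
  if (nrow(genes) == 0L) stop("empty annotation")
  stopifnot(bin_size >= 2L)
  genes <- dplyr::arrange(genes, .data$order)
  arm_key <- paste(genes$chrom, genes$arm, sep = "")
  arm_rle <- rle(arm_key)
  within_arm <- unlist(lapply(arm_rle$lengths, seq_len), use.names = FALSE)
  local_bin <- (within_arm - 1L) %/% bin_size
  # make bin ids unique across arms, in genome order
  arm_idx <- rep(seq_along(arm_rle$lengths), arm_rle$lengths)
  key <- paste(arm_idx, local_bin)
  bin_id <- cumsum(!duplicated(key))[match(key, key)]
  out <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                        arm = genes$arm, bin_id = as.integer(bin_id))
  class(out) <- c("bin_map", class(out))
  out
}

#' Per-bin summary of a bin map
#' @param binmap output of [make_bins()].
#' @return tibble with one row per bin: `bin_id`, `chrom`, `arm`, `n_genes`.
#' @export
bin_info <- function(binmap) {
  dplyr::summarise(dplyr::group_by(binmap, .data$bin_id),
                   chrom = dplyr::first(.data$chrom),
                   arm = dplyr::first(.data$arm),
                   n_genes = dplyr::n(), .groups = "drop")
}

#' Construct a cell-by-feature-by-state probability tensor
#'
#' @param P numeric array, cells x features x states; each (cell, feature)
#'   row must sum to 1.
#' @param states character vector of state labels (length 3, 4 or 5).
#' @param scale `"gene"` or `"gene_bin"`.
#' @return the array with class `state_tensor` and attributes `states`,
#'   `scale`.
#' @export
state_tensor <- function(P, states, scale = c("gene", "gene_bin")) {
  scale <- match.arg(scale)
  stopifnot(length(dim(P)) == 3L, dim(P)[3] == length(states))
  sums <- apply(P, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("state probabilities must sum to 1")
  if (any(P < -1e-12)) stop("negative state probabilities")
  dimnames(P)[[3]] <- states
  structure(P, class = "state_tensor", states = states, scale = scale)
}

tensor_states <- function(P) attr(P, "states")

#' Map a bin-scale probability tensor back to gene scale
#'
#' Every gene receives the probability row of its bin unchanged. Genes
#' present in `genes` but absent from the bin map (e.g. filtered before
#' phasing) receive a one-hot row at `neutral_state` and are reported in the
#' `filled_genes` attribute.
#'
#' @param tensor `state_tensor` at `gene_bin` scale (features ordered by
#'   `bin_id`).
#' @param binmap [make_bins()] output restricted to the genes that entered
#'   the bins.
#' @param genes gene annotation giving the target gene order.
#' @param neutral_state label of the balanced/neutral state used for fill.
#' @return `state_tensor` at gene scale (cells x genes x K).
#' @export
bins_to_genes <- function(tensor, binmap, genes, neutral_state) {
  stopifnot(attr(tensor, "scale") == "gene_bin")
  states <- tensor_states(tensor)
  stopifnot(neutral_state %in% states)
  bins <- sort(unique(binmap$bin_id))
  stopifnot(dim(tensor)[2] == length(bins))
  idx <- match(binmap$bin_id[match(genes$gene_id, binmap$gene_id)], bins)
  n_cells <- dim(tensor)[1]
  out <- array(0, dim = c(n_cells, nrow(genes), length(states)))
  known <- !is.na(idx)
  out[, known, ] <- tensor[, idx[known], , drop = FALSE]
  if (any(!known)) out[, !known, states == neutral_state] <- 1
  res <- state_tensor(out, states, scale = "gene")
  attr(res, "filled_genes") <- genes$gene_id[!known]
  res
}
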