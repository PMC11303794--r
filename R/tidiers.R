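#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy per-gene parameters of an expression-module fit
#' @param x `rdr_fit`.
#' @param ... unused.
#' @return tibble with `gene_id`, `chrom`, `arm`, `X_ref`, `phi`,
#'   `phi_flagged`.
#' @export
tidy.rdr_fit <- function(x, ...) {
  tibble::tibble(gene_id = x$genes$gene_id,
                 chrom = as.character(x$genes$chrom), arm = x$genes$arm,
                 X_ref = unname(x$X_ref), phi = x$dispersion$phi,
                 phi_flagged = x$dispersion$flagged)
}

#' @export
glance.rdr_fit <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$emission), n_genes = ncol(x$emission),
                 C_loss = unname(x$C[1]), C_neutral = unname(x$C[2]),
                 C_gain = unname(x$C[3]), platform = x$platform)
}

#' Tidy per-bin allelic-state frequencies of a BAF fit
#' @param x `baf_fit`.
#' @param ... unused.
#' @return tibble with `bin_id`, `chrom`, `arm`, `n_genes` and one `rho_*`
#'   column per allelic state.
#' @export
tidy.baf_fit <- function(x, ...) {
  rho <- tibble::as_tibble(x$params$rho)
  names(rho) <- paste0("rho_", names(rho))
  dplyr::bind_cols(x$phased$bins, rho)
}

#' @export
glance.baf_fit <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$emission), n_bins = ncol(x$emission),
                 n_states = length(x$params$states),
                 tau = mean(x$params$tau),
                 theoretical_rho = x$params$theoretical)
}

#' Tidy CNA calls into a long table
#' @param x `cna_calls`.
#' @param ... unused.
#' @return tibble with `barcode` (row index when unnamed), `gene_id`
#'   (column index when unnamed), `call`, `allele_detail`, `wgd_flag`.
#' @export
tidy.cna_calls <- function(x, ...) {
  n_c <- nrow(x$calls); n_g <- ncol(x$calls)
  bc <- rownames(x$calls) %||% as.character(seq_len(n_c))
  gid <- colnames(x$calls) %||% as.character(seq_len(n_g))
  tibble::tibble(barcode = rep(bc, times = n_g),
                 gene_id = rep(gid, each = n_c),
                 call = as.vector(x$calls),
                 allele_detail = as.vector(x$allele_detail),
                 wgd_flag = as.vector(x$wgd_flags))
}

#' @export
glance.cna_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = FINAL_STATES))
  tibble::tibble(n_cells = nrow(x$calls), n_genes = ncol(x$calls),
                 frac_loss = unname(tab[["loss"]]) / length(x$calls),
                 frac_neutral = unname(tab[["neutral"]]) / length(x$calls),
                 frac_gain = unname(tab[["gain"]]) / length(x$calls),
                 frac_loh = unname(tab[["LOH"]]) / length(x$calls),
                 frac_wgd_flag = mean(x$wgd_flags))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Heatmap of hard CNA calls
#'
#' Cells (rows) ordered by annotation group, genes (columns) by genome
#' order, coloured by the called state.
#'
#' @param object `cna_calls`.
#' @param cells optional cell annotation used to order rows by `cell_type`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cna_calls <- function(object, cells = NULL, ...) {
  n_c <- nrow(object$calls)
  ord <- if (!is.null(cells)) order(cells$cell_type) else seq_len(n_c)
  df <- tibble::tibble(
    cell = rep(match(seq_len(n_c), ord), times = ncol(object$calls)),
    gene = rep(seq_len(ncol(object$calls)), each = n_c),
    call = factor(as.vector(object$calls), levels = FINAL_STATES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$cell,
                                   fill = .data$call)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(loss = "#2166AC", neutral = "grey92",
                                          gain = "#B2182B", LOH = "#66BD63"),
                               drop = FALSE) +
    ggplot2::labs(x = "genes (genome order)", y = "cells", fill = "CNA state") +
    ggplot2::theme_minimal()
}

#' Smoothed log read-depth-ratio heatmap
#'
#' @param object `rdr_fit`.
#' @param cells optional cell annotation used to order rows.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rdr_fit <- function(object, cells = NULL, ...) {
  X <- object$log_ratio_smooth
  ord <- if (!is.null(cells)) order(cells$cell_type) else seq_len(nrow(X))
  df <- tibble::tibble(
    cell = rep(match(seq_len(nrow(X)), ord), times = ncol(X)),
    gene = rep(seq_len(ncol(X)), each = nrow(X)),
    log_ratio = as.vector(X))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$cell,
                                   fill = .data$log_ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1.5, 1.5),
                                  oob = scales_squish) +
    ggplot2::labs(x = "genes (genome order)", y = "cells",
                  fill = "log ratio") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])
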