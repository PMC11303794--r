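#' Run the full CNA inference pipeline
#'
#' Executes load -> filter -> phase -> smooth -> expression module ->
#' allelic module -> HMM -> combine -> denoise on a [cna_dataset()], with
#' optional benchmarking against ground-truth masks.
#'
#' @param dataset a [cna_dataset()] (with AD/DP unless `modules = "rdr"`).
#' @param platform `"droplet"` or `"smartseq"`.
#' @param modules character subset of `c("rdr", "baf")`; with `"rdr"` only,
#'   no allelic artifacts are produced and the final calls are the
#'   expression-module posteriors.
#' @param ratio_mode CNA-ratio mode for the expression module (default
#'   `"guided"`).
#' @param bin_size genes per bin for phasing (default 100).
#' @param knn_k,wma_t_rdr,wma_t_baf smoothing parameters (defaults 10, 40,
#'   101).
#' @param tau,n_baf_states,min_ref_cells allelic-module parameters.
#' @param trans_t HMM cross-state transition probability (default `1e-6`).
#' @param denoise apply the post-denoise mask to the allelic posterior
#'   (default `TRUE`).
#' @param truth optional list of cell-by-gene logical masks (`loss`,
#'   `gain`, `loh`, ...) for benchmarking.
#' @param outdir optional output directory for TSV artifacts and a run
#'   manifest.
#' @param n_top_markers marker genes removed per annotated group
#'   (default 15).
#' @return list of class `cna_pipeline`: `rdr`, `rdr_posterior`, `baf`,
#'   `baf_posterior`, `combined` (`cna_calls`), `denoise`, `wgd`, `genes`
#'   (retained gene annotation), `benchmark` (tibble or `NULL`), `M`.
#' @export
run_cna_pipeline <- function(dataset, platform = c("droplet", "smartseq"),
                             modules = c("rdr", "baf"),
                             ratio_mode = c("guided", "theoretical"),
                             bin_size = 100L, knn_k = 10L, wma_t_rdr = 40L,
                             wma_t_baf = 101L, tau = 100, n_baf_states = 5L,
                             min_ref_cells = 20L, trans_t = 1e-6,
                             denoise = TRUE, truth = NULL, outdir = NULL,
                             n_top_markers = 15L) {
  platform <- match.arg(platform)
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(all(modules %in% c("rdr", "baf")), "rdr" %in% modules)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  M <- stage("knn", knn_matrix(dataset$RD, k = min(knn_k, nrow(dataset$RD) - 1L)))
  rdr <- stage("rdr_fit",
               rdr_fit(dataset, platform, ratio_mode = ratio_mode,
                       n_top_markers = n_top_markers, wma_t = wma_t_rdr, M = M))
  cfg_rdr <- hmm_config(default_hmm_start("rdr", platform), trans_t)
  rdr_post <- stage("rdr_hmm",
                    infer_states(rdr$emission, M, cfg_rdr,
                                 feature_chrom = rdr$genes$chrom,
                                 neutral_state = "neutral"))
  res <- list(rdr = rdr, rdr_posterior = rdr_post, M = M, genes = rdr$genes,
              baf = NULL, baf_posterior = NULL, combined = NULL,
              denoise = NULL, wgd = NULL, benchmark = NULL)
  if ("baf" %in% modules) {
    if (is.null(dataset$AD)) stop("allelic module requested but dataset has no AD/DP")
    markers <- if (n_top_markers > 0L &&
                   length(unique(dataset$cells$cell_type)) > 1L) {
      rank_marker_genes(dataset$RD, dataset$cells$cell_type, n_top_markers)
    } else character(0)
    genes_baf <- dataset$genes[!dataset$genes$gene_id %in% markers, , drop = FALSE]
    binmap <- make_bins(genes_baf, bin_size = bin_size)
    baf <- stage("baf_fit",
                 baf_fit(dataset, binmap, M = M, tau = tau,
                         n_states = n_baf_states,
                         min_ref_cells = min_ref_cells, wma_t = wma_t_baf))
    cfg_baf <- hmm_config(if (n_baf_states == 5L)
      default_hmm_start("baf") else c(0.25, 0.5, 0.25), trans_t)
    baf_post <- stage("baf_hmm",
                      infer_states(baf$emission, M, cfg_baf,
                                   feature_chrom = baf$phased$bins$chrom,
                                   neutral_state = "balanced"))
    baf_gene <- stage("bins_to_genes",
                      bins_to_genes(baf_post$posterior, binmap, rdr$genes,
                                    neutral_state = "balanced"))
    dn <- if (denoise) {
      stage("denoise", post_denoise(baf_gene, neutral_state = "balanced"))
    } else list(tensor = baf_gene, mask = rep(FALSE, ncol(baf_gene)),
                proportions = NULL)
    combined <- stage("combine",
                      combine_modules(rdr_post$posterior, dn$tensor))
    res$baf <- baf
    res$baf_posterior <- baf_post
    res$denoise <- dn
    res$combined <- combined
    res$wgd <- stage("wgd", suppressWarnings(
      wgd_warning(combined, dataset$cells, rdr$genes)))
  }
  if (!is.null(truth)) {
    res$benchmark <- stage("benchmark",
                           benchmark_pipeline(res, truth, dataset$cells))
  }
  res$cells <- dataset$cells
  class(res) <- "cna_pipeline"
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

# per-state ROC of a pipeline result against simulator truth masks
benchmark_pipeline <- function(res, truth, cells) {
  gene_ids <- res$genes$gene_id
  state_prob <- function(state) {
    if (!is.null(res$combined)) {
      res$combined$P[, , state, drop = TRUE]
    } else if (state == "loss") {
      res$rdr_posterior$posterior[, , "loss", drop = TRUE]
    } else if (state == "gain") {
      res$rdr_posterior$posterior[, , "gain", drop = TRUE]
    } else NULL
  }
  states <- c(loss = "loss", gain = "gain", loh = "LOH")
  rows <- list()
  for (s in names(states)) {
    if (is.null(truth[[s]])) next
    prob <- state_prob(states[[s]])
    if (is.null(prob)) next
    tm <- truth[[s]][, gene_ids, drop = FALSE]
    if (!any(tm) || all(tm)) next
    bench <- roc_per_state(prob, tm)
    rows[[s]] <- tibble::tibble(state = unname(states[[s]]),
                                auroc = bench$auroc, auprc = bench$auprc,
                                n = bench$n)
  }
  dplyr::bind_rows(rows)
}

#' @method print cna_pipeline
#' @export
print.cna_pipeline <- function(x, ...) {
  cat(sprintf("<cna_pipeline> %d cells, %d retained genes; modules: %s\n",
              nrow(x$rdr$emission), nrow(x$genes),
              if (is.null(x$baf)) "rdr" else "rdr+baf"))
  if (!is.null(x$benchmark)) print(x$benchmark)
  invisible(x)
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  calls <- if (!is.null(res$combined)) res$combined$calls else
    res$rdr_posterior$calls
  ct <- tibble::as_tibble(calls, .name_repair = "minimal")
  names(ct) <- res$genes$gene_id
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(barcode = res$cells$barcode), ct),
                   file.path(outdir, "calls.tsv"))
  readr::write_tsv(generics::tidy(res$rdr), file.path(outdir, "rdr_params.tsv"))
  if (!is.null(res$baf)) {
    readr::write_tsv(generics::tidy(res$baf), file.path(outdir, "baf_params.tsv"))
    write_flip_record(res$baf$phased, file.path(outdir, "phasing_flips.tsv"))
  }
  if (!is.null(res$benchmark)) {
    readr::write_tsv(res$benchmark, file.path(outdir, "benchmark.tsv"))
  }
  manifest <- list(
    package = "ascna",
    version = as.character(utils::packageVersion("ascna")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_cells = nrow(res$rdr$emission),
    n_genes = nrow(res$genes),
    C = as.list(res$rdr$C),
    modules = if (is.null(res$baf)) "rdr" else "rdr+baf")
  writeLines(yaml::as.yaml(manifest), file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
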