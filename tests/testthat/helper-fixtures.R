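# lazily built shared fixtures (constructed once per test session)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic gene table: chromosomes of `genes_per_chrom` genes, p/q
# arms split at the midpoint
toy_genes <- function(n_chroms = 2L, genes_per_chrom = 10L) {
  tabs <- lapply(seq_len(n_chroms), function(ch) {
    j <- seq_len(genes_per_chrom)
    tibble::tibble(gene_id = sprintf("c%dg%02d", ch, j),
                   chrom = as.character(ch),
                   start = (j - 1L) * 1000L + 1L, end = (j - 1L) * 1000L + 500L,
                   arm = ifelse(j <= genes_per_chrom / 2, "p", "q"))
  })
  gene_annotation(dplyr::bind_rows(tabs))
}

toy_cells <- function(n_ref = 2L, n_tumor = 1L) {
  n <- n_ref + n_tumor
  cell_meta(tibble::tibble(
    barcode = sprintf("bc%02d", seq_len(n)),
    cell_type = rep(c("reference", "tumor"), c(n_ref, n_tumor)),
    is_reference = rep(c(TRUE, FALSE), c(n_ref, n_tumor))))
}

random_state_tensor <- function(n_c, n_f, K, states = paste0("s", seq_len(K)),
                                scale = "gene") {
  P <- array(stats::runif(n_c * n_f * K), c(n_c, n_f, K))
  tot <- apply(P, c(1, 2), sum)
  for (k in seq_len(K)) P[, , k] <- P[, , k] / tot
  state_tensor(P, states, scale = scale)
}

# the end-to-end subclonal preset run shared by acceptance checks
preset_run <- function() {
  fixture("preset_run", function() {
    ps <- scenario_preset("subclonal_allele_loss", seed = 1L)
    sim <- simulate_cna(ps$profile, ps$config)
    res <- suppressWarnings(run_cna_pipeline(sim$dataset, truth = sim$truth))
    list(sim = sim, res = res)
  })
}
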