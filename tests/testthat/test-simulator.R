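test_that("simulation is deterministic under a fixed seed and counts nest", {
  ps <- scenario_preset("subclonal_allele_loss", seed = 42,
                        n_ref_cells = 20, n_tumor_cells = 20)
  ps$config$genes_per_chrom <- 40L
  s1 <- simulate_cna(ps$profile, ps$config)
  s2 <- simulate_cna(ps$profile, ps$config)
  expect_identical(s1$dataset$RD, s2$dataset$RD)
  expect_identical(s1$dataset$AD, s2$dataset$AD)
  expect_true(all(s1$dataset$AD <= s1$dataset$DP))
  expect_true(all(s1$dataset$DP <= s1$dataset$RD))
})

test_that("a null profile generates balanced, copy-neutral data", {
  prof <- cna_profile(tibble::tibble(clone_id = "tumor", n_cells = 150),
                      tibble::tibble(clone_id = character(), chrom = character(),
                                     arm = character(), state = character()))
  cfg <- sim_config(seed = 9, n_ref_cells = 50, n_chroms = 4,
                    genes_per_chrom = 500)
  sim <- simulate_cna(prof, cfg)
  tumor <- !sim$dataset$cells$is_reference
  AD <- sim$dataset$AD[tumor, ]; DP <- sim$dataset$DP[tumor, ]
  expect_lt(abs(sum(AD) / sum(DP) - 0.5), 0.02)
  # library-normalised expression ratio against the reference profile
  RD <- sim$dataset$RD
  l <- rowSums(RD) / mean(rowSums(RD[!tumor, ]))
  Xn <- RD / l
  ref_prof <- colMeans(Xn[!tumor, ])
  lr <- log(colMeans(Xn[tumor, ]) / ref_prof)
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("haplotype loss regions have the stated allelic and depth moments", {
  prof <- cna_profile(tibble::tibble(clone_id = "tumor", n_cells = 120),
                      tibble::tibble(clone_id = "tumor", chrom = "1",
                                     arm = NA, state = "loss_hapA"))
  cfg <- sim_config(seed = 10, n_ref_cells = 60, n_chroms = 4,
                    genes_per_chrom = 250)
  sim <- simulate_cna(prof, cfg)
  tumor <- !sim$dataset$cells$is_reference
  in_region <- sim$dataset$genes$chrom == "1"
  AD <- sim$dataset$AD[tumor, in_region]; DP <- sim$dataset$DP[tumor, in_region]
  expect_gte(sum(AD) / sum(DP), 0.85)   # B allele retained, attenuated by phase errors
  # expression ratio vs reference cells near 0.5
  RD <- sim$dataset$RD
  l <- rowSums(RD[, !in_region]) / mean(rowSums(RD[!tumor, !in_region]))
  ratio <- mean(colMeans(RD[tumor, in_region] / l[tumor]) /
                  colMeans(RD[!tumor, in_region] / l[!tumor]))
  expect_lt(abs(ratio - 0.5), 0.1)
})

test_that("phasing restores bin-level imbalance attenuated by phase errors", {
  prof <- cna_profile(tibble::tibble(clone_id = "tumor", n_cells = 150),
                      tibble::tibble(clone_id = "tumor", chrom = "1",
                                     arm = NA, state = "cnloh_B"))
  base <- list(seed = 11, n_ref_cells = 30, n_chroms = 2, genes_per_chrom = 200)
  cfg_err <- do.call(sim_config, c(base, phase_error_rate = 0.2))
  cfg_clean <- do.call(sim_config, c(base, phase_error_rate = 0))
  sim_e <- simulate_cna(prof, cfg_err)
  sim_c <- simulate_cna(prof, cfg_clean)
  tumor <- !sim_e$dataset$cells$is_reference
  in_region <- sim_e$dataset$genes$chrom == "1"
  gene_baf <- function(sim) {
    sum(sim$dataset$AD[tumor, in_region]) / sum(sim$dataset$DP[tumor, in_region])
  }
  # raw gene-level BAF is attenuated toward 0.5 by phasing errors
  expect_lt(gene_baf(sim_e), gene_baf(sim_c) - 0.1)
  bin_imbalance <- function(sim) {
    ph <- phase_dataset(sim$dataset, make_bins(sim$dataset$genes, 100))
    baf <- ph$AD / pmax(ph$DP, 1)
    bins1 <- ph$bins$chrom == "1"
    mean(abs(colMeans(baf[tumor, bins1, drop = FALSE]) - 0.5))
  }
  expect_lt(abs(bin_imbalance(sim_e) - bin_imbalance(sim_c)), 0.05)
})

test_that("scenario presets set the stated population sizes", {
  p1 <- scenario_preset("subclonal_allele_loss", seed = 1)
  expect_equal(p1$profile$clones$n_cells, c(125, 125))
  expect_equal(p1$config$n_chroms * p1$config$genes_per_chrom, 3000L)
  # the subclones differ exactly on the haplotype-specific chromosome-3 masks
  p1$config$genes_per_chrom <- 50L
  sim <- simulate_cna(p1$profile, p1$config)
  c1 <- sim$clone == "clone1"; c2 <- sim$clone == "clone2"
  chr3 <- sim$dataset$genes$chrom == "3"
  expect_true(all(sim$truth$loss_hapA[c1, chr3]))
  expect_true(all(sim$truth$loss_hapB[c2, chr3]))
  expect_false(any(sim$truth$loss_hapA[c2, chr3]))
  expect_equal(sim$truth$loss[c1, !chr3], sim$truth$loss[c2, !chr3][seq_len(sum(c1)), ],
               ignore_attr = TRUE)

  p2 <- scenario_preset("ref_downsample", variant = 5, seed = 1)
  expect_equal(p2$config$n_ref_cells, 5L)
  p3 <- scenario_preset("tumor_downsample", variant = 22, seed = 1)
  expect_equal(sum(p3$profile$clones$n_cells), 22L)
  expect_error(scenario_preset("ref_downsample", variant = 7), "10 or 5")
})

test_that("overlapping events within a clone are rejected", {
  clones <- tibble::tibble(clone_id = "t", n_cells = 5)
  events <- tibble::tibble(clone_id = "t", chrom = c("1", "1"),
                           arm = c(NA, "p"),
                           state = c("loss_hapA", "gain_hapB"))
  expect_error(cna_profile(clones, events), "overlap")
})
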