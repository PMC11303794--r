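one_hot_tensor <- function(states, hot, n_c = 1, n_g = 1, scale = "gene") {
  P <- array(0, c(n_c, n_g, length(states)))
  P[, , which(states == hot)] <- 1
  state_tensor(P, states, scale = scale)
}

RDR3 <- c("loss", "neutral", "gain")

test_that("one-hot inputs follow the combination rule table", {
  b5 <- ascna:::BAF_STATES_5
  cases <- list(
    list(rdr = "neutral", baf = "balanced", final = "neutral", detail = "none",  wgd = FALSE),
    list(rdr = "neutral", baf = "B_strong", final = "LOH",     detail = "LOH-A", wgd = FALSE),
    list(rdr = "neutral", baf = "A_minor",  final = "LOH",     detail = "LOH-B", wgd = FALSE),
    list(rdr = "loss",    baf = "A_strong", final = "loss",    detail = "loss-B", wgd = FALSE),
    list(rdr = "loss",    baf = "B_minor",  final = "loss",    detail = "loss-A", wgd = FALSE),
    list(rdr = "loss",    baf = "balanced", final = "loss",    detail = "none",  wgd = TRUE),
    list(rdr = "gain",    baf = "B_strong", final = "gain",    detail = "none",  wgd = FALSE))
  for (cs in cases) {
    cmb <- combine_modules(one_hot_tensor(RDR3, cs$rdr),
                           one_hot_tensor(b5, cs$baf))
    expect_equal(unname(cmb$calls[1, 1]), cs$final, info = paste(cs$rdr, cs$baf))
    expect_equal(unname(cmb$allele_detail[1, 1]), cs$detail,
                 info = paste(cs$rdr, cs$baf))
    expect_equal(unname(cmb$wgd_flags[1, 1]), cs$wgd, info = paste(cs$rdr, cs$baf))
    expect_equal(max(abs(apply(cmb$P, c(1, 2), sum) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("uniform inputs produce a normalised distribution", {
  b5 <- ascna:::BAF_STATES_5
  rdr <- state_tensor(array(1/3, c(2, 3, 3)), RDR3)
  baf <- state_tensor(array(0.2, c(2, 3, 5)), b5)
  cmb <- combine_modules(rdr, baf)
  expect_true(max(abs(apply(cmb$P, c(1, 2), sum) - 1)) < 1e-12)
  expect_true(max(abs(apply(cmb$detailed, c(1, 2), sum) - 1)) < 1e-12)
})

test_that("with uniform allelic input the expression marginal is recovered", {
  set.seed(22)
  b5 <- ascna:::BAF_STATES_5
  rdr <- random_state_tensor(3, 4, 3, RDR3)
  baf <- state_tensor(array(0.2, c(3, 4, 5)), b5)
  cmb <- combine_modules(rdr, baf)
  expect_equal(cmb$P[, , "loss"], unclass(rdr)[, , 1], tolerance = 1e-12)
  expect_equal(cmb$P[, , "gain"], unclass(rdr)[, , 3], tolerance = 1e-12)
  expect_equal(cmb$P[, , "neutral"] + cmb$P[, , "LOH"], unclass(rdr)[, , 2],
               tolerance = 1e-12)
})

test_that("LOH and loss are mutually exclusive by construction", {
  set.seed(23)
  b5 <- ascna:::BAF_STATES_5
  rdr <- random_state_tensor(10, 10, 3, RDR3)
  baf <- random_state_tensor(10, 10, 5, b5)
  cmb <- combine_modules(rdr, baf)
  loh <- cmb$calls == "LOH"
  loss_dominant <- rdr[, , 1] > rdr[, , 2]
  expect_false(any(loh & loss_dominant))
})

test_that("post-denoise masks the low-aneuploid component with high fidelity", {
  set.seed(24)
  n_c <- 100; n_g <- 200
  aneu_gene <- c(rep(FALSE, 180), rep(TRUE, 20))
  P <- array(0, c(n_c, n_g, 3))
  for (g in seq_len(n_g)) {
    p_alt <- if (aneu_gene[g]) 0.6 else 0.02
    alt <- runif(n_c) < p_alt
    P[, g, 2] <- ifelse(alt, 0.1, 0.9)
    P[, g, 1] <- ifelse(alt, 0.8, 0.05)
    P[, g, 3] <- 1 - P[, g, 1] - P[, g, 2]
  }
  tens <- state_tensor(P, c("alt_a", "balanced", "alt_b"))
  dn <- post_denoise(tens, "balanced")
  recall <- sum(dn$mask & !aneu_gene) / sum(!aneu_gene)
  precision <- sum(dn$mask & !aneu_gene) / sum(dn$mask)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # masked genes are forced to the balanced one-hot
  expect_equal(unname(dn$tensor[1, which(dn$mask)[1], ]), c(0, 1, 0))
})

test_that("denoise is a no-op for all-neutral calls and honours manual thresholds", {
  P <- array(0, c(10, 5, 3)); P[, , 2] <- 1
  tens <- state_tensor(P, c("a", "balanced", "b"))
  expect_warning(dn <- post_denoise(tens, "balanced"), "constant")
  expect_false(any(dn$mask))

  set.seed(25)
  tens2 <- random_state_tensor(50, 8, 3, c("a", "balanced", "b"))
  dn2 <- post_denoise(tens2, "balanced", threshold = 0.5)
  expect_equal(dn2$mask, dn2$proportions < 0.5)
})

test_that("WGD warning needs widespread flags within a cluster", {
  genes <- toy_genes(1, 20)
  cells <- toy_cells(5, 5)
  fake <- list(wgd_flags = matrix(FALSE, 10, 20))
  out <- wgd_warning(fake, cells, genes)
  expect_false(out$warning)
  # scattered flags below both thresholds stay silent
  fake$wgd_flags[1, 1:20] <- TRUE   # one cell only: cell_frac below 0.5
  out2 <- wgd_warning(fake, cells, genes)
  expect_false(out2$warning)
  # a whole-cluster block of flags trips the warning and names the region
  fake$wgd_flags[6:10, 1:10] <- TRUE
  expect_warning(out3 <- wgd_warning(fake, cells, genes), "duplication")
  expect_true(out3$warning)
  expect_true(all(out3$report$arm == "p"))
})
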