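test_that("two-gene bin is phased to a common allele frequency", {
  AD <- matrix(c(9, 1), 1, 2)
  DP <- matrix(10, 1, 2)
  fit <- local_phase_bin(AD, DP)
  # (0,1) or (1,0) are inversion-equivalent solutions
  expect_true(identical(fit$flips, c(FALSE, TRUE)) ||
                identical(fit$flips, c(TRUE, FALSE)))
  freq <- fit$AD_phased / DP
  expect_true(all(freq == 0.9) || all(freq == 0.1))
})

test_that("a perfectly balanced bin returns all-false flips", {
  AD <- matrix(5, 4, 3)
  DP <- matrix(10, 4, 3)
  fit <- local_phase_bin(AD, DP)
  expect_equal(fit$flips, rep(FALSE, 3))
})

test_that("EM marginal log-likelihood never decreases", {
  set.seed(99)
  for (r in 1:5) {
    C <- 40; G <- 12
    DP <- matrix(rpois(C * G, 3), C, G)
    AD <- matrix(rbinom(C * G, as.vector(DP), runif(1, 0.2, 0.8)), C, G)
    fit <- local_phase_bin(AD, DP)
    expect_true(all(diff(fit$loglik) >= -1e-8))
  }
})

test_that("all-zero depth bins fall back to identity flips with a warning", {
  expect_warning(fit <- local_phase_bin(matrix(0, 2, 3), matrix(0, 2, 3)),
                 "zero allelic depth")
  expect_equal(fit$flips, rep(FALSE, 3))
})

test_that("global phasing aligns mirrored bins and leaves identical bins alone", {
  baf <- rbind(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2))
  fit <- global_phase_arm(baf)
  expect_equal(fit$flips, c(FALSE, TRUE))

  baf2 <- matrix(0.7, 5, 4)
  expect_equal(global_phase_arm(baf2)$flips, rep(FALSE, 5))
  expect_equal(global_phase_arm(baf2[1, , drop = FALSE])$flips, FALSE)
})

test_that("dynamic programming matches the exhaustive minimum on small arms", {
  euc <- function(u, v) sqrt(sum((u - v)^2))
  brute_cost <- function(baf) {
    B <- nrow(baf)
    best <- Inf
    for (m in 0:(2^(B - 1) - 1)) {
      fl <- c(0L, as.integer(intToBits(m))[seq_len(B - 1)])
      tot <- 0
      for (j in 2:B) {
        tot <- tot + euc(abs(fl[j - 1] - baf[j - 1, ]), abs(fl[j] - baf[j, ]))
      }
      best <- min(best, tot)
    }
    best
  }
  set.seed(5)
  for (r in 1:10) {
    B <- sample(2:8, 1)
    baf <- matrix(runif(B * 4), B, 4)
    expect_equal(global_phase_arm(baf)$cost, brute_cost(baf), tolerance = 1e-10)
  }
})

test_that("dataset phasing sums genes into bins, conserves DP, and is involutive", {
  genes <- toy_genes(1, 4)[1:2, ]
  cells <- toy_cells(0, 1)
  AD <- matrix(c(9, 1), 1, 2); DP <- matrix(10, 1, 2)
  RD <- DP
  ds <- cna_dataset(RD, genes, cells, AD = AD, DP = DP)
  ph <- phase_dataset(ds, make_bins(genes, 2))
  expect_true(ph$AD[1, 1] %in% c(18, 2))
  expect_equal(unname(ph$DP[1, 1]), 20)

  # flipping twice restores the original AD; DP invariant under flips
  x <- matrix(c(3, 7), 1, 2)
  d <- matrix(10, 1, 2)
  flip <- c(TRUE, FALSE)
  x1 <- x; x1[, flip] <- d[, flip] - x1[, flip]
  x2 <- x1; x2[, flip] <- d[, flip] - x2[, flip]
  expect_equal(x2, x)

  # total DP conserved across bin aggregation on a random dataset
  genes2 <- toy_genes(2, 10)
  cells2 <- toy_cells(3, 3)
  set.seed(2)
  DP2 <- matrix(rpois(6 * 20, 2), 6, 20)
  AD2 <- matrix(rbinom(6 * 20, as.vector(DP2), 0.5), 6, 20)
  ds2 <- cna_dataset(DP2, genes2, cells2, AD = AD2, DP = DP2)
  ph2 <- phase_dataset(ds2, make_bins(genes2, 4))
  expect_equal(sum(ph2$DP), sum(DP2))
  expect_true(all(ph2$AD <= ph2$DP))
})

test_that("relabelling alleles leaves phasing equivalent up to global inversion", {
  set.seed(31)
  C <- 50; G <- 8
  DP <- matrix(rpois(C * G, 4), C, G)
  AD <- matrix(rbinom(C * G, as.vector(DP), rep(sample(c(0.15, 0.85), C, TRUE), G)), C, G)
  f1 <- local_phase_bin(AD, DP)
  f2 <- local_phase_bin(DP - AD, DP)
  agree <- mean(f1$flips == f2$flips)
  expect_true(agree <= 0.05 || agree >= 0.95)
})

test_that("balanced data give balanced posteriors regardless of arbitrary flips", {
  # no allelic imbalance: phasing is arbitrary and must not affect the
  # balanced-state posterior downstream
  set.seed(77)
  C <- 60; G <- 20
  DP <- matrix(rpois(C * G, 5), C, G)
  AD <- matrix(rbinom(C * G, as.vector(DP), 0.5), C, G)
  flips <- sample(c(TRUE, FALSE), G, TRUE)
  AD_f <- AD; AD_f[, flips] <- DP[, flips] - AD_f[, flips]
  params <- theoretical_baf_params(1, tau = 100)
  em_a <- baf_emission(matrix(rowSums(AD), C, 1), matrix(rowSums(DP), C, 1), params)
  em_b <- baf_emission(matrix(rowSums(AD_f), C, 1), matrix(rowSums(DP), C, 1), params)
  calls_a <- names(which.max(table(apply(em_a[, 1, ], 1, which.max))))
  calls_b <- names(which.max(table(apply(em_b[, 1, ], 1, which.max))))
  expect_equal(calls_a, "3")  # balanced state dominates
  expect_equal(calls_b, "3")
})
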