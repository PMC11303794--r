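make_expr_dataset <- function(RD, n_ref, n_tumor = nrow(RD) - n_ref,
                              genes = NULL) {
  if (is.null(genes)) genes <- toy_genes(1, 2 * ncol(RD))[seq_len(ncol(RD)), ]
  cna_dataset(RD, genes, toy_cells(n_ref, n_tumor))
}

test_that("expression filter applies platform thresholds", {
  # reference means 0.4, 0.5, 2.0 over two reference cells
  RD <- rbind(c(0, 1, 2), c(0.8, 0, 2), c(5, 5, 5))
  ds <- make_expr_dataset(RD, 2)
  expect_equal(filter_genes(ds, "droplet", n_top_markers = 0),
               c(FALSE, TRUE, TRUE))
  expect_equal(filter_genes(ds, "smartseq", n_top_markers = 0),
               c(FALSE, FALSE, TRUE))
})

test_that("marker genes of annotated groups are removed from the mask", {
  set.seed(10)
  RD <- matrix(rpois(40 * 30, 5), 40, 30)
  RD[21:40, 3] <- RD[21:40, 3] + 60   # strong tumor marker
  ds <- make_expr_dataset(RD, 20, genes = toy_genes(1, 60)[1:30, ])
  mask_no <- filter_genes(ds, "droplet", n_top_markers = 0)
  mask_yes <- filter_genes(ds, "droplet", n_top_markers = 1)
  expect_true(mask_no[3])
  expect_false(mask_yes[3])
})

test_that("library factors are total-count ratios to the reference mean", {
  RD <- rbind(c(5, 5), c(15, 5), c(20, 20))
  ds <- make_expr_dataset(RD, 2)
  l <- estimate_library_factors(ds$RD, ds$cells)
  expect_equal(unname(l), c(10, 20, 40) / 15)
  RD0 <- RD; RD0[2, ] <- 0
  expect_error(estimate_library_factors(RD0, ds$cells), "bc02")
})

test_that("dispersion fitting floors degenerate genes and flags them", {
  cells <- toy_cells(5, 0)
  RD <- matrix(1, 5, 2, dimnames = list(NULL, c("g1", "g2")))
  RD[, 2] <- c(0, 0, 0, 0, 1)
  fit <- fit_dispersions(RD, cells, rep(1, 5), colMeans(RD))
  expect_equal(fit$phi[1], 1e-8)
  expect_true(fit$flagged[1])
  expect_error(fit_dispersions(RD[1, , drop = FALSE], toy_cells(1, 0),
                               1, colMeans(RD)), "2 reference")
})

test_that("CNA ratio estimation falls back to theoretical values when guided fails", {
  expect_equal(estimate_cna_ratios(mode = "theoretical"),
               c(loss = 0.5, neutral = 1, gain = 1.5))
  # fewer than three arms
  genes <- toy_genes(1, 4)[1:2, ]
  cells <- toy_cells(1, 1)
  expect_warning(C <- estimate_cna_ratios(matrix(1, 2, 2), genes, cells,
                                          mode = "guided"), "fewer than 3")
  expect_equal(unname(C), c(0.5, 1, 1.5))
  # degenerate (constant) ratios are not strictly increasing
  genes6 <- toy_genes(3, 4)
  expect_warning(C2 <- estimate_cna_ratios(matrix(1, 2, 12), genes6,
                                           cells, mode = "guided"),
                 "not strictly increasing")
  expect_equal(unname(C2), c(0.5, 1, 1.5))
})

test_that("NB emission identifies the generating state and normalises", {
  l <- c(1, 1)
  X_ref <- c(10, 10, 10)
  phi <- rep(0.01, 3)
  C <- c(loss = 0.5, neutral = 1, gain = 1.5)
  RD <- rbind(c(15, 10, 5), c(0, 0, 0))
  em <- rdr_emission(RD, l, X_ref, phi, C)
  expect_equal(tensor_states(em)[apply(em[1, , ], 1, which.max)],
               c("gain", "neutral", "loss"))
  # X = 0 with large expected count: loss posterior above gain posterior
  expect_gt(em[2, 1, "loss"], em[2, 1, "gain"])
  sums <- apply(em, c(1, 2), sum)
  expect_true(max(abs(sums - 1)) < 1e-10)
})

test_that("emission is monotone in the count for the gain-vs-loss ratio", {
  em <- rdr_emission(matrix(0:30, 31, 1), rep(1, 31), X_ref = 8, phi = 0.1)
  ratio <- em[, 1, "gain"] / em[, 1, "loss"]
  expect_true(all(diff(log(ratio)) > 0))
})

test_that("cell-count scaling with matched library factor is approximately invariant", {
  set.seed(12)
  X_ref <- rlnorm(50, log(5), 0.4)
  phi <- rep(0.1, 50)
  x <- rpois(50, X_ref)
  em1 <- rdr_emission(matrix(x, 1), 1, X_ref, phi)
  em2 <- rdr_emission(matrix(3L * x, 1), 3, X_ref, phi)
  agree <- mean(apply(em1[1, , ], 1, which.max) == apply(em2[1, , ], 1, which.max))
  expect_gte(agree, 0.85)
})

test_that("rdr_fit returns tidy parameter tables", {
  set.seed(13)
  RD <- matrix(rpois(30 * 40, 4), 30, 40)
  ds <- make_expr_dataset(RD, 15, genes = toy_genes(2, 20))
  fit <- suppressWarnings(rdr_fit(ds, ratio_mode = "theoretical",
                                  knn_k = 5, n_top_markers = 0))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), ncol(fit$emission))
  gl <- glance(fit)
  expect_equal(gl$C_neutral, 1)
})

test_that("dispersion MLE agrees with the score-equation estimator", {
  skip_if_not_installed("MASS")
  set.seed(33)
  n <- 400
  cells <- cell_meta(tibble::tibble(barcode = paste0("c", seq_len(n)),
                                    cell_type = "ref", is_reference = TRUE))
  mu <- 6
  x <- rnbinom(n, size = 1 / 0.25, mu = mu)
  RD <- matrix(x, n, 1, dimnames = list(NULL, "g1"))
  fit <- fit_dispersions(RD, cells, rep(1, n), mean(x))
  theta <- suppressWarnings(MASS::theta.ml(x, mu = rep(mean(x), n)))
  expect_equal(fit$phi[1], 1 / as.numeric(theta), tolerance = 1e-3)
})
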