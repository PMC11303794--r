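test_that("HMM config validates its inputs", {
  expect_error(hmm_config(c(0.5, 0.4)), "sum")
  expect_error(hmm_config(c(0.5, 0.5), trans_t = 1.2))
  cfg <- hmm_config(c(0.1, 0.8, 0.1))
  expect_equal(cfg$K, 3L)
})

test_that("a length-one chain returns start times emission", {
  cfg <- hmm_config(c(0.2, 0.5, 0.3))
  em <- matrix(c(0.6, 0.1, 0.3), 1, 3)
  g <- forward_backward(em, cfg)$gamma
  expected <- cfg$start * em[1, ]
  expect_equal(unname(g[1, ]), expected / sum(expected), tolerance = 1e-12)
})

test_that("uniform emissions reproduce the chain marginals from matrix powers", {
  cfg <- hmm_config(c(0.7, 0.2, 0.1), trans_t = 0.05)
  L <- 6
  em <- matrix(1, L, 3)
  g <- forward_backward(em, cfg)$gamma
  Tm <- matrix(cfg$trans_t, 3, 3); diag(Tm) <- 1 - 2 * cfg$trans_t
  marg <- cfg$start
  for (i in 1:L) {
    expect_equal(unname(g[i, ]), unname(marg), tolerance = 1e-10)
    marg <- as.numeric(marg %*% Tm)
  }
})

test_that("posteriors are invariant to positive rescaling of emission rows", {
  set.seed(17)
  cfg <- hmm_config(c(0.25, 0.25, 0.25, 0.25), trans_t = 1e-4)
  em <- matrix(runif(20 * 4), 20, 4)
  em2 <- em * runif(20, 0.1, 10)
  g1 <- forward_backward(em, cfg)$gamma
  g2 <- forward_backward(em2, cfg)$gamma
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("forward and backward passes agree on the marginal likelihood", {
  set.seed(18)
  cfg <- hmm_config(c(0.3, 0.4, 0.3), trans_t = 1e-3)
  em <- matrix(runif(15 * 3), 15, 3)
  fb <- forward_backward(em, cfg)
  # backward-only likelihood: sum_k start_k em_1k beta_1k, recomputed here
  K <- 3
  logT <- log(matrix(cfg$trans_t, K, K) + diag(rep(1 - (K - 1) * cfg$trans_t - cfg$trans_t, K)))
  lb <- matrix(0, 15, K)
  for (i in 14:1) {
    for (j in 1:K) {
      v <- logT[j, ] + log(em[i + 1, ]) + lb[i + 1, ]
      lb[i, j] <- max(v) + log(sum(exp(v - max(v))))
    }
  }
  v <- log(cfg$start) + log(em[1, ]) + lb[1, ]
  ll_backward <- max(v) + log(sum(exp(v - max(v))))
  expect_equal(fb$loglik, ll_backward, tolerance = 1e-8)
})

test_that("zero emission rows are replaced by uniform and flagged", {
  cfg <- hmm_config(c(0.5, 0.5), trans_t = 0.01)
  em <- rbind(c(0.9, 0.1), c(0, 0), c(0.2, 0.8))
  fb <- forward_backward(em, cfg)
  expect_equal(fb$zero_rows, 2L)
  expect_true(all(is.finite(fb$gamma)))
})

test_that("emission smoothing respects identity, averaging and normalisation", {
  set.seed(19)
  tens <- random_state_tensor(4, 6, 3, c("loss", "neutral", "gain"))
  out <- smooth_emission(tens, Matrix::Diagonal(4))
  expect_equal(unclass(out)[, , ], unclass(tens)[, , ], tolerance = 1e-12)

  # two identical cells fully averaged stay identical
  tens2 <- random_state_tensor(2, 5, 3, c("loss", "neutral", "gain"))
  tens2[2, , ] <- tens2[1, , ]
  M <- matrix(0.5, 2, 2)
  out2 <- smooth_emission(state_tensor(unclass(tens2), tensor_states(tens2)), M)
  expect_equal(out2[1, , ], out2[2, , ], tolerance = 1e-12)

  sums <- apply(out, c(1, 2), sum)
  expect_true(max(abs(sums - 1)) < 1e-10)
})

test_that("uninformative transitions with identity smoothing return the emissions", {
  set.seed(20)
  tens <- random_state_tensor(3, 8, 3, c("loss", "neutral", "gain"))
  cfg <- hmm_config(rep(1/3, 3), trans_t = 1/3 - 1e-12)
  res <- infer_states(tens, NULL, cfg, rep("1", 8), neutral_state = "neutral")
  expect_equal(unclass(res$posterior)[, , ], unclass(tens)[, , ],
               tolerance = 1e-6)
})

test_that("chains reset at chromosome boundaries", {
  cfg <- hmm_config(c(0.5, 0.5), trans_t = 1e-6)
  # strong state-1 evidence on chrom 1, strong state-2 evidence on chrom 2
  em <- array(0, c(1, 8, 2))
  em[1, 1:4, 1] <- 0.99; em[1, 1:4, 2] <- 0.01
  em[1, 5:8, 1] <- 0.01; em[1, 5:8, 2] <- 0.99
  tens <- state_tensor(em / array(rep(apply(em, c(1, 2), sum), 2), dim(em)),
                       c("neutral", "alt"))
  res <- infer_states(tens, NULL, cfg, rep(c("1", "2"), each = 4),
                      neutral_state = "neutral")
  expect_true(all(res$calls[1, 1:4] == "neutral"))
  expect_true(all(res$calls[1, 5:8] == "alt"))
})

test_that("raising the transition rate relaxes smoothing monotonically", {
  set.seed(3)
  L <- 60; K <- 3
  truth <- rep(1:3, each = 20)
  em <- matrix(0.15 / (K - 1), L, K)
  em[cbind(1:L, truth)] <- 0.85
  em <- em * matrix(runif(L * K, 0.8, 1.2), L, K)
  sharp <- vapply(c(1e-6, 1e-4, 1e-2, 0.2), function(tt) {
    mean(apply(forward_backward(em, hmm_config(rep(1/3, 3), tt))$gamma, 1, max))
  }, numeric(1))
  expect_true(all(diff(sharp) < 0))
})
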