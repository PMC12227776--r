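test_that("Treves-Rolls sparseness hits its edge cases exactly", {
  expect_identical(population_sparseness(c(0.3, 0.3, 0.3)), 1)
  expect_identical(population_sparseness(c(0, 0, 0, 1)), 0.25)
  expect_equal(population_sparseness(c(1, 0.5)), 0.75^2 / 0.625)
  expect_equal(population_sparseness(c(1, 0.5)), 0.9)
  # scale invariance
  set.seed(1)
  r <- runif(50)
  expect_equal(population_sparseness(r), population_sparseness(3.7 * r),
               tolerance = 1e-12)
  expect_error(population_sparseness(c(-1, 2)), "non-negative")
  expect_error(population_sparseness(c(0, 0)), "zero")

  m <- rbind(c(0.3, 0.3, 0.3), c(0, 0, 1))
  tr <- sparseness_trial(m, layer = "L5")
  expect_equal(tr$s_per_stimulus, c(1, 1 / 3))
  expect_equal(tr$s_mean, 2 / 3)
  expect_identical(tr$n_neurons, 3L)
})

test_that("linear decoding separates blobs and degrades to chance on shuffles", {
  set.seed(2)
  n <- 120
  labels <- rep(1:2, each = n)
  feats <- rbind(matrix(rnorm(n * 4, 0), n),
                 matrix(rnorm(n * 4, 4), n))
  for (method in c("multinom", "svm")) {
    dr <- linear_decode(feats, labels, seed = 3, method = method)
    expect_identical(dr$accuracy, 1)
    expect_equal(sum(dr$confusion), dr$n_test)
    expect_equal(unname(diag(dr$confusion)), unname(rowSums(dr$confusion)))
  }
  # shuffled labels: 10-class chance within 3 sigma
  set.seed(4)
  feats10 <- matrix(rnorm(1500 * 6), 1500)
  labels10 <- rep(1:10, each = 150)
  ch <- linear_decode(feats10, labels10, seed = 5, shuffle = TRUE)
  n_test <- ch$n_test
  expect_lt(abs(ch$accuracy - 0.1), 3 * sqrt(0.1 * 0.9 / n_test))
  expect_error(linear_decode(feats, rep(1, 240)), "2 classes")
})

test_that("explained-variance profile identifies rank and degeneracy", {
  set.seed(6)
  base <- rnorm(30)
  rank1 <- outer(runif(40), base)
  ev <- explained_variance_profile(rank1)
  expect_equal(ev$cum_var[1], 1, tolerance = 1e-9)
  expect_identical(ev$n90, 1L)
  expect_false(ev$degenerate)

  flat <- matrix(2.5, 10, 4)
  expect_true(explained_variance_profile(flat)$degenerate)

  # isotropic data: curve approximately linear in component count
  iso <- matrix(rnorm(4000 * 8), 4000)
  evi <- explained_variance_profile(iso)
  expect_lt(max(abs(evi$cum_var - (1:8) / 8)), 0.05)
})

test_that("baseline subtraction self-consistency: no-mismatch stream gives ME ~ 0", {
  spec <- visuomotor_spec(mismatch_rate = 0, seed = 7)
  vm <- visuomotor_stream(spec, 4000)
  w <- microcircuit_weights(spec$n_dims, 16, 16, 16, n_td = 1, seed = 8)
  st <- as_training_stream(vm)
  # label one half of the baseline as pseudo-mismatch: both halves are
  # statistically identical, so the subtracted ME must be near zero
  st$mismatch <- seq_len(nrow(st$x_t)) %% 2 == 0
  rep <- mismatch_errors(w, st, margin = 0)
  scale <- mean(abs(rep$l23$me_baseline)) + mean(abs(rep$l5$me_baseline))
  expect_lt(mean(abs(rep$l23$me)), 0.05 * scale)
  expect_lt(mean(abs(rep$l5$me)), 0.05 * scale)
  expect_equal(rep$l23$me, rep$l23$me_mismatch - rep$l23$me_baseline,
               tolerance = 1e-12)
  expect_error(mismatch_errors(w, as_training_stream(vm)), "mismatch")
})

test_that("stimulation protocol: identity at gain 1, rejects gain < 1", {
  spec <- visuomotor_spec(mismatch_rate = 1 / 800, seed = 9)
  vm <- visuomotor_stream(spec, 6000)
  w <- microcircuit_weights(spec$n_dims, 16, 16, 16, n_td = 1, seed = 10)
  st <- as_training_stream(vm)
  for (layer in c("l5", "l23")) {
    sr <- stimulation_experiment(w, st, layer, gain = 1)
    expect_equal(sr$after$me, sr$before$me, tolerance = 1e-10)
  }
  expect_error(stimulation_experiment(w, st, "l5", gain = 0.5), "gain")
  # subset restriction only touches the chosen neurons' columns
  sr2 <- stimulation_experiment(w, st, "l5", gain = 3, subset = "positive_me")
  expect_s3_class(sr2$after, "mismatch_report")
})

test_that("denoising autoencoder baseline is deterministic and monotone", {
  spec <- gabor_task_spec(seed = 12)
  gs <- gabor_sequence(spec, 400)
  levels <- c(0, 0.5, 1)
  d1 <- denoising_autoencoder_baseline(gs$frames, levels, seed = 13,
                                       n_hidden = 32, epochs = 8)
  d2 <- denoising_autoencoder_baseline(gs$frames, levels, seed = 13,
                                       n_hidden = 32, epochs = 8)
  expect_identical(d1$residuals, d2$residuals)
  expect_true(all(diff(d1$residuals$mse) >= 0))
})

test_that("reconstruction residuals: level zero is the clean residual", {
  cfg <- gabor_config(n_l4 = 16, n_l23 = 16, n_l5 = 16, train_steps = 1500,
                      eval_steps = 300)
  m <- train_gabor_model(1, cfg)
  spec <- gabor_task_spec(seed = 1)
  eseq <- gabor_sequence(spec, 201, seed = 55)
  rr <- reconstruction_residual(m$weights, eseq, "noise", c(0, 0.5),
                                seed = 3)
  st <- as_training_stream(eseq)
  fwd <- forward_sequence(m$weights, st)
  expect_equal(rr$mse_l5[1], mean((fwd$xhat - st$x_t)^2), tolerance = 1e-12)
  expect_gt(rr$mse_l5[2], rr$mse_l5[1])
  ro <- reconstruction_residual(m$weights, eseq, "occlusion", c(0, 10),
                                seed = 3)
  expect_gt(ro$mse_l5[2], ro$mse_l5[1])
})
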