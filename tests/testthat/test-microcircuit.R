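test_that("layer encodings match an independent sigmoid-matvec oracle", {
  w <- tiny_weights(seed = 3)
  set.seed(11)
  x <- runif(6); x2 <- runif(6); itd <- runif(2)

  expect_equal(l4_encode(x, w),
               sig_oracle(as.vector(w$W_thal_l4 %*% x)), tolerance = 1e-12)

  z4 <- l4_encode(x, w)
  expect_equal(l23_integrate(z4, itd, w),
               sig_oracle(as.vector(w$W_l4_l23 %*% z4 + w$W_td_l23 %*% itd)),
               tolerance = 1e-12)

  z23 <- l23_integrate(z4, itd, w)
  l5 <- l5_integrate(z23, x2, w)
  u_expect <- as.vector(w$alpha * w$W_l23_l5 %*% z23 + w$W_thal_l5 %*% x2)
  expect_equal(l5$u_l5, u_expect, tolerance = 1e-12)
  expect_equal(l5$z_l5, sig_oracle(u_expect), tolerance = 1e-12)

  expect_equal(predict_l5(z23, w), as.vector(w$W_l23_l5 %*% z23),
               tolerance = 1e-12)
  expect_equal(reconstruct_input(l5$z_l5, w),
               as.vector(w$W_decoder %*% l5$z_l5), tolerance = 1e-12)
})

test_that("zero weights give 0.5 activations and activations stay in (0,1)", {
  w <- tiny_weights(seed = 1)
  w$W_thal_l4[] <- 0
  expect_equal(l4_encode(runif(6) * 5, w), rep(0.5, 5))

  w2 <- tiny_weights(seed = 2)
  w2$W_l4_l23[] <- 0; w2$W_td_l23[] <- 0
  expect_equal(l23_integrate(runif(5), runif(2), w2), rep(0.5, 4))

  # both L5 drives removed by knockouts
  fl <- knockout_flags(ko_l23_l5 = TRUE, ko_thal_l5 = TRUE)
  expect_equal(l5_integrate(runif(4), runif(6), tiny_weights(), fl)$z_l5,
               rep(0.5, 3))

  acts <- rand_step(tiny_weights(seed = 5), seed = 6)
  for (z in list(acts$z_l4, acts$z_l23, acts$z_l5)) {
    expect_true(all(z > 0 & z < 1))
  }
})

test_that("prediction vector is unattenuated and unsquashed", {
  w <- tiny_weights(seed = 4, n_l23 = 3, n_l5 = 3)
  w$W_l23_l5 <- diag(3)
  z23 <- c(0.2, 0.5, 0.9)
  expect_identical(predict_l5(z23, w), z23)
  expect_equal(predict_l5(numeric(3), w), numeric(3))
  # inside the L5 dynamics the same product is alpha-scaled and squashed
  acts <- forward_step(runif(6), runif(6), runif(2), w)
  expect_equal(acts$zhat_l5, as.vector(w$W_l23_l5 %*% acts$z_l23))
  expect_false(isTRUE(all.equal(acts$zhat_l5, acts$z_l5)))
})

test_that("knockout switches remove exactly their pathway", {
  w <- tiny_weights(seed = 7)
  set.seed(8)
  x1 <- runif(6); x2 <- runif(6)
  itd_a <- c(1, 0); itd_b <- c(0, 1)

  # top-down knockout: output independent of the context vector
  fl <- knockout_flags(ko_topdown = TRUE)
  z4 <- l4_encode(x1, w)
  expect_identical(l23_integrate(z4, itd_a, w, fl),
                   l23_integrate(z4, itd_b, w, fl))

  # L2/3 -> L5 knockout: z5 invariant under perturbing z23
  fl2 <- knockout_flags(ko_l23_l5 = TRUE)
  expect_identical(l5_integrate(runif(4), x2, w, fl2)$z_l5,
                   l5_integrate(runif(4), x2, w, fl2)$z_l5)

  # alpha -> 0 reduces z5 to the thalamus-only encoding exactly
  w0 <- w; w0$alpha <- 1e-300
  z23 <- runif(4)
  expect_equal(l5_integrate(z23, x2, w0)$z_l5,
               sigmoid(as.vector(w0$W_thal_l5 %*% x2)), tolerance = 1e-12)

  # delay knockout only matters when x_prev != x_t
  a_same <- forward_step(x1, x1, itd_a, w)
  b_same <- forward_step(x1, x1, itd_a, w, knockout_flags(ko_delay = TRUE))
  expect_identical(a_same$z_l23, b_same$z_l23)
  a_diff <- forward_step(x1, x2, itd_a, w)
  b_diff <- forward_step(x1, x2, itd_a, w, knockout_flags(ko_delay = TRUE))
  expect_false(identical(a_diff$z_l23, b_diff$z_l23))
  expect_equal(b_diff$z_l4, l4_encode(x2, w))
})

test_that("forward_step is deterministic and matches field-by-field oracle", {
  w <- tiny_weights(seed = 9)
  set.seed(10)
  xp <- runif(6); xt <- runif(6); itd <- runif(2)
  a <- forward_step(xp, xt, itd, w)
  b <- forward_step(xp, xt, itd, w)
  expect_identical(a, b)

  z4 <- sig_oracle(as.vector(w$W_thal_l4 %*% xp))
  z23 <- sig_oracle(as.vector(w$W_l4_l23 %*% z4 + w$W_td_l23 %*% itd))
  u5 <- as.vector(w$alpha * w$W_l23_l5 %*% z23 + w$W_thal_l5 %*% xt)
  expect_equal(a$z_l4, z4, tolerance = 1e-12)
  expect_equal(a$z_l23, z23, tolerance = 1e-12)
  expect_equal(a$z_l5, sig_oracle(u5), tolerance = 1e-12)
  expect_equal(a$zhat_l5, as.vector(w$W_l23_l5 %*% z23), tolerance = 1e-12)
  expect_equal(a$xhat, as.vector(w$W_decoder %*% sig_oracle(u5)),
               tolerance = 1e-12)
})

test_that("batched forward pass agrees with per-step forward_step", {
  w <- tiny_weights(seed = 12)
  set.seed(13)
  T_len <- 7
  stream <- as_training_stream(list(
    x_prev = matrix(runif(T_len * 6), T_len),
    x_t = matrix(runif(T_len * 6), T_len),
    i_td = matrix(runif(T_len * 2), T_len)))
  for (fl in list(knockout_flags(), knockout_flags(ko_delay = TRUE),
                  knockout_flags(ko_thal_l5 = TRUE),
                  knockout_flags(ko_l4_l23 = TRUE, ko_topdown = TRUE))) {
    fwd <- forward_sequence(w, stream, fl)
    for (t in seq_len(T_len)) {
      acts <- forward_step(stream$x_prev[t, ], stream$x_t[t, ],
                           stream$i_td[t, ], w, fl)
      expect_equal(fwd$z_l23[t, ], acts$z_l23, tolerance = 1e-12)
      expect_equal(fwd$z_l5[t, ], acts$z_l5, tolerance = 1e-12)
      expect_equal(fwd$zhat_l5[t, ], acts$zhat_l5, tolerance = 1e-12)
      expect_equal(fwd$xhat[t, ], acts$xhat, tolerance = 1e-12)
    }
  }
})

test_that("shape errors name the offending quantity", {
  w <- tiny_weights()
  expect_error(l4_encode(runif(7), w), "x")
  expect_error(l23_integrate(runif(3), runif(2), w), "z_l4_prev")
  expect_error(predict_l5(runif(9), w), "z_l23")
  expect_error(forward_step(runif(6), runif(5), runif(2), w), "x_t")
  expect_error(microcircuit_weights(6, alpha = 0), "alpha")
})

test_that("weights serialize to a bit-exact round trip", {
  w <- tiny_weights(seed = 20, feedback = feedback_spec("random", 0.7,
                                                        mask_seed = 5))
  path <- tempfile(fileext = ".rds")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_identical(w, w2)
  unlink(path)
})

test_that("feedback matrix obeys mode, live transpose, and mask", {
  w <- tiny_weights(seed = 21)
  expect_identical(feedback_matrix(w), t(w$W_l23_l5))
  # live view: reflects later edits of the forward weights
  w$W_l23_l5[1, 1] <- 99
  expect_identical(feedback_matrix(w)[1, 1], 99)

  wz <- set_feedback(w, feedback_spec("none"))
  expect_true(all(feedback_matrix(wz) == 0))
  expect_true(all(make_feedback(w, feedback_spec("none")) == 0))

  # p = 0 zeroes everything regardless of mode
  expect_true(all(make_feedback(w, feedback_spec("symmetric", 0)) == 0))

  # random mode is fixed: does not track W_l23_l5
  wr <- set_feedback(w, feedback_spec("random", mask_seed = 3))
  fb1 <- feedback_matrix(wr)
  wr$W_l23_l5[2, 2] <- -50
  expect_identical(feedback_matrix(wr), fb1)

  # masked fraction within 3 sigma of p over ~1000 entries
  big <- microcircuit_weights(4, n_l4 = 4, n_l23 = 40, n_l5 = 25, n_td = 2,
                              feedback = feedback_spec("symmetric", 0.5,
                                                       mask_seed = 11))
  frac <- mean(big$fb_mask == 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})
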