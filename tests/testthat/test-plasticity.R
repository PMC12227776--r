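test_that("cost components match their closed forms and combine exactly", {
  w <- tiny_weights(seed = 1)
  acts <- rand_step(w, seed = 2)

  expect_equal(predictive_cost(acts),
               0.5 * sum((acts$zhat_l5 - acts$z_l5)^2), tolerance = 1e-12)
  expect_equal(reconstruction_cost(acts),
               0.5 * sum((acts$x_t - acts$xhat)^2), tolerance = 1e-12)

  # hand cases: perfect prediction -> 0; unit error -> 1/2
  a2 <- acts
  a2$zhat_l5 <- a2$z_l5
  expect_identical(predictive_cost(a2), 0)
  a3 <- acts
  a3$zhat_l5 <- c(1, 0, 0); a3$z_l5 <- c(0, 0, 0)
  expect_identical(predictive_cost(a3), 0.5)
  a4 <- acts
  a4$x_t <- rep(1, 6); a4$xhat <- rep(1, 6)
  expect_identical(reconstruction_cost(a4), 0)

  cb <- cost_breakdown(acts, lambda_p = 0.7, lambda_r = 2.5)
  expect_identical(cb$c_total, 0.7 * cb$c_pred + 2.5 * cb$c_recon)
})

test_that("layer error signals agree with central finite differences", {
  w <- tiny_weights(seed = 5)
  acts <- rand_step(w, seed = 6)
  lp <- 1.3; lr <- 0.8

  # L5: total cost as a function of z5, zhat held, xhat through W_decoder
  f5 <- function(z5) {
    lp * 0.5 * sum((acts$zhat_l5 - z5)^2) +
      lr * 0.5 * sum((acts$x_t - as.vector(w$W_decoder %*% z5))^2)
  }
  expect_lt(rel_err(l5_error_signal(acts, w, lp, lr),
                    fd_grad(f5, acts$z_l5)), 1e-6)

  # zero when prediction and reconstruction are both perfect
  ap <- acts
  ap$zhat_l5 <- ap$z_l5
  ap$xhat <- ap$x_t
  expect_equal(l5_error_signal(ap, w), numeric(3))

  # predictive-only, zhat > z5 componentwise -> strictly negative entries
  an <- acts
  an$zhat_l5 <- an$z_l5 + runif(3, 0.1, 0.3)
  expect_true(all(l5_error_signal(an, w, lambda_r = 0) < 0))

  # L2/3: predictive cost with z5 recomputed through the L5 dynamics
  f23 <- function(z23) {
    zhat <- as.vector(w$W_l23_l5 %*% z23)
    z5 <- sigmoid(w$alpha * zhat + as.vector(w$W_thal_l5 %*% acts$x_t))
    lp * 0.5 * sum((zhat - z5)^2)
  }
  expect_lt(rel_err(l23_error_signal(acts, w, lp),
                    fd_grad(f23, acts$z_l23)), 1e-6)

  # alpha -> 0 reduces the backprojection to the plain transpose
  w0 <- w; w0$alpha <- 1e-300
  a0 <- rand_step(w0, seed = 7)
  e <- lp * (a0$zhat_l5 - a0$z_l5)
  expect_equal(l23_error_signal(a0, w0, lp),
               as.vector(t(w0$W_l23_l5) %*% e), tolerance = 1e-10)
})

test_that("every analytic weight update matches finite differences", {
  w <- tiny_weights(seed = 9)
  set.seed(10)
  xp <- runif(6); xt <- runif(6); itd <- runif(2)
  acts <- forward_step(xp, xt, itd, w)
  lp <- 1.1; lr <- 0.6

  fd_for <- function(field, lambda_p = lp, lambda_r = lr) {
    fd_grad(function(W) {
      w2 <- w; w2[[field]] <- W
      cost_of_weights(w2, xp, xt, itd, lambda_p, lambda_r)
    }, w[[field]])
  }

  # W_l23_l5 and W_l4_l23 see only the predictive component (blocking)
  expect_lt(rel_err(grad_w_l23_l5(acts, w, lp, eta = 1),
                    -fd_for("W_l23_l5", lambda_r = 0)), 1e-5)
  expect_lt(rel_err(grad_w_l4_l23(acts, w, lp, eta = 1),
                    -fd_for("W_l4_l23", lambda_r = 0)), 1e-5)

  # W_thal_l5 sees both components
  expect_lt(rel_err(grad_w_thal_l5(acts, w, lp, lr, eta = 1),
                    -fd_for("W_thal_l5")), 1e-5)

  # upstream chain-rule updates (symmetric feedback) and decoder
  up <- grad_upstream(acts, w, lp, lr, eta = 1)
  expect_lt(rel_err(up$W_thal_l4, -fd_for("W_thal_l4", lambda_r = 0)), 1e-5)
  expect_lt(rel_err(up$W_td_l23, -fd_for("W_td_l23", lambda_r = 0)), 1e-5)
  expect_lt(rel_err(up$W_decoder,
                    -fd_grad(function(W) {
                      lr * 0.5 * sum((xt - as.vector(W %*% acts$z_l5))^2)
                    }, w$W_decoder)), 1e-5)

  # eta scales every update linearly
  expect_equal(grad_w_l23_l5(acts, w, lp, eta = 2),
               2 * grad_w_l23_l5(acts, w, lp, eta = 1), tolerance = 1e-12)

  # zero error -> zero updates
  a0 <- acts
  a0$zhat_l5 <- a0$z_l5
  a0$xhat <- a0$x_t
  expect_equal(grad_w_l23_l5(a0, w), matrix(0, 3, 4))
  expect_equal(grad_upstream(a0, w)$W_decoder, matrix(0, 6, 3))
})

test_that("the simplified thalamus-to-L5 rule drops the sigmoid slope", {
  w <- tiny_weights(seed = 11)
  acts <- rand_step(w, seed = 12)
  full <- grad_w_thal_l5(acts, w, eta = 1)
  lit <- grad_w_thal_l5(acts, w, eta = 1, literal = TRUE)
  err5 <- l5_error_signal(acts, w)
  expect_equal(lit, -err5 %*% t(acts$x_t), tolerance = 1e-12)
  expect_equal(full, -(err5 * dsigmoid_u(acts$u_l5)) %*% t(acts$x_t),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(full, lit)))
})

test_that("reconstruction gradients are blocked from the L2/3 pathway", {
  w <- tiny_weights(seed = 13)
  acts <- rand_step(w, seed = 14)
  g1 <- gradient_set(acts, w)

  w2 <- w
  w2$W_decoder <- w2$W_decoder + matrix(rnorm(18), 6, 3)
  acts2 <- forward_step(acts$x_prev, acts$x_t, acts$i_td, w2)
  # same activations up to L5 (decoder only affects xhat)
  expect_identical(acts2$z_l5, acts$z_l5)
  g2 <- gradient_set(acts2, w2)
  for (nm in c("W_l23_l5", "W_l4_l23", "W_thal_l4", "W_td_l23")) {
    expect_identical(g1[[nm]], g2[[nm]])
  }
  # while the decoder and thalamo-L5 updates do change
  expect_false(identical(g1$W_decoder, g2$W_decoder))
  expect_false(identical(g1$W_thal_l5, g2$W_thal_l5))
})

test_that("feedback mode none yields exactly zero L2/3-upstream updates", {
  w <- tiny_weights(seed = 15, feedback = feedback_spec("none"))
  acts <- rand_step(w, seed = 16)
  expect_equal(grad_w_l4_l23(acts, w), matrix(0, 4, 5))
  up <- grad_upstream(acts, w)
  expect_equal(up$W_thal_l4, matrix(0, 5, 6))
  expect_equal(up$W_td_l23, matrix(0, 4, 2))
  # the decoder still learns
  expect_false(all(up$W_decoder == 0))
})

test_that("random feedback updates are deterministic and differ from symmetric", {
  w <- tiny_weights(seed = 17, feedback = feedback_spec("random",
                                                        mask_seed = 4))
  acts <- rand_step(w, seed = 18)
  g1 <- grad_w_l4_l23(acts, w)
  g2 <- grad_w_l4_l23(acts, w)
  expect_identical(g1, g2)
  ws <- set_feedback(w, feedback_spec("symmetric"))
  expect_false(identical(g1, grad_w_l4_l23(acts, ws)))
})

test_that("compiled trainer reproduces the reference R update step", {
  set.seed(30)
  T_len <- 5
  stream <- as_training_stream(list(
    x_prev = matrix(runif(T_len * 6), T_len),
    x_t = matrix(runif(T_len * 6), T_len),
    i_td = matrix(runif(T_len * 2), T_len)))

  for (fb in list(feedback_spec("symmetric"),
                  feedback_spec("random", mask_seed = 2),
                  feedback_spec("none"),
                  feedback_spec("symmetric", 0.5, mask_seed = 7))) {
    for (fl in list(knockout_flags(), knockout_flags(ko_delay = TRUE),
                    knockout_flags(ko_l23_l5 = TRUE),
                    knockout_flags(ko_thal_l5 = TRUE, ko_topdown = TRUE))) {
      w <- tiny_weights(seed = 31, feedback = fb)
      cfg <- train_config(lambda_p = 1.2, lambda_r = 0.7, eta = 0.05,
                          optimizer = "sgd", flags = fl)
      res <- train(w, stream, cfg)
      wr <- w
      for (t in seq_len(T_len)) {
        wr <- train_step_r(wr, stream$x_prev[t, ], stream$x_t[t, ],
                           stream$i_td[t, ], cfg)
      }
      for (nm in c("W_thal_l4", "W_l4_l23", "W_td_l23", "W_l23_l5",
                   "W_thal_l5", "W_decoder")) {
        expect_equal(res$weights[[nm]], wr[[nm]], tolerance = 1e-12,
                     info = paste(fb$mode, nm))
      }
    }
  }
})

test_that("training is deterministic and its cost decreases on a fixed input", {
  set.seed(40)
  x <- runif(6)
  itd <- runif(2)
  rep_stream <- as_training_stream(list(
    x_prev = matrix(x, 100, 6, byrow = TRUE),
    x_t = matrix(x, 100, 6, byrow = TRUE),
    i_td = matrix(itd, 100, 2, byrow = TRUE)))
  w <- tiny_weights(seed = 41)
  cfg <- train_config(eta = 0.1, optimizer = "sgd")
  r1 <- train(w, rep_stream, cfg)
  r2 <- train(w, rep_stream, cfg)
  expect_identical(r1$weights, r2$weights)
  expect_true(all(diff(r1$costs$c_total) <= 1e-10))
  expect_lt(r1$costs$c_total[100], r1$costs$c_total[1])
})

test_that("training with feedback mode none leaves upstream weights untouched", {
  set.seed(42)
  stream <- as_training_stream(list(
    x_prev = matrix(runif(240), 40),
    x_t = matrix(runif(240), 40),
    i_td = matrix(runif(80), 40)))
  w <- tiny_weights(seed = 43, feedback = feedback_spec("none"))
  res <- train(w, stream, train_config(eta = 0.05, optimizer = "sgd"))
  expect_identical(res$weights$W_thal_l4, w$W_thal_l4)
  expect_identical(res$weights$W_l4_l23, w$W_l4_l23)
  expect_identical(res$weights$W_td_l23, w$W_td_l23)
  expect_false(identical(res$weights$W_l23_l5, w$W_l23_l5))
})

test_that("plasticity curve shows the depression-to-potentiation switch", {
  pc <- plasticity_curve(n_samples = 500, seed = 2)
  expect_gt(pc$slope, 0)
  # doubling eta doubles every sampled update
  pc2 <- plasticity_curve(n_samples = 500, seed = 2, eta = 2)
  expect_equal(pc2$samples$update, 2 * pc$samples$update, tolerance = 1e-12)
  # at z5 = zhat the update is exactly zero
  w <- tiny_weights(seed = 50)
  acts <- rand_step(w, seed = 51)
  acts$z_l5 <- acts$zhat_l5
  expect_equal(grad_w_l23_l5(acts, w), matrix(0, 3, 4))
  expect_error(plasticity_curve(n_samples = 5), "n_samples")
})

test_that("train config round-trips through YAML with strict keys", {
  cfg <- train_config(lambda_p = 0.5, eta = 2e-4, optimizer = "sgd",
                      flags = knockout_flags(ko_delay = TRUE))
  path <- tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  cfg2 <- read_train_config(path)
  expect_equal(cfg2$lambda_p, 0.5)
  expect_equal(cfg2$eta, 2e-4)
  expect_true(cfg2$flags$ko_delay)
  writeLines(c("eta: 0.1", "bogus_key: 3"), path)
  expect_error(read_train_config(path), "bogus_key")
  unlink(path)
})
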