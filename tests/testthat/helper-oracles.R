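# Small random circuit instances and finite-difference oracles shared by the
# gradient and dynamics tests.

tiny_weights <- function(seed = 1, n_in = 6, n_l4 = 5, n_l23 = 4, n_l5 = 3,
                         n_td = 2, feedback = feedback_spec()) {
  microcircuit_weights(n_in = n_in, n_l4 = n_l4, n_l23 = n_l23, n_l5 = n_l5,
                       n_td = n_td, feedback = feedback, seed = seed)
}

rand_step <- function(w, seed = 1, flags = knockout_flags()) {
  set.seed(seed)
  d <- w$dims
  forward_step(runif(d[["n_in"]]), runif(d[["n_in"]]), runif(d[["n_td"]]),
               w, flags)
}

# independent elementwise sigmoid used by the re-implementation oracles
sig_oracle <- function(u) exp(u) / (1 + exp(u))

# central finite differences of scalar f w.r.t. a matrix or vector argument
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}

# total cost as a function of the weights, recomputing the forward pass:
# the differentiable target of the learning rules (symmetric feedback)
cost_of_weights <- function(w, x_prev, x_t, i_td, lambda_p = 1,
                            lambda_r = 1) {
  z4 <- sigmoid(as.vector(w$W_thal_l4 %*% x_prev))
  z23 <- sigmoid(as.vector(w$W_l4_l23 %*% z4 + w$W_td_l23 %*% i_td))
  zhat <- as.vector(w$W_l23_l5 %*% z23)
  z5 <- sigmoid(w$alpha * zhat + as.vector(w$W_thal_l5 %*% x_t))
  xhat <- as.vector(w$W_decoder %*% z5)
  lambda_p * 0.5 * sum((zhat - z5)^2) + lambda_r * 0.5 * sum((x_t - xhat)^2)
}
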