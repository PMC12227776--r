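#' Update for the L2/3-to-L5 prediction weights
#'
#' Delta W_l23_l5 = -eta * lambda_p * outer(e * (1 - alpha * sigmoid'(u^L5)),
#' z^L2/3), with e = zhat^L5 - z^L5. The elementwise factor
#' (1 - alpha * sigmoid'(u^L5)) is the attenuation effect: the weight enters
#' both the prediction readout and (alpha-scaled, through the sigmoid) the
#' L5 activity itself. Reconstruction gradients are blocked from this matrix.
#'
#' The rule reproduces the depression-to-potentiation switch seen in
#' long-term plasticity of L2/3-to-L5 synapses: for fixed presynaptic L2/3
#' activity the mean update grows with postsynaptic L5 activity, crossing
#' from depression (z^L5 below the prediction) to potentiation (above it).
#'
#' @param acts a `step_activations` object.
#' @param weights a [microcircuit_weights()] object.
#' @param lambda_p predictive cost scale.
#' @param eta learning rate.
#' @return An n_l5 x n_l23 update matrix (to be *added* to W_l23_l5).
#' @export
grad_w_l23_l5 <- function(acts, weights, lambda_p = 1, eta = 1) {
  stopifnot(inherits(acts, "step_activations"),
            inherits(weights, "microcircuit_weights"))
  e <- acts$zhat_l5 - acts$z_l5
  ef <- e * (1 - weights$alpha * dsigmoid_u(acts$u_l5))
  -eta * lambda_p * (ef %*% t(acts$z_l23))
}

#' Update for the L4-to-L2/3 weights (feedback-carried error)
#'
#' The L5-side predictive error, filtered by the attenuation effect, is
#' carried to L2/3 through the feedback pathway (the transpose of W_l23_l5
#' in symmetric mode, a fixed random matrix in random mode, zero in none
#' mode), multiplied by sigmoid'(u^L2/3), and outer-multiplied with the
#' presynaptic L4 activity. With no feedback the update is exactly zero —
#' L2/3 cannot learn. Reconstruction gradients are blocked.
#'
#' @inheritParams grad_w_l23_l5
#' @param fb optional explicit feedback matrix; defaults to
#'   [feedback_matrix()] of `weights`.
#' @return An n_l23 x n_l4 update matrix.
#' @export
grad_w_l4_l23 <- function(acts, weights, lambda_p = 1, eta = 1, fb = NULL) {
  d23 <- l23_delta(acts, weights, lambda_p, fb)
  -eta * (d23 %*% t(acts$z_l4))
}

## shared backpropagated L2/3 delta: feedback matrix applied to the
## attenuation-filtered predictive error, times sigmoid'(u_l23)
l23_delta <- function(acts, weights, lambda_p = 1, fb = NULL) {
  stopifnot(inherits(acts, "step_activations"),
            inherits(weights, "microcircuit_weights"))
  if (is.null(fb)) fb <- feedback_matrix(weights)
  e <- lambda_p * (acts$zhat_l5 - acts$z_l5)
  ef <- (1 - weights$alpha * dsigmoid_u(acts$u_l5)) * e
  as.vector(fb %*% ef) * dsigmoid_u(acts$u_l23)
}

#' Update for the thalamus-to-L5 weights
#'
#' The only matrix adapted by *both* cost components:
#' Delta W_thal_l5 = -eta * outer(err5 * sigmoid'(u^L5), x_t) with err5 the
#' full L5 error signal ([l5_error_signal()]). The sigmoid-derivative factor
#' follows from differentiating the L5 dynamics; `literal = TRUE` drops it,
#' reproducing a commonly printed simplified form of the rule (the
#' finite-difference oracle validates the default).
#'
#' @inheritParams grad_w_l23_l5
#' @param lambda_r reconstruction cost scale.
#' @param literal drop the sigmoid-derivative factor.
#' @return An n_l5 x n_in update matrix.
#' @export
grad_w_thal_l5 <- function(acts, weights, lambda_p = 1, lambda_r = 1,
                           eta = 1, literal = FALSE) {
  err5 <- l5_error_signal(acts, weights, lambda_p, lambda_r)
  if (!literal) err5 <- err5 * dsigmoid_u(acts$u_l5)
  -eta * (err5 %*% t(acts$x_t))
}

#' Updates for the remaining trainable matrices
#'
#' Chain-rule continuations of the feedback-carried L2/3 error for
#' W_thal_l4 and W_td_l23, plus the decoder update
#' Delta W_decoder = -eta * lambda_r * outer(xhat - x_t, z^L5). The
#' reconstruction gradient is confined to the decoder; with feedback mode
#' none the two upstream updates are exactly zero.
#'
#' @inheritParams grad_w_l4_l23
#' @param lambda_r reconstruction cost scale (decoder update only).
#' @return List with matrices `W_thal_l4`, `W_td_l23`, `W_decoder`.
#' @export
grad_upstream <- function(acts, weights, lambda_p = 1, lambda_r = 1,
                          eta = 1, fb = NULL) {
  d23 <- l23_delta(acts, weights, lambda_p, fb)
  d4 <- as.vector(t(weights$W_l4_l23) %*% d23) * dsigmoid_u(acts$u_l4)
  # L4 normally encodes the delayed input; under the delay knockout, x_t
  x_l4 <- if (is.null(acts$x_l4)) acts$x_prev else acts$x_l4
  list(W_thal_l4 = -eta * (d4 %*% t(x_l4)),
       W_td_l23 = -eta * (d23 %*% t(acts$i_td)),
       W_decoder = -eta * lambda_r * ((acts$xhat - acts$x_t) %*% t(acts$z_l5)))
}

#' All weight updates for one timestep
#'
#' Collects the manually specified learning rules into one gradient set;
#' convenience wrapper used by the reference (R-side) training step and the
#' tests that pin the compiled trainer to it.
#'
#' @inheritParams grad_w_thal_l5
#' @param flags a [knockout_flags()]; knocked-out pathways yield zero
#'   updates for their weights. Knocking out the L2/3-to-L5 connection
#'   disables the self-supervised cost altogether (no predictive updates to
#'   any weight), matching how the ablation is defined for the robustness
#'   experiments.
#' @param fb optional explicit feedback matrix.
#' @return List of class `gradient_set` with one update matrix per trainable
#'   weight, named as in [microcircuit_weights()].
#' @export
gradient_set <- function(acts, weights, lambda_p = 1, lambda_r = 1, eta = 1,
                         flags = knockout_flags(), literal = FALSE,
                         fb = NULL) {
  if (flags$ko_l23_l5) lambda_p <- 0
  up <- grad_upstream(acts, weights, lambda_p, lambda_r, eta, fb)
  g <- list(
    W_thal_l4 = up$W_thal_l4,
    W_l4_l23 = grad_w_l4_l23(acts, weights, lambda_p, eta, fb),
    W_td_l23 = up$W_td_l23,
    W_l23_l5 = grad_w_l23_l5(acts, weights, lambda_p, eta),
    W_thal_l5 = grad_w_thal_l5(acts, weights, lambda_p, lambda_r, eta, literal),
    W_decoder = up$W_decoder)
  zero <- function(W) W * 0
  if (flags$ko_l23_l5) g$W_l23_l5 <- zero(g$W_l23_l5)
  if (flags$ko_thal_l5) g$W_thal_l5 <- zero(g$W_thal_l5)
  if (flags$ko_l4_l23) {
    # no L4 -> L2/3 route: the error cannot reach W_l4_l23 or W_thal_l4
    g$W_l4_l23 <- zero(g$W_l4_l23)
    g$W_thal_l4 <- zero(g$W_thal_l4)
  }
  if (flags$ko_topdown) g$W_td_l23 <- zero(g$W_td_l23)
  structure(g, class = "gradient_set")
}
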