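#' Predictive (self-supervised) cost
#'
#' C_pred = 1/2 * sum_i (zhat^L5_i - z^L5_i)^2: half the squared distance
#' between the L2/3 prediction and the actual L5 activity, summed over L5
#' units.
#'
#' @param acts a `step_activations` object from [forward_step()].
#' @return Non-negative scalar.
#' @export
predictive_cost <- function(acts) {
  stopifnot(inherits(acts, "step_activations"))
  0.5 * sum((acts$zhat_l5 - acts$z_l5)^2)
}

#' Reconstruction cost
#'
#' C_recon = 1/2 * sum_j (x_t_j - xhat_j)^2: half the squared error of the
#' linear L5 readout against the thalamic input. This term regularizes L5
#' towards informative representations and prevents representational
#' collapse.
#'
#' @inheritParams predictive_cost
#' @return Non-negative scalar.
#' @export
reconstruction_cost <- function(acts) {
  stopifnot(inherits(acts, "step_activations"))
  0.5 * sum((acts$x_t - acts$xhat)^2)
}

#' Total cost and its components
#'
#' C_total = lambda_p * C_pred + lambda_r * C_recon.
#'
#' @inheritParams predictive_cost
#' @param lambda_p,lambda_r non-negative scales of the predictive and
#'   reconstruction components (default 1 each).
#' @return List of class `cost_breakdown` with fields `c_pred`, `c_recon`,
#'   `c_total`, `lambda_p`, `lambda_r`.
#' @export
cost_breakdown <- function(acts, lambda_p = 1, lambda_r = 1) {
  stopifnot(lambda_p >= 0, lambda_r >= 0)
  cp <- predictive_cost(acts)
  cr <- reconstruction_cost(acts)
  structure(list(c_pred = cp, c_recon = cr,
                 c_total = lambda_p * cp + lambda_r * cr,
                 lambda_p = lambda_p, lambda_r = lambda_r),
            class = "cost_breakdown")
}

#' L5 error signal (gradient of the total cost w.r.t. L5 activity)
#'
#' dC_total/dz^L5 = -lambda_p (zhat^L5 - z^L5) - lambda_r W_decoder^T
#' (x_t - xhat). This per-neuron gradient is the model's proxy for the L5
#' mismatch response (before baseline subtraction): when the L2/3 prediction
#' exceeds L5 activity the predictive term is negative, matching the
#' hyperpolarization of deep-layer neurons during sensorimotor mismatch.
#'
#' @inheritParams cost_breakdown
#' @param weights a [microcircuit_weights()] object.
#' @return Numeric vector of length n_l5.
#' @export
l5_error_signal <- function(acts, weights, lambda_p = 1, lambda_r = 1) {
  stopifnot(inherits(acts, "step_activations"),
            inherits(weights, "microcircuit_weights"))
  e <- acts$zhat_l5 - acts$z_l5
  -lambda_p * e - lambda_r * as.vector(t(weights$W_decoder) %*% (acts$x_t - acts$xhat))
}

#' L2/3 error signal (gradient of the cost w.r.t. L2/3 activity)
#'
#' Applies to the prediction error e = lambda_p (zhat^L5 - z^L5) the
#' transpose of \[W_l23_l5 - alpha * diag(sigmoid'(u^L5)) W_l23_l5\]: the
#' direct route through the prediction readout minus the indirect route
#' through the attenuated L5 drive. The reconstruction term is excluded by
#' construction — the circuit blocks reconstruction gradients from reaching
#' L2/3 (their contribution is negligible).
#'
#' @inheritParams l5_error_signal
#' @return Numeric vector of length n_l23.
#' @export
l23_error_signal <- function(acts, weights, lambda_p = 1, lambda_r = 1) {
  stopifnot(inherits(acts, "step_activations"),
            inherits(weights, "microcircuit_weights"))
  e <- lambda_p * (acts$zhat_l5 - acts$z_l5)
  sp5 <- dsigmoid_u(acts$u_l5)
  ## t(W - alpha diag(sp5) W) e  ==  t(W) ((1 - alpha*sp5) * e)
  as.vector(t(weights$W_l23_l5) %*% ((1 - weights$alpha * sp5) * e))
}
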