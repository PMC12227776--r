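#' L4 encoding of thalamic input
#'
#' Computes the granular-layer representation z^L4 = sigmoid(W_thal_l4 x).
#' In the temporal circuit this is the encoding of the *previous* input
#' x_{t-1}, which reaches L2/3 one step late.
#'
#' @param x input vector of length n_in.
#' @param weights a [microcircuit_weights()] object.
#' @return Activation vector of length n_l4 with entries in (0, 1).
#' @export
l4_encode <- function(x, weights) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  check_len(x, weights$dims[["n_in"]], "x")
  as.vector(sigmoid(weights$W_thal_l4 %*% x))
}

#' L2/3 integration of delayed L4 input and top-down context
#'
#' z^L2/3_t = sigmoid(W_l4_l23 z^L4 + W_td_l23 I^td_t). The caller controls
#' the delay convention: pass the L4 encoding of x_{t-1} for the intact
#' circuit, or of x_t under the delay knockout. `ko_topdown` zeroes the
#' context term; `ko_l4_l23` zeroes the L4 term.
#'
#' @param z_l4_prev L4 activation vector (length n_l4).
#' @param i_td top-down context vector (length n_td).
#' @param weights a [microcircuit_weights()] object.
#' @param flags a [knockout_flags()] object.
#' @return Activation vector of length n_l23.
#' @export
l23_integrate <- function(z_l4_prev, i_td, weights, flags = knockout_flags()) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  check_len(z_l4_prev, weights$dims[["n_l4"]], "z_l4_prev")
  check_len(i_td, weights$dims[["n_td"]], "i_td")
  drive <- 0
  if (!flags$ko_l4_l23) drive <- drive + weights$W_l4_l23 %*% z_l4_prev
  if (!flags$ko_topdown) drive <- drive + weights$W_td_l23 %*% i_td
  u <- drive + numeric(weights$dims[["n_l23"]])  # promote scalar 0 if both cut
  as.vector(sigmoid(u))
}

#' L5 integration of attenuated L2/3 drive and direct thalamic input
#'
#' u^L5_t = alpha W_l23_l5 z^L2/3_t + W_thal_l5 x_t and z^L5_t =
#' sigmoid(u^L5_t). Both the pre-activation (needed by the learning rules'
#' sigmoid-derivative terms) and the activation are returned. `ko_l23_l5`
#' zeroes the attenuated prediction drive; `ko_thal_l5` the thalamic drive.
#'
#' @param z_l23 L2/3 activation vector (length n_l23).
#' @param x_t current input vector (length n_in).
#' @param weights a [microcircuit_weights()] object.
#' @param flags a [knockout_flags()] object.
#' @return List with `u_l5` (pre-activation) and `z_l5` (activation), each of
#'   length n_l5.
#' @export
l5_integrate <- function(z_l23, x_t, weights, flags = knockout_flags()) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  check_len(z_l23, weights$dims[["n_l23"]], "z_l23")
  check_len(x_t, weights$dims[["n_in"]], "x_t")
  drive <- 0
  if (!flags$ko_l23_l5) drive <- drive + weights$alpha * (weights$W_l23_l5 %*% z_l23)
  if (!flags$ko_thal_l5) drive <- drive + weights$W_thal_l5 %*% x_t
  u <- as.vector(drive + numeric(weights$dims[["n_l5"]]))
  list(u_l5 = u, z_l5 = sigmoid(u))
}

#' L2/3 prediction of the L5 encoding
#'
#' The prediction vector zhat^L5_t = W_l23_l5 z^L2/3_t entering the
#' predictive cost. It is the raw matrix product: no attenuation and no
#' sigmoid, in contrast to the alpha-scaled drive inside the L5 dynamics.
#' This vector is what is meant by "the output of L2/3" in the decoding
#' analyses.
#'
#' @param z_l23 L2/3 activation vector.
#' @param weights a [microcircuit_weights()] object.
#' @return Numeric vector of length n_l5.
#' @export
predict_l5 <- function(z_l23, weights) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  check_len(z_l23, weights$dims[["n_l23"]], "z_l23")
  as.vector(weights$W_l23_l5 %*% z_l23)
}

#' L5 reconstruction of its thalamic input
#'
#' xhat_t = W_decoder z^L5_t, the linear readout whose squared error against
#' x_t forms the reconstruction cost.
#'
#' @param z_l5 L5 activation vector.
#' @param weights a [microcircuit_weights()] object.
#' @return Numeric vector of length n_in.
#' @export
reconstruct_input <- function(z_l5, weights) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  check_len(z_l5, weights$dims[["n_l5"]], "z_l5")
  as.vector(weights$W_decoder %*% z_l5)
}

#' One full timestep of the microcircuit
#'
#' Composes the layer dynamics with the one-step L4 delay: L4 encodes
#' x_{t-1} (or x_t under `ko_delay`), L2/3 integrates that encoding with the
#' top-down context, L5 integrates the attenuated L2/3 drive with the
#' current input x_t, and the prediction and reconstruction readouts are
#' attached. Deterministic: identical inputs and weights give identical
#' output.
#'
#' @param x_prev input vector at t-1.
#' @param x_t input vector at t.
#' @param i_td top-down context vector at t.
#' @param weights a [microcircuit_weights()] object.
#' @param flags a [knockout_flags()] object.
#' @return An object of class `step_activations`: a list with fields
#'   `x_prev`, `x_t`, `i_td`, `u_l4`, `z_l4`, `u_l23`, `z_l23`, `u_l5`,
#'   `z_l5`, `zhat_l5`, `xhat`.
#' @export
forward_step <- function(x_prev, x_t, i_td, weights,
                         flags = knockout_flags()) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  d <- weights$dims
  check_len(x_prev, d[["n_in"]], "x_prev")
  check_len(x_t, d[["n_in"]], "x_t")
  check_len(i_td, d[["n_td"]], "i_td")

  x_l4 <- if (flags$ko_delay) x_t else x_prev
  u_l4 <- as.vector(weights$W_thal_l4 %*% x_l4)
  z_l4 <- sigmoid(u_l4)

  itd_eff <- if (flags$ko_topdown) numeric(d[["n_td"]]) else i_td
  u_l23 <- as.vector(
    (if (flags$ko_l4_l23) numeric(d[["n_l23"]]) else weights$W_l4_l23 %*% z_l4) +
      weights$W_td_l23 %*% itd_eff)
  z_l23 <- sigmoid(u_l23)

  l5 <- l5_integrate(z_l23, x_t, weights, flags)

  acts <- list(x_prev = x_prev, x_t = x_t, i_td = i_td, x_l4 = x_l4,
               u_l4 = u_l4, z_l4 = z_l4,
               u_l23 = u_l23, z_l23 = z_l23,
               u_l5 = l5$u_l5, z_l5 = l5$z_l5,
               zhat_l5 = predict_l5(z_l23, weights),
               xhat = reconstruct_input(l5$z_l5, weights))
  structure(acts, class = "step_activations")
}

#' Batched forward pass over a training stream
#'
#' Runs the circuit over every timestep of a stream at once using
#' matrix-matrix products; used by the analysis battery where no learning
#' takes place. Row t of every output corresponds to row t of the stream.
#'
#' @param weights a [microcircuit_weights()] object.
#' @param stream a `training_stream` (see [as_training_stream()]).
#' @param flags a [knockout_flags()] object.
#' @return List of matrices (`z_l4`, `z_l23`, `u_l5`, `z_l5`, `zhat_l5`,
#'   `xhat`), each with one row per timestep.
#' @export
forward_sequence <- function(weights, stream, flags = knockout_flags()) {
  stopifnot(inherits(weights, "microcircuit_weights"),
            inherits(stream, "training_stream"))
  d <- weights$dims
  X_l4 <- if (flags$ko_delay) stream$x_t else stream$x_prev
  Z4 <- sigmoid(X_l4 %*% t(weights$W_thal_l4))
  TD <- if (flags$ko_topdown) 0 * stream$i_td else stream$i_td
  U23 <- (if (flags$ko_l4_l23) 0 else Z4 %*% t(weights$W_l4_l23)) +
    TD %*% t(weights$W_td_l23)
  if (!is.matrix(U23)) U23 <- matrix(U23, nrow(Z4), d[["n_l23"]])
  Z23 <- sigmoid(U23)
  Zhat <- Z23 %*% t(weights$W_l23_l5)
  U5 <- (if (flags$ko_l23_l5) 0 else weights$alpha * Zhat) +
    (if (flags$ko_thal_l5) 0 else stream$x_t %*% t(weights$W_thal_l5))
  if (!is.matrix(U5)) U5 <- matrix(U5, nrow(Z23), d[["n_l5"]])
  Z5 <- sigmoid(U5)
  list(z_l4 = Z4, z_l23 = Z23, u_l5 = U5, z_l5 = Z5, zhat_l5 = Zhat,
       xhat = Z5 %*% t(weights$W_decoder))
}
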