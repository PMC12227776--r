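## vectorized per-timestep error signals over a forward pass
## (rows = timesteps); mirrors l23_error_signal / l5_error_signal
error_signals_batch <- function(weights, stream, fwd, lambda_p = 1,
                                lambda_r = 1) {
  E <- fwd$zhat_l5 - fwd$z_l5
  SP5 <- fwd$z_l5 * (1 - fwd$z_l5)
  EF <- lambda_p * E * (1 - weights$alpha * SP5)
  list(me_l23 = EF %*% weights$W_l23_l5,
       me_l5 = -lambda_p * E -
         lambda_r * ((stream$x_t - fwd$xhat) %*% weights$W_decoder))
}

## baseline rows: non-mismatch steps with a safety margin around windows
baseline_rows <- function(mask, margin) {
  T_len <- length(mask)
  excl <- mask
  if (margin > 0) {
    for (k in seq_len(margin)) {
      excl <- excl | c(mask[-seq_len(k)], rep(FALSE, k)) |
        c(rep(FALSE, k), mask[seq_len(T_len - k)])
    }
  }
  !excl
}

make_mismatch_report <- function(ME, mm, bl, layer) {
  me_mm <- colMeans(ME[mm, , drop = FALSE])
  me_bl <- colMeans(ME[bl, , drop = FALSE])
  me <- me_mm - me_bl
  structure(list(me_baseline = me_bl, me_mismatch = me_mm, me = me,
                 layer = layer,
                 sign_fractions = c(positive = mean(me > 0),
                                    negative = mean(me < 0))),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf(
    "<mismatch_report> %s: mean ME = %+.4g (%.0f%% positive, %.0f%% negative)\n",
    x$layer, mean(x$me), 100 * x$sign_fractions[["positive"]],
    100 * x$sign_fractions[["negative"]]))
  invisible(x)
}

#' Per-neuron mismatch errors with baseline subtraction
#'
#' Runs the (trained) circuit over a visuomotor stream and evaluates the
#' per-neuron cost gradients — the model's proxy for mismatch responses —
#' separately during mismatch windows and during baseline (non-mismatch)
#' steps, excluding a `margin` of steps around every window from the
#' baseline. Reports ME_i = <gradient>_mismatch - <gradient>_baseline per
#' neuron and layer; positive ME is the depolarization analogue.
#'
#' After closed-loop training, L2/3 (whose output predicts non-zero flow
#' from the sustained locomotion context while the flow is halted) shows
#' predominantly positive ME, and L5 (whose activity encodes the actual zero
#' flow while receiving the non-zero L2/3 prediction) predominantly
#' negative ME.
#'
#' @param weights a trained [microcircuit_weights()] object.
#' @param stream a `training_stream` built from a [visuomotor_stream()]
#'   containing mismatch windows.
#' @param lambda_p,lambda_r cost scales.
#' @param margin baseline exclusion margin in steps around each window.
#' @param flags a [knockout_flags()] applied at evaluation.
#' @return List of class `mismatch_reports` with elements `l23` and `l5`
#'   (each a `mismatch_report`).
#' @export
mismatch_errors <- function(weights, stream, lambda_p = 1, lambda_r = 1,
                            margin = 10, flags = knockout_flags()) {
  stopifnot(inherits(weights, "microcircuit_weights"),
            inherits(stream, "training_stream"))
  mm <- stream$mismatch
  if (is.null(mm) || !any(mm)) {
    stop("stream contains no mismatch windows", call. = FALSE)
  }
  bl <- baseline_rows(mm, margin)
  if (!any(bl)) stop("no baseline steps left after margin", call. = FALSE)
  fwd <- forward_sequence(weights, stream, flags)
  sig <- error_signals_batch(weights, stream, fwd, lambda_p, lambda_r)
  structure(list(l23 = make_mismatch_report(sig$me_l23, mm, bl, "L2/3"),
                 l5 = make_mismatch_report(sig$me_l5, mm, bl, "L5")),
            class = "mismatch_reports")
}

#' Correlation of mismatch errors with locomotion speed
#'
#' During flow-halt windows the L2/3 prediction tracks the top-down speed,
#' so the mismatch error should scale with the speed held during the halt.
#' Returns the per-mismatch-step population-mean error of each layer
#' together with the speed, and Pearson correlations of both the signed and
#' absolute L2/3 error with speed.
#'
#' @inheritParams mismatch_errors
#' @return List with `steps` (data.frame: speed, me_l23, me_l5) and
#'   `correlations` (named vector: signed_l23, abs_l23, signed_l5, abs_l5).
#' @export
me_speed_correlation <- function(weights, stream, lambda_p = 1, lambda_r = 1,
                                 flags = knockout_flags()) {
  mm <- stream$mismatch
  if (is.null(mm) || !any(mm)) {
    stop("stream contains no mismatch windows", call. = FALSE)
  }
  fwd <- forward_sequence(weights, stream, flags)
  sig <- error_signals_batch(weights, stream, fwd, lambda_p, lambda_r)
  steps <- data.frame(speed = stream$speed[mm],
                      me_l23 = rowMeans(sig$me_l23[mm, , drop = FALSE]),
                      me_l5 = rowMeans(sig$me_l5[mm, , drop = FALSE]))
  corrs <- c(signed_l23 = cor(steps$speed, steps$me_l23),
             abs_l23 = cor(steps$speed, abs(steps$me_l23)),
             signed_l5 = cor(steps$speed, steps$me_l5),
             abs_l5 = cor(steps$speed, abs(steps$me_l5)))
  list(steps = steps, correlations = corrs)
}

#' Simulated stimulation during mismatch windows
#'
#' Multiplies the activation vector of one layer by `gain` (>= 1) during
#' mismatch steps only — optionally restricted to the neurons whose baseline
#' mismatch error is positive or negative — propagates the scaled output
#' downstream, and recomputes the mismatch errors of the *other* layer.
#' Scaling all of L5 at high gain makes the fed-back L5 activity surpass the
#' L2/3 prediction, flipping the sign of L2/3 mismatch errors; scaling L2/3
#' amplifies its prediction and with it the magnitude of L5 mismatch errors.
#'
#' @inheritParams mismatch_errors
#' @param layer layer whose output is scaled, `"l5"` or `"l23"`.
#' @param gain multiplicative factor, >= 1 (protocol: stimulation only).
#' @param subset `"all"`, `"positive_me"` or `"negative_me"` — which neurons
#'   of the stimulated layer are scaled, classified by their baseline
#'   (unstimulated) mismatch error.
#' @return List of class `stimulation_result` with `before` and `after`
#'   `mismatch_report`s of the unstimulated layer, plus `layer`, `gain`,
#'   `subset`.
#' @export
stimulation_experiment <- function(weights, stream, layer = c("l5", "l23"),
                                   gain = 1, subset = c("all", "positive_me",
                                                        "negative_me"),
                                   lambda_p = 1, lambda_r = 1, margin = 10,
                                   flags = knockout_flags()) {
  layer <- match.arg(layer)
  subset <- match.arg(subset)
  if (gain < 1) stop("gain must be >= 1 (stimulation protocol)", call. = FALSE)
  mm <- stream$mismatch
  if (is.null(mm) || !any(mm)) {
    stop("stream contains no mismatch windows", call. = FALSE)
  }
  bl <- baseline_rows(mm, margin)
  base <- mismatch_errors(weights, stream, lambda_p, lambda_r, margin, flags)
  fwd <- forward_sequence(weights, stream, flags)

  stim_cols <- function(report) {
    switch(subset, all = seq_along(report$me),
           positive_me = which(report$me > 0),
           negative_me = which(report$me < 0))
  }

  if (layer == "l5") {
    cols <- stim_cols(base$l5)
    Z5s <- fwd$z_l5
    Z5s[mm, cols] <- gain * Z5s[mm, cols]
    ## L2/3 error with the scaled L5 output fed back; u_l5 (hence the
    ## sigmoid-derivative factor) is the unscaled somatic state
    E <- fwd$zhat_l5 - Z5s
    EF <- lambda_p * E * (1 - weights$alpha * fwd$z_l5 * (1 - fwd$z_l5))
    ME23 <- EF %*% weights$W_l23_l5
    after <- make_mismatch_report(ME23, mm, bl, "L2/3")
    before <- base$l23
  } else {
    cols <- stim_cols(base$l23)
    Z23s <- fwd$z_l23
    Z23s[mm, cols] <- gain * Z23s[mm, cols]
    Zhat_s <- Z23s %*% t(weights$W_l23_l5)
    U5s <- (if (flags$ko_l23_l5) 0 else weights$alpha * Zhat_s) +
      (if (flags$ko_thal_l5) 0 else stream$x_t %*% t(weights$W_thal_l5))
    Z5s <- sigmoid(U5s)
    Xhat_s <- Z5s %*% t(weights$W_decoder)
    ME5 <- -lambda_p * (Zhat_s - Z5s) -
      lambda_r * ((stream$x_t - Xhat_s) %*% weights$W_decoder)
    after <- make_mismatch_report(ME5, mm, bl, "L5")
    before <- base$l5
  }
  structure(list(before = before, after = after, layer = layer, gain = gain,
                 subset = subset),
            class = "stimulation_result")
}
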