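#' Reconstruction residuals under input corruption
#'
#' Corrupts a clean Gabor sequence at each level (additive Gaussian noise
#' scale, or occlusion patch size), runs the circuit on the corrupted
#' stream, and reports the mean squared residual between the L5
#' reconstruction and the *clean* current input. The L2/3 route — the
#' decoder applied to the L2/3 prediction zhat^L5 — is reported alongside,
#' since the prediction can fill in occluded or displaced evidence that the
#' feedforward L5 encoding cannot.
#'
#' @param weights a trained [microcircuit_weights()] object.
#' @param gseq a clean [gabor_sequence()].
#' @param corruption `"noise"` (levels = noise scales, 0 meaning clean) or
#'   `"occlusion"` (levels = patch sizes in pixels, 0 meaning clean).
#' @param levels numeric vector of corruption levels.
#' @param seed RNG seed for the corruption draws.
#' @param flags a [knockout_flags()] applied at evaluation.
#' @return data.frame with columns `level`, `mse_l5`, `mse_l23_route`.
#' @export
reconstruction_residual <- function(weights, gseq,
                                    corruption = c("noise", "occlusion"),
                                    levels = seq(0, 1, 0.2), seed = 1L,
                                    flags = knockout_flags()) {
  corruption <- match.arg(corruption)
  stopifnot(inherits(weights, "microcircuit_weights"),
            inherits(gseq, "gabor_sequence"))
  clean_stream <- as_training_stream(gseq)
  out <- lapply(seq_along(levels), function(i) {
    lv <- levels[i]
    frames <- if (lv == 0) gseq$frames else switch(corruption,
      noise = corrupt_noise(gseq$frames, lv, seed + i),
      occlusion = occlude(gseq$frames, as.integer(lv), seed + i)$frames)
    gc <- gseq
    gc$frames <- frames
    stream <- as_training_stream(gc)
    fwd <- forward_sequence(weights, stream, flags)
    data.frame(level = lv,
               mse_l5 = mean((fwd$xhat - clean_stream$x_t)^2),
               mse_l23_route = mean((fwd$zhat_l5 %*% t(weights$W_decoder) -
                                       clean_stream$x_t)^2))
  })
  do.call(rbind, out)
}

#' Denoising-autoencoder reference for the noise-robustness curve
#'
#' Trains a single-hidden-layer autoencoder (sigmoid hidden layer, linear
#' output) on corrupted-to-clean frame pairs across all noise levels — the
#' network is explicitly optimized for denoising, so its residual curve is a
#' near-optimal reference against which the microcircuit's emergent
#' denoising is compared. Deterministic under `seed`.
#'
#' @param frames T x pixels matrix of clean frames.
#' @param levels noise scales to train over and report.
#' @param seed RNG seed (initialization, minibatches, corruption draws).
#' @param n_hidden hidden-layer width.
#' @param epochs passes over the data.
#' @param batch_size minibatch size.
#' @param eta Adam learning rate.
#' @return List of class `dae_baseline`: `residuals` (data.frame `level`,
#'   `mse` on freshly corrupted data) and the trained `params`.
#' @export
denoising_autoencoder_baseline <- function(frames, levels = seq(0, 1, 0.2),
                                           seed = 1L, n_hidden = 128,
                                           epochs = 5, batch_size = 64,
                                           eta = 1e-3) {
  stopifnot(is.matrix(frames), nrow(frames) >= batch_size)
  n_in <- ncol(frames)
  with_local_seed(seed, {
    W1 <- matrix(rnorm(n_in * n_hidden, sd = 1 / sqrt(n_in)), n_in, n_hidden)
    b1 <- numeric(n_hidden)
    W2 <- matrix(rnorm(n_hidden * n_in, sd = 1 / sqrt(n_hidden)), n_hidden,
                 n_in)
    b2 <- numeric(n_in)
    adam <- lapply(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                   function(p) list(m = p * 0, v = p * 0))
    step_n <- 0
    upd <- function(p, g, nm) {
      st <- adam[[nm]]
      st$m <- 0.9 * st$m + 0.1 * g
      st$v <- 0.999 * st$v + 0.001 * g^2
      adam[[nm]] <<- st
      p - eta * (st$m / (1 - 0.9^step_n)) /
        (sqrt(st$v / (1 - 0.999^step_n)) + 1e-8)
    }
    T_len <- nrow(frames)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(T_len)
      for (b0 in seq(1, T_len - batch_size + 1, by = batch_size)) {
        idx <- ord[b0:(b0 + batch_size - 1)]
        lv <- sample(levels, 1)
        Xc <- frames[idx, , drop = FALSE] +
          lv * matrix(rnorm(batch_size * n_in), batch_size)
        Xt <- frames[idx, , drop = FALSE]
        H <- sigmoid(sweep(Xc %*% W1, 2, b1, `+`))
        Y <- sweep(H %*% W2, 2, b2, `+`)
        E <- (Y - Xt) / batch_size
        dH <- (E %*% t(W2)) * H * (1 - H)
        step_n <- step_n + 1
        W2 <- upd(W2, t(H) %*% E, "W2")
        b2 <- upd(b2, colSums(E), "b2")
        W1 <- upd(W1, t(Xc) %*% dH, "W1")
        b1 <- upd(b1, colSums(dH), "b1")
      }
    }
    predict_dae <- function(X) {
      sweep(sigmoid(sweep(X %*% W1, 2, b1, `+`)) %*% W2, 2, b2, `+`)
    }
    res <- vapply(seq_along(levels), function(i) {
      lv <- levels[i]
      Xc <- if (lv == 0) frames else
        frames + lv * matrix(rnorm(length(frames)), T_len)
      mean((predict_dae(Xc) - frames)^2)
    }, numeric(1))
    structure(list(residuals = data.frame(level = levels, mse = res),
                   params = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)),
              class = "dae_baseline")
  })
}
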