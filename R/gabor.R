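#' Render a Gabor patch
#'
#' Oriented sinusoidal grating (phase 0) under an elliptical Gaussian
#' envelope, evaluated on a `size` x `size` pixel grid centred on the canvas
#' (plus an optional centre offset), then linearly rescaled to \[0, 1\].
#' Deterministic in its arguments. Orientations theta and theta + 180 render
#' identically (cosine grating, even envelope).
#'
#' @param theta orientation in degrees.
#' @param freq spatial frequency in cycles/pixel.
#' @param sigma_x,sigma_y envelope standard deviations in pixels (along and
#'   across the grating axis); must be positive.
#' @param size canvas side in pixels (default 28).
#' @param center_x,center_y centre offset in pixels from the canvas centre.
#' @return Numeric vector of length `size^2` (column-major pixels) in
#'   \[0, 1\].
#' @export
render_gabor <- function(theta, freq, sigma_x, sigma_y, size = 28,
                         center_x = 0, center_y = 0) {
  if (!is.finite(theta) || !is.finite(freq)) {
    stop("theta and freq must be finite", call. = FALSE)
  }
  if (sigma_x <= 0 || sigma_y <= 0) {
    stop("envelope sigmas must be positive", call. = FALSE)
  }
  half <- (size - 1) / 2
  px <- seq_len(size) - 1 - half
  x <- matrix(px, size, size) - center_x          # varies down columns
  y <- matrix(px, size, size, byrow = TRUE) - center_y
  th <- theta * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  g <- cos(2 * pi * freq * u) *
    exp(-(u^2 / (2 * sigma_x^2) + v^2 / (2 * sigma_y^2)))
  rng <- range(g)
  if (rng[2] > rng[1]) g <- (g - rng[1]) / (rng[2] - rng[1]) else g[] <- 0.5
  as.vector(g)
}

#' Specification of the contextual Gabor task
#'
#' 28 x 28 Gabor patches whose orientation lives on an 18-degree grid of 10
#' classes and evolves under a three-valued top-down context (rotate -18,
#' stay, rotate +18 degrees). Patch frequency is drawn per frame from
#' N(`freq_mean`, `freq_sd`) truncated below at `freq_floor` (avoids
#' degenerate gratings; negligible tail mass), and envelope sigmas uniformly
#' from `envelope_range`.
#'
#' @param image_size canvas side in pixels.
#' @param freq_mean,freq_sd Gaussian frequency parameters (cycles/pixel).
#' @param freq_floor truncation floor for drawn frequencies.
#' @param envelope_range length-2 range of envelope sigmas in pixels.
#' @param n_theta number of orientation classes (grid spacing 180/n_theta).
#' @param seed RNG seed for sequence generation.
#' @return An object of class `gabor_task_spec`.
#' @export
gabor_task_spec <- function(image_size = 28, freq_mean = 0.2, freq_sd = 0.1,
                            freq_floor = 0.02, envelope_range = c(3, 8),
                            n_theta = 10, seed = 1L) {
  stopifnot(image_size >= 4, freq_sd >= 0, length(envelope_range) == 2,
            envelope_range[1] > 0, envelope_range[2] >= envelope_range[1],
            n_theta >= 2)
  structure(list(image_size = image_size, freq_mean = freq_mean,
                 freq_sd = freq_sd, freq_floor = freq_floor,
                 envelope_range = envelope_range, n_theta = n_theta,
                 theta_step = 180 / n_theta,
                 contexts = c(-1L, 0L, 1L) * as.integer(180 / n_theta),
                 seed = as.integer(seed)),
            class = "gabor_task_spec")
}

## contexts admissible at orientation class i (1-based): the boundary
## classes admit only two successors
admissible_contexts <- function(i, n_theta) {
  ctx <- 1:3  # 1 = -step, 2 = stay, 3 = +step
  if (i == 1L) ctx <- ctx[-1]
  if (i == n_theta) ctx <- ctx[ctx != 3L]
  ctx
}

## shared generator; shift_range > 0 additionally jitters the patch centre
generate_gabor <- function(spec, T_len, shift_range = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "gabor_task_spec"), T_len >= 2)
  half <- (spec$image_size - 1) / 2
  if (shift_range < 0 || shift_range > half) {
    stop("shift_range must keep the envelope centre on the canvas",
         call. = FALSE)
  }
  n_th <- spec$n_theta
  with_local_seed(seed, {
    ## orientation/context bookkeeping first (fixed draw order so that the
    ## shifted variant reproduces the same labels under the same seed)
    ori <- integer(T_len)
    ctx <- integer(T_len)
    ori[1] <- sample.int(n_th, 1L)
    for (t in seq_len(T_len - 1L)) {
      adm <- admissible_contexts(ori[t], n_th)
      ctx[t] <- if (length(adm) == 1L) adm else adm[sample.int(length(adm), 1L)]
      ori[t + 1L] <- ori[t] + (ctx[t] - 2L)
    }
    adm <- admissible_contexts(ori[T_len], n_th)
    ctx[T_len] <- if (length(adm) == 1L) adm else adm[sample.int(length(adm), 1L)]

    freqs <- pmax(rnorm(T_len, spec$freq_mean, spec$freq_sd), spec$freq_floor)
    sx <- runif(T_len, spec$envelope_range[1], spec$envelope_range[2])
    sy <- runif(T_len, spec$envelope_range[1], spec$envelope_range[2])
    shifts <- matrix(0, T_len, 2)
    if (shift_range > 0) {
      shifts[, 1] <- runif(T_len, -shift_range, shift_range)
      shifts[, 2] <- runif(T_len, -shift_range, shift_range)
    }

    frames <- matrix(0, T_len, spec$image_size^2)
    for (t in seq_len(T_len)) {
      frames[t, ] <- render_gabor((ori[t] - 1L) * spec$theta_step, freqs[t],
                                  sx[t], sy[t], spec$image_size,
                                  shifts[t, 1], shifts[t, 2])
    }
    structure(list(frames = frames, orientation_labels = ori,
                   context_labels = ctx, shifts = shifts, spec = spec,
                   seed = as.integer(seed)),
              class = "gabor_sequence")
  })
}

#' Generate a contextual Gabor sequence
#'
#' At every step the context label drawn at t (1 = rotate -18, 2 = stay,
#' 3 = rotate +18 degrees) determines the orientation class at t + 1; at the
#' boundary orientations (0 and 162 degrees) the context is drawn uniformly
#' from the two admissible values. Frequencies and envelopes are redrawn per
#' frame. Pure function of (spec, T, seed).
#'
#' @param spec a [gabor_task_spec()].
#' @param T_len sequence length (>= 2).
#' @param seed RNG seed (defaults to the spec's).
#' @return An object of class `gabor_sequence`: `frames` (T x pixels matrix
#'   in \[0, 1\]), `orientation_labels` (1-based class indices),
#'   `context_labels` (1..3).
#' @export
gabor_sequence <- function(spec, T_len, seed = spec$seed) {
  generate_gabor(spec, T_len, shift_range = 0, seed = seed)
}

#' Gabor sequence with random positional shifts
#'
#' Same transition rule as [gabor_sequence()] (identical labels under the
#' same seed), with the patch centre jittered uniformly within
#' `shift_range` pixels per axis and per frame.
#'
#' @inheritParams gabor_sequence
#' @param shift_range maximal centre offset in pixels (must keep the centre
#'   on the canvas).
#' @return A `gabor_sequence` whose `shifts` field holds the per-frame
#'   offsets.
#' @export
shift_position <- function(spec, T_len, shift_range, seed = spec$seed) {
  generate_gabor(spec, T_len, shift_range = shift_range, seed = seed)
}

#' Additive Gaussian input corruption
#'
#' x* = x + noise_level * eps with eps ~ N(0, I), applied independently per
#' frame and pixel. The input matrix is left untouched.
#'
#' @param frames T x pixels matrix.
#' @param noise_level non-negative noise scale.
#' @param seed RNG seed.
#' @return Corrupted copy of `frames`.
#' @export
corrupt_noise <- function(frames, noise_level, seed = 1L) {
  stopifnot(is.matrix(frames), noise_level >= 0)
  if (noise_level == 0) return(frames)
  with_local_seed(seed, frames + noise_level * matrix(rnorm(length(frames)),
                                                      nrow(frames)))
}

#' Occlude each frame with a dark square patch
#'
#' A `patch_size` x `patch_size` region, uniformly placed per frame, is set
#' to exactly zero. Pixels are assumed column-major on a square canvas.
#'
#' @param frames T x pixels matrix (pixels = size^2).
#' @param patch_size patch side in pixels; must fit inside the image.
#' @param seed RNG seed.
#' @return List with the corrupted `frames` and `coords`, a data.frame of
#'   per-frame top-left patch coordinates (row, col, 1-based).
#' @export
occlude <- function(frames, patch_size = 10, seed = 1L) {
  stopifnot(is.matrix(frames))
  size <- sqrt(ncol(frames))
  if (size != round(size)) stop("frames are not square images", call. = FALSE)
  size <- as.integer(size)
  if (patch_size > size) stop("patch larger than image", call. = FALSE)
  if (patch_size < 1) stop("patch_size must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    T_len <- nrow(frames)
    r0 <- sample.int(size - patch_size + 1L, T_len, replace = TRUE)
    c0 <- sample.int(size - patch_size + 1L, T_len, replace = TRUE)
    rows_in_patch <- seq_len(patch_size) - 1L
    for (t in seq_len(T_len)) {
      cols <- (c0[t] + rows_in_patch - 1L) * size
      idx <- as.vector(outer(r0[t] + rows_in_patch, cols, `+`))
      frames[t, idx] <- 0
    }
    list(frames = frames, coords = data.frame(row = r0, col = c0))
  })
}
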