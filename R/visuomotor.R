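#' Specification of the visuomotor task
#'
#' A locomotion-speed trace follows a random walk (steps -1/0/+1 with equal
#' probability, reflected into \[0, `s_max`\]) and drives a visual-flow
#' vector through the coupling f (identity or sine) plus Gaussian noise.
#' Visuomotor mismatches are contiguous windows of exactly `mismatch_len`
#' steps during which the flow is forced to zero while locomotion continues
#' (closed-loop mode). In open-loop mode the flow follows an independent
#' random walk, decoupled from the speed; there, a "mismatch" window is a
#' flow onset after a forced zero-flow stretch of the same length — the
#' probe under which mismatch errors invert.
#'
#' @param n_dims flow dimensionality (default 10).
#' @param coupling `"linear"` (f(s) = s) or `"sine"` (f(s) = sin(s)).
#' @param noise_sd standard deviation of the additive flow noise (default 1,
#'   i.e. standard Gaussian).
#' @param walk_step magnitude of a speed increment (default 1).
#' @param s_max reflection ceiling of the speed walk; speed is a locomotion
#'   magnitude, reflected at 0 and capped so that the sigmoid circuit
#'   operates in range.
#' @param mismatch_len window length k in timesteps (default 600).
#' @param mismatch_rate per-step probability of starting a mismatch window
#'   (windows are non-overlapping with at least `mismatch_len` baseline gap
#'   between them).
#' @param loop_mode `"closed"` or `"open"`.
#' @param seed RNG seed.
#' @return An object of class `visuomotor_spec`.
#' @export
visuomotor_spec <- function(n_dims = 10, coupling = c("linear", "sine"),
                            noise_sd = 1, walk_step = 1, s_max = 6,
                            mismatch_len = 600, mismatch_rate = 0,
                            loop_mode = c("closed", "open"), seed = 1L) {
  coupling <- match.arg(coupling)
  loop_mode <- match.arg(loop_mode)
  stopifnot(n_dims >= 1, noise_sd >= 0, walk_step > 0, s_max > 0,
            mismatch_len >= 1, mismatch_rate >= 0, mismatch_rate <= 1)
  structure(list(n_dims = n_dims, coupling = coupling, noise_sd = noise_sd,
                 walk_step = walk_step, s_max = s_max,
                 mismatch_len = as.integer(mismatch_len),
                 mismatch_rate = mismatch_rate, loop_mode = loop_mode,
                 seed = as.integer(seed)),
            class = "visuomotor_spec")
}

## random-walk speed trace reflected into [0, s_max]
speed_walk <- function(T_len, walk_step, s_max, s0 = 0) {
  incr <- sample(c(-1, 0, 1), T_len, replace = TRUE) * walk_step
  s <- numeric(T_len)
  cur <- s0
  for (t in seq_len(T_len)) {
    cur <- cur + incr[t]
    if (cur < 0) cur <- -cur
    if (cur > s_max) cur <- 2 * s_max - cur
    s[t] <- cur
  }
  s
}

## non-overlapping window starts with >= len baseline gap between windows
draw_windows <- function(T_len, len, rate) {
  mask <- logical(T_len)
  if (rate <= 0) return(mask)
  u <- runif(T_len)
  next_allowed <- 1L
  t <- 1L
  while (t <= T_len - len + 1L) {
    if (t >= next_allowed && u[t] < rate) {
      mask[t:(t + len - 1L)] <- TRUE
      next_allowed <- t + 2L * len   # window plus a >= len clean gap
      t <- t + len
    } else {
      t <- t + 1L
    }
  }
  mask
}

#' Generate a visuomotor speed/flow stream
#'
#' See [visuomotor_spec()] for the generative model. Pure function of
#' (spec, T, seed): the same seed gives a bitwise-identical stream.
#'
#' @param spec a [visuomotor_spec()].
#' @param T_len stream length; must exceed the mismatch window length.
#' @param seed RNG seed (defaults to the spec's).
#' @return An object of class `visuomotor_stream`: `speed` (length T),
#'   `flow` (T x n_dims), `mismatch_mask` (logical T).
#' @export
visuomotor_stream <- function(spec, T_len, seed = spec$seed) {
  stopifnot(inherits(spec, "visuomotor_spec"), T_len > spec$mismatch_len)
  f <- switch(spec$coupling, linear = identity, sine = sin)
  with_local_seed(seed, {
    s <- speed_walk(T_len, spec$walk_step, spec$s_max)
    mask <- draw_windows(T_len, spec$mismatch_len, spec$mismatch_rate)
    noise <- if (spec$noise_sd > 0) {
      spec$noise_sd * matrix(rnorm(T_len * spec$n_dims), T_len)
    } else 0
    if (spec$loop_mode == "closed") {
      flow <- matrix(f(s), T_len, spec$n_dims) + noise
      flow[mask, ] <- 0        # coupling broken: flow halted exactly
    } else {
      ## open loop: flow driven by an independent walk, decoupled from speed
      s2 <- speed_walk(T_len, spec$walk_step, spec$s_max)
      flow <- matrix(f(s2), T_len, spec$n_dims) + noise
      if (any(mask)) {
        ## probe: force a zero-flow stretch of mismatch_len immediately
        ## before each window; the window itself is the (unexpected) onset
        starts <- which(mask & !c(FALSE, mask[-T_len]))
        for (st in starts) {
          pre <- max(1L, st - spec$mismatch_len):(st - 1L)
          if (st > 1L) flow[pre, ] <- 0
        }
      }
    }
    structure(list(speed = s, flow = flow, mismatch_mask = mask, spec = spec,
                   seed = as.integer(seed)),
              class = "visuomotor_stream")
  })
}
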