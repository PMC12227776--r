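#' Error-feedback pathway specification
#'
#' Describes how the learning error computed at L5 is carried back to L2/3.
#' Three modes are supported: `"symmetric"` (feedback weights mirror the
#' forward L2/3-to-L5 weights, i.e. their transpose, re-read at every use),
#' `"random"` (a fixed random matrix drawn once, as in feedback alignment),
#' and `"none"` (no error pathway; L2/3-upstream weights cannot learn).
#' Independently of the mode, individual feedback connections are retained
#' with probability `p_connectivity` (an elementwise Bernoulli mask drawn
#' once at `mask_seed` and fixed thereafter); forward connections are always
#' dense.
#'
#' @param mode one of `"symmetric"`, `"random"`, `"none"`.
#' @param p_connectivity probability in \[0, 1\] that a feedback connection
#'   is present.
#' @param mask_seed integer seed for the connectivity mask and, in random
#'   mode, the fixed feedback matrix.
#' @param random_scale standard-deviation multiplier for the random feedback
#'   matrix; the matrix is drawn N(0, (random_scale / sqrt(n_l5))^2), the
#'   same fan-in scaling used for forward initialization.
#' @return An object of class `feedback_spec`.
#' @export
feedback_spec <- function(mode = c("symmetric", "random", "none"),
                          p_connectivity = 1, mask_seed = 1L,
                          random_scale = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(p_connectivity) || length(p_connectivity) != 1 ||
      is.na(p_connectivity) || p_connectivity < 0 || p_connectivity > 1) {
    stop("p_connectivity must be a probability in [0, 1]", call. = FALSE)
  }
  if (random_scale <= 0) stop("random_scale must be positive", call. = FALSE)
  structure(list(mode = mode, p_connectivity = p_connectivity,
                 mask_seed = as.integer(mask_seed),
                 random_scale = random_scale),
            class = "feedback_spec")
}

#' Knockout switches for the microcircuit
#'
#' Each flag removes one circuit element; all `FALSE` is the intact model.
#'
#' @param ko_l23_l5 silence the attenuated L2/3-to-L5 drive and freeze its
#'   learning.
#' @param ko_thal_l5 remove the direct thalamic input to L5.
#' @param ko_topdown zero the top-down contextual input to L2/3.
#' @param ko_delay feed L2/3 the L4 encoding of the current input x_t instead
#'   of the delayed x_{t-1}.
#' @param ko_l4_l23 remove the L4-to-L2/3 drive.
#' @return An object of class `knockout_flags`.
#' @export
knockout_flags <- function(ko_l23_l5 = FALSE, ko_thal_l5 = FALSE,
                           ko_topdown = FALSE, ko_delay = FALSE,
                           ko_l4_l23 = FALSE) {
  flags <- list(ko_l23_l5 = isTRUE(ko_l23_l5), ko_thal_l5 = isTRUE(ko_thal_l5),
                ko_topdown = isTRUE(ko_topdown), ko_delay = isTRUE(ko_delay),
                ko_l4_l23 = isTRUE(ko_l4_l23))
  structure(flags, class = "knockout_flags")
}

#' Construct the trainable state of the three-layer microcircuit
#'
#' Holds all weight matrices of the L4/L2/3/L5 circuit, the
#' dendritic-to-somatic attenuation constant alpha that scales the
#' L2/3-to-L5 drive at the L5 soma, and the error-feedback configuration.
#' Weights are initialized zero-mean Gaussian with standard deviation
#' 1/sqrt(fan-in), which keeps the sigmoid units unsaturated at the start of
#' learning.
#'
#' @param n_in input (thalamic) dimensionality, e.g. 784 for 28x28 images.
#' @param n_l4,n_l23,n_l5 layer sizes (default 128 each).
#' @param n_td dimensionality of the top-down context vector (3 for the
#'   one-hot rotation cue of the Gabor task, 1 for locomotion speed).
#' @param alpha attenuation constant in (0, 1\]; default 0.3.
#' @param feedback a [feedback_spec()].
#' @param seed integer seed for the weight draw.
#' @return An object of class `microcircuit_weights`.
#' @export
microcircuit_weights <- function(n_in, n_l4 = 128, n_l23 = 128, n_l5 = 128,
                                 n_td = 3, alpha = 0.3,
                                 feedback = feedback_spec(), seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a strictly positive scalar", call. = FALSE)
  }
  stopifnot(inherits(feedback, "feedback_spec"))
  dims <- c(n_in = n_in, n_l4 = n_l4, n_l23 = n_l23, n_l5 = n_l5, n_td = n_td)
  if (any(dims < 1)) stop("all layer sizes must be >= 1", call. = FALSE)

  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  w <- with_local_seed(seed, {
    list(W_thal_l4 = init(n_l4, n_in),
         W_l4_l23  = init(n_l23, n_l4),
         W_td_l23  = init(n_l23, n_td),
         W_l23_l5  = init(n_l5, n_l23),
         W_thal_l5 = init(n_l5, n_in),
         W_decoder = init(n_in, n_l5))
  })
  w$alpha <- alpha
  w$feedback <- feedback
  ## fixed parts of the feedback pathway, drawn once at mask_seed
  fb <- with_local_seed(feedback$mask_seed, {
    list(random = matrix(rnorm(n_l23 * n_l5,
                               sd = feedback$random_scale / sqrt(n_l5)),
                         n_l23, n_l5),
         mask = matrix(rbinom(n_l23 * n_l5, 1L, feedback$p_connectivity),
                       n_l23, n_l5))
  })
  w$fb_random <- fb$random
  w$fb_mask <- fb$mask
  w$dims <- dims
  w$seed <- as.integer(seed)
  structure(w, class = "microcircuit_weights")
}

#' Realize the error-feedback matrix
#'
#' Returns the n_l23 x n_l5 matrix that carries the L5-side predictive error
#' back to L2/3, as configured by the weights' [feedback_spec()]. In symmetric
#' mode this is the transpose of the *current* forward L2/3-to-L5 weights
#' (never a stale copy); in random mode the fixed matrix drawn at
#' construction; in none mode all zeros. The fixed Bernoulli connectivity
#' mask is applied elementwise in every mode.
#'
#' @param weights a [microcircuit_weights()] object.
#' @return An n_l23 x n_l5 matrix.
#' @export
feedback_matrix <- function(weights) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  base <- switch(weights$feedback$mode,
                 symmetric = t(weights$W_l23_l5),
                 random = weights$fb_random,
                 none = matrix(0, weights$dims[["n_l23"]],
                               weights$dims[["n_l5"]]))
  base * weights$fb_mask
}

#' Build a feedback matrix from an explicit specification
#'
#' Convenience wrapper: applies `spec` to `weights` and returns the realized
#' feedback matrix. Useful for constructing a feedback pathway that differs
#' from the one stored in the weights (e.g. during sweeps over connection
#' probability).
#'
#' @param weights a [microcircuit_weights()] object.
#' @param spec a [feedback_spec()].
#' @return An n_l23 x n_l5 matrix.
#' @export
make_feedback <- function(weights, spec) {
  w2 <- set_feedback(weights, spec)
  feedback_matrix(w2)
}

#' Replace the feedback configuration of a weights object
#'
#' Redraws the fixed random feedback matrix and the connectivity mask at the
#' spec's `mask_seed`; forward weights are untouched.
#'
#' @inheritParams make_feedback
#' @return A `microcircuit_weights` object with the new feedback pathway.
#' @export
set_feedback <- function(weights, spec) {
  stopifnot(inherits(weights, "microcircuit_weights"),
            inherits(spec, "feedback_spec"))
  n_l23 <- weights$dims[["n_l23"]]
  n_l5 <- weights$dims[["n_l5"]]
  fb <- with_local_seed(spec$mask_seed, {
    list(random = matrix(rnorm(n_l23 * n_l5,
                               sd = spec$random_scale / sqrt(n_l5)),
                         n_l23, n_l5),
         mask = matrix(rbinom(n_l23 * n_l5, 1L, spec$p_connectivity),
                       n_l23, n_l5))
  })
  weights$feedback <- spec
  weights$fb_random <- fb$random
  weights$fb_mask <- fb$mask
  weights
}

#' @export
print.microcircuit_weights <- function(x, ...) {
  d <- x$dims
  cat("<microcircuit_weights>\n")
  cat(sprintf("  input %d | L4 %d | L2/3 %d | L5 %d | top-down %d\n",
              d[["n_in"]], d[["n_l4"]], d[["n_l23"]], d[["n_l5"]],
              d[["n_td"]]))
  cat(sprintf("  alpha = %g, feedback = %s (P_connectivity = %g)\n",
              x$alpha, x$feedback$mode, x$feedback$p_connectivity))
  invisible(x)
}

#' Serialize microcircuit weights
#'
#' Writes all weight matrices plus scalar attributes (alpha, feedback mode,
#' mask seed) to a single binary container; `read_weights()` restores a
#' bit-exact copy.
#'
#' @param weights a [microcircuit_weights()] object.
#' @param path file path.
#' @return `write_weights()` returns `path` invisibly; `read_weights()`
#'   returns the restored object.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "microcircuit_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  w <- readRDS(path)
  stopifnot(inherits(w, "microcircuit_weights"))
  w
}
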