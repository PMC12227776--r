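#' Build a training stream of (x_prev, x_t, i_td) triples
#'
#' The trainer and the batched forward pass consume streams: three row-aligned
#' matrices holding, for each timestep, the previous input, the current input
#' and the top-down context vector. `as_training_stream()` converts the task
#' generators' outputs:
#'
#' * For a [gabor_sequence()], row t pairs frame t-1 (delayed, seen by L4)
#'   with frame t (seen by L5) and the one-hot encoding of the context drawn
#'   at t-1 — the cue that generated the t-1 to t orientation transition, so
#'   L2/3 receives exactly the information needed to predict the incoming
#'   frame.
#' * For a [visuomotor_stream()], row t pairs flow at t-1 with flow at t and
#'   the current speed s_t as a one-dimensional context.
#'
#' @param x a task object.
#' @param ... unused.
#' @return An object of class `training_stream`: list of matrices `x_prev`,
#'   `x_t`, `i_td` (one row per step) plus task-specific label/mask vectors.
#' @export
as_training_stream <- function(x, ...) UseMethod("as_training_stream")

#' @rdname as_training_stream
#' @export
as_training_stream.gabor_sequence <- function(x, ...) {
  T_len <- nrow(x$frames)
  stopifnot(T_len >= 2)
  idx <- 2:T_len
  structure(list(
    x_prev = x$frames[idx - 1, , drop = FALSE],
    x_t = x$frames[idx, , drop = FALSE],
    i_td = one_hot(x$context_labels[idx - 1], 3L),
    orientation = x$orientation_labels[idx],
    orientation_prev = x$orientation_labels[idx - 1],
    context = x$context_labels[idx - 1]),
    class = "training_stream")
}

#' @rdname as_training_stream
#' @export
as_training_stream.visuomotor_stream <- function(x, ...) {
  T_len <- nrow(x$flow)
  stopifnot(T_len >= 2)
  idx <- 2:T_len
  structure(list(
    x_prev = x$flow[idx - 1, , drop = FALSE],
    x_t = x$flow[idx, , drop = FALSE],
    i_td = matrix(x$speed[idx], ncol = 1),
    speed = x$speed[idx],
    mismatch = x$mismatch_mask[idx]),
    class = "training_stream")
}

#' @rdname as_training_stream
#' @export
as_training_stream.default <- function(x, ...) {
  stopifnot(is.list(x), all(c("x_prev", "x_t", "i_td") %in% names(x)))
  stopifnot(nrow(x$x_prev) == nrow(x$x_t), nrow(x$x_t) == nrow(x$i_td))
  structure(x, class = "training_stream")
}

#' Training configuration
#'
#' Flat key-value configuration of one training run. `write_train_config()`
#' and `read_train_config()` serialize it as YAML so every run can persist
#' its resolved settings beside its outputs.
#'
#' @param lambda_p,lambda_r cost scales (default 1 each).
#' @param eta learning rate (default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param steps number of online updates; `NULL` uses the whole stream.
#' @param flags a [knockout_flags()] applied *during learning*.
#' @param literal_eq9 use the simplified thalamus-to-L5 rule without the
#'   sigmoid-derivative factor.
#' @return List of class `train_config`.
#' @export
train_config <- function(lambda_p = 1, lambda_r = 1, eta = 1e-3,
                         optimizer = c("adam", "sgd"), beta1 = 0.9,
                         beta2 = 0.999, adam_eps = 1e-8, steps = NULL,
                         flags = knockout_flags(), literal_eq9 = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(lambda_p >= 0, lambda_r >= 0, eta > 0,
            inherits(flags, "knockout_flags"))
  structure(list(lambda_p = lambda_p, lambda_r = lambda_r, eta = eta,
                 optimizer = optimizer, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, steps = steps, flags = flags,
                 literal_eq9 = isTRUE(literal_eq9)),
            class = "train_config")
}

#' @rdname train_config
#' @param config a `train_config`.
#' @param path file path for the YAML serialization.
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  out <- config
  out$flags <- unclass(out$flags)
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}

#' @rdname train_config
#' @export
read_train_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("lambda_p", "lambda_r", "eta", "optimizer", "beta1", "beta2",
             "adam_eps", "steps", "flags", "literal_eq9")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown train_config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  flags <- if (is.null(raw$flags)) knockout_flags() else
    do.call(knockout_flags, raw$flags)
  do.call(train_config, c(raw[setdiff(names(raw), "flags")],
                          list(flags = flags)))
}

#' Train the microcircuit online on a stream
#'
#' Runs one online update per stream element: forward pass, manually
#' specified weight updates with reconstruction-gradient blocking, optimizer
#' step. Deterministic given the initial weights and the stream. Training
#' aborts with a diagnostic if the cost diverges.
#'
#' @param weights a [microcircuit_weights()] object (initial state).
#' @param stream a `training_stream`.
#' @param config a [train_config()].
#' @return List of class `train_result`: `weights` (trained
#'   `microcircuit_weights`), `costs` (data.frame with per-step `c_pred`,
#'   `c_recon`, `c_total`), and the resolved `config`.
#' @export
train <- function(weights, stream, config = train_config()) {
  stopifnot(inherits(weights, "microcircuit_weights"),
            inherits(stream, "training_stream"),
            inherits(config, "train_config"))
  d <- weights$dims
  stopifnot(ncol(stream$x_t) == d[["n_in"]],
            ncol(stream$i_td) == d[["n_td"]])
  n_steps <- nrow(stream$x_t)
  if (!is.null(config$steps)) n_steps <- min(n_steps, config$steps)
  rows <- seq_len(n_steps)
  fb_mode <- match(weights$feedback$mode, c("symmetric", "random", "none")) - 1L
  use_mask <- weights$feedback$p_connectivity < 1
  fl <- config$flags

  res <- train_loop_cpp(
    weights$W_thal_l4, weights$W_l4_l23, weights$W_td_l23,
    weights$W_l23_l5, weights$W_thal_l5, weights$W_decoder,
    stream$x_prev[rows, , drop = FALSE], stream$x_t[rows, , drop = FALSE],
    stream$i_td[rows, , drop = FALSE], weights$alpha,
    config$lambda_p, config$lambda_r, config$eta,
    ifelse(config$optimizer == "adam", 1L, 0L),
    config$beta1, config$beta2, config$adam_eps,
    fb_mode, weights$fb_random, weights$fb_mask, use_mask,
    fl$ko_l23_l5, fl$ko_thal_l5, fl$ko_topdown, fl$ko_delay, fl$ko_l4_l23,
    config$literal_eq9)

  for (nm in c("W_thal_l4", "W_l4_l23", "W_td_l23", "W_l23_l5", "W_thal_l5",
               "W_decoder")) {
    weights[[nm]] <- res[[nm]]
  }
  costs <- data.frame(step = rows, c_pred = res$costs[, 1],
                      c_recon = res$costs[, 2])
  costs$c_total <- config$lambda_p * costs$c_pred +
    config$lambda_r * costs$c_recon
  structure(list(weights = weights, costs = costs, config = config),
            class = "train_result")
}

#' Reference R-side training step
#'
#' One online update computed entirely from the exported per-step operations
#' ([forward_step()], [gradient_set()]) with plain SGD. Used to pin the
#' compiled trainer to the documented learning rules.
#'
#' @inheritParams train
#' @param x_prev,x_t,i_td one stream element.
#' @return Updated `microcircuit_weights`.
#' @export
train_step_r <- function(weights, x_prev, x_t, i_td,
                         config = train_config(optimizer = "sgd")) {
  acts <- forward_step(x_prev, x_t, i_td, weights, config$flags)
  g <- gradient_set(acts, weights, config$lambda_p, config$lambda_r,
                    config$eta, config$flags, config$literal_eq9)
  for (nm in names(g)) weights[[nm]] <- weights[[nm]] + g[[nm]]
  weights
}

#' Plasticity curve of the L2/3-to-L5 learning rule
#'
#' Draws random pre/postsynaptic activity pairs, evaluates the L2/3-to-L5
#' weight update as a function of the postsynaptic L5 rate, and fits a line.
#' The positive slope is the depression-to-potentiation switch: for L5
#' activity below the L2/3 prediction the synapse depresses, above it it
#' potentiates — mirroring the switch observed with increasing postsynaptic
#' depolarization in sensory cortex.
#'
#' @param n_samples number of random samples (>= 10).
#' @param seed RNG seed.
#' @param eta learning rate scaling every update.
#' @param alpha attenuation constant.
#' @param lambda_p predictive cost scale.
#' @return List of class `plasticity_curve`: data.frame `samples` (columns
#'   `z_l5`, `update`) and scalar `slope` of the linear fit.
#' @export
plasticity_curve <- function(n_samples = 200, seed = 1L, eta = 1,
                             alpha = 0.3, lambda_p = 1) {
  stopifnot(n_samples >= 10)
  samples <- with_local_seed(seed, {
    z23 <- runif(n_samples, 0.05, 0.95)   # presynaptic L2/3 rate
    z5 <- runif(n_samples, 0.05, 0.95)    # postsynaptic L5 rate
    w <- rnorm(n_samples)                 # current synaptic weight
    zhat <- w * z23                       # the unit's share of the prediction
    u5 <- qlogis(z5)                      # pre-activation consistent with z5
    e <- zhat - z5
    upd <- -eta * lambda_p * e * (1 - alpha * dsigmoid_u(u5)) * z23
    data.frame(z_l5 = z5, update = upd)
  })
  fit <- lm(update ~ z_l5, data = samples)
  structure(list(samples = samples,
                 slope = unname(coef(fit)[["z_l5"]])),
            class = "plasticity_curve")
}
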