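#' Default configuration of the contextual Gabor experiments
#'
#' Resolved settings of one Gabor-task run: layer sizes, cost scales,
#' optimizer, training/evaluation lengths and the feedback pathway. Unknown
#' arguments are rejected (strict schema). Defaults are the desk-scale study
#' conditions: 128-unit layers, both cost scales 1, Adam at 1e-4, 30000
#' online training steps and a 4000-step evaluation sequence.
#'
#' @param n_l4,n_l23,n_l5 layer sizes.
#' @param alpha dendritic-to-somatic attenuation.
#' @param lambda_p,lambda_r cost scales.
#' @param eta learning rate.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param train_steps,eval_steps sequence lengths for learning / analysis.
#' @param image_size Gabor canvas side.
#' @param feedback_mode,p_connectivity feedback pathway settings.
#' @param decode_split train fraction of the decoder split.
#' @param n_seeds number of initial conditions aggregated by experiments.
#' @return List of class `experiment_config` (task `"gabor"`).
#' @export
gabor_config <- function(n_l4 = 128, n_l23 = 128, n_l5 = 128, alpha = 0.3,
                         lambda_p = 1, lambda_r = 1, eta = 1e-4,
                         optimizer = "adam", train_steps = 30000,
                         eval_steps = 4000, image_size = 28,
                         feedback_mode = "symmetric", p_connectivity = 1,
                         decode_split = 0.8, n_seeds = 5) {
  structure(list(task = "gabor", n_l4 = n_l4, n_l23 = n_l23, n_l5 = n_l5,
                 alpha = alpha, lambda_p = lambda_p, lambda_r = lambda_r,
                 eta = eta, optimizer = optimizer, train_steps = train_steps,
                 eval_steps = eval_steps, image_size = image_size,
                 feedback_mode = feedback_mode,
                 p_connectivity = p_connectivity, decode_split = decode_split,
                 n_seeds = n_seeds),
            class = "experiment_config")
}

#' Default configuration of the visuomotor experiments
#'
#' @inheritParams gabor_config
#' @param n_dims flow dimensionality.
#' @param coupling `"linear"` or `"sine"`.
#' @param noise_sd flow noise scale.
#' @param s_max speed-walk ceiling.
#' @param mismatch_len mismatch window length (timesteps).
#' @param eval_mismatch_rate per-step window start probability in the
#'   evaluation stream (training streams are fully coupled).
#' @return List of class `experiment_config` (task `"visuomotor"`).
#' @export
visuomotor_config <- function(n_l4 = 64, n_l23 = 64, n_l5 = 64, n_dims = 10,
                              coupling = "linear", noise_sd = 1, s_max = 6,
                              alpha = 0.3, lambda_p = 1, lambda_r = 1,
                              eta = 1e-4, optimizer = "adam",
                              train_steps = 50000, eval_steps = 20000,
                              mismatch_len = 600,
                              eval_mismatch_rate = 1 / 2000,
                              feedback_mode = "symmetric",
                              p_connectivity = 1, n_seeds = 5) {
  structure(list(task = "visuomotor", n_l4 = n_l4, n_l23 = n_l23,
                 n_l5 = n_l5, n_dims = n_dims, coupling = coupling,
                 noise_sd = noise_sd, s_max = s_max, alpha = alpha,
                 lambda_p = lambda_p, lambda_r = lambda_r, eta = eta,
                 optimizer = optimizer, train_steps = train_steps,
                 eval_steps = eval_steps,
                 mismatch_len = as.integer(mismatch_len),
                 eval_mismatch_rate = eval_mismatch_rate,
                 feedback_mode = feedback_mode,
                 p_connectivity = p_connectivity, n_seeds = n_seeds),
            class = "experiment_config")
}

## weights constructor shared by the experiment runners
config_weights <- function(config, seed, n_in, n_td) {
  microcircuit_weights(
    n_in = n_in, n_l4 = config$n_l4, n_l23 = config$n_l23,
    n_l5 = config$n_l5, n_td = n_td, alpha = config$alpha,
    feedback = feedback_spec(config$feedback_mode, config$p_connectivity,
                             mask_seed = seed),
    seed = seed)
}

config_train <- function(config, flags = knockout_flags()) {
  train_config(lambda_p = config$lambda_p, lambda_r = config$lambda_r,
               eta = config$eta, optimizer = config$optimizer, flags = flags)
}

#' Train one Gabor-task model
#'
#' Generates a contextual Gabor sequence at `seed`, initializes weights at
#' the same seed, and trains online. `noise_input = TRUE` replaces every
#' frame by per-frame min-max-normalized Gaussian noise (the no-sensory
#' control used for the sparseness analyses), keeping the context stream.
#'
#' @param seed integer seed of this initial condition.
#' @param config a [gabor_config()].
#' @param flags a [knockout_flags()] applied during learning.
#' @param noise_input replace frames by normalized Gaussian noise.
#' @return List of class `gabor_model`: trained `weights`, `costs`, `seed`,
#'   `config`, `flags`.
#' @export
train_gabor_model <- function(seed, config = gabor_config(),
                              flags = knockout_flags(),
                              noise_input = FALSE) {
  stopifnot(inherits(config, "experiment_config"), config$task == "gabor")
  spec <- gabor_task_spec(image_size = config$image_size, seed = seed)
  gseq <- gabor_sequence(spec, config$train_steps + 1L)
  if (noise_input) gseq <- noise_frames(gseq, seed)
  w <- config_weights(config, seed, config$image_size^2, 3L)
  tr <- train(w, as_training_stream(gseq), config_train(config, flags))
  structure(list(weights = tr$weights, costs = tr$costs, seed = seed,
                 config = config, flags = flags,
                 noise_input = isTRUE(noise_input)),
            class = "gabor_model")
}

## replace frames by per-frame min-max normalized white noise
noise_frames <- function(gseq, seed) {
  gseq$frames <- with_local_seed(seed + 777L, {
    f <- matrix(rnorm(length(gseq$frames)), nrow(gseq$frames))
    t(apply(f, 1, function(r) (r - min(r)) / (max(r) - min(r))))
  })
  gseq
}

#' Evaluate a Gabor-task model on a held-out sequence
#'
#' Generates a fresh sequence (seed offset from the model's), runs the
#' batched forward pass and returns the stream and activations for decoding
#' and sparseness analyses.
#'
#' @param model a [train_gabor_model()] result.
#' @param flags a [knockout_flags()] applied at evaluation (defaults to the
#'   flags the model was trained with).
#' @param eval_steps override the config's evaluation length.
#' @return List with `stream`, `fwd` (see [forward_sequence()]).
#' @export
eval_gabor_model <- function(model, flags = model$flags, eval_steps = NULL) {
  config <- model$config
  n_eval <- if (is.null(eval_steps)) config$eval_steps else eval_steps
  spec <- gabor_task_spec(image_size = config$image_size, seed = model$seed)
  gseq <- gabor_sequence(spec, n_eval + 1L, seed = model$seed + 100000L)
  if (isTRUE(model$noise_input)) gseq <- noise_frames(gseq, model$seed + 1L)
  stream <- as_training_stream(gseq)
  list(stream = stream, fwd = forward_sequence(model$weights, stream, flags))
}

#' Decode orientation from a layer's output
#'
#' @param fwd,stream a [eval_gabor_model()] result's fields.
#' @param layer `"l23"` (the prediction vector zhat^L5), `"l5"` (z^L5),
#'   `"l4"` (z^L4), or `"z23"` (raw L2/3 activations, for comparison).
#' @param target `"current"` (orientation of the input at t, the frame L2/3
#'   predicts and L5 encodes), `"past"` (orientation at t-1), or `"next"`
#'   (orientation at t+1 — the upcoming frame relative to the *current*
#'   input, the relevant prediction target under the delay knockout, where
#'   the whole network operates on x_t).
#' @inheritParams linear_decode
#' @return A `decode_result`.
#' @export
decode_layer <- function(fwd, stream, layer = c("l23", "l5", "l4", "z23"),
                         target = c("current", "past", "next"),
                         split_fraction = 0.8,
                         seed = 1L, method = "multinom", shuffle = FALSE) {
  layer <- match.arg(layer)
  target <- match.arg(target)
  features <- switch(layer, l23 = fwd$zhat_l5, l5 = fwd$z_l5, l4 = fwd$z_l4,
                     z23 = fwd$z_l23)
  if (target == "next") {
    T_len <- length(stream$orientation)
    features <- features[-T_len, , drop = FALSE]
    labels <- stream$orientation[-1]
    return(linear_decode(features, labels, split_fraction, seed, method,
                         shuffle = shuffle, target = target,
                         source_layer = layer))
  }
  labels <- switch(target, current = stream$orientation,
                   past = stream$orientation_prev)
  linear_decode(features, labels, split_fraction, seed, method,
                shuffle = shuffle, target = target, source_layer = layer)
}

#' Train one visuomotor model
#'
#' Closed-loop training couples flow to the locomotion speed (no mismatch
#' windows during learning); open-loop training draws the flow from an
#' independent walk. Mismatch windows are inserted only in evaluation
#' streams (see [eval_visuomotor_stream()]).
#'
#' @param seed integer seed.
#' @param config a [visuomotor_config()].
#' @param loop_mode `"closed"` or `"open"`.
#' @param flags a [knockout_flags()] applied during learning.
#' @return List of class `visuomotor_model`.
#' @export
train_visuomotor_model <- function(seed, config = visuomotor_config(),
                                   loop_mode = c("closed", "open"),
                                   flags = knockout_flags()) {
  stopifnot(inherits(config, "experiment_config"),
            config$task == "visuomotor")
  loop_mode <- match.arg(loop_mode)
  spec <- visuomotor_spec(n_dims = config$n_dims, coupling = config$coupling,
                          noise_sd = config$noise_sd, s_max = config$s_max,
                          mismatch_len = config$mismatch_len,
                          mismatch_rate = 0, loop_mode = loop_mode,
                          seed = seed)
  vm <- visuomotor_stream(spec, config$train_steps + 1L)
  w <- config_weights(config, seed, config$n_dims, 1L)
  tr <- train(w, as_training_stream(vm), config_train(config, flags))
  structure(list(weights = tr$weights, costs = tr$costs, seed = seed,
                 config = config, loop_mode = loop_mode, flags = flags),
            class = "visuomotor_model")
}

#' Evaluation stream with mismatch windows for a visuomotor model
#'
#' @param model a [train_visuomotor_model()] result.
#' @param loop_mode override the model's training mode for the probe.
#' @return A `training_stream` with `mismatch` annotations.
#' @export
eval_visuomotor_stream <- function(model, loop_mode = model$loop_mode) {
  config <- model$config
  spec <- visuomotor_spec(n_dims = config$n_dims, coupling = config$coupling,
                          noise_sd = config$noise_sd, s_max = config$s_max,
                          mismatch_len = config$mismatch_len,
                          mismatch_rate = config$eval_mismatch_rate,
                          loop_mode = loop_mode, seed = model$seed + 100000L)
  as_training_stream(visuomotor_stream(spec, config$eval_steps))
}

## ---------------------------------------------------------------------------
## named experiments

exp_gabor_prediction <- function(config, seeds) {
  do.call(rbind, lapply(seeds, function(s) {
    model <- train_gabor_model(s, config)
    ev <- eval_gabor_model(model)
    acc23 <- decode_layer(ev$fwd, ev$stream, "l23", "current",
                          config$decode_split, seed = s)
    acc5 <- decode_layer(ev$fwd, ev$stream, "l5", "current",
                         config$decode_split, seed = s)
    chance <- decode_layer(ev$fwd, ev$stream, "l5", "current",
                           config$decode_split, seed = s, shuffle = TRUE)
    data.frame(seed = s, acc_l23_next = acc23$accuracy,
               acc_l5_current = acc5$accuracy, chance = chance$accuracy)
  }))
}

exp_collapse_check <- function(config, seeds) {
  do.call(rbind, lapply(seeds, function(s) {
    cfg0 <- config
    cfg0$lambda_r <- 0
    collapsed <- train_gabor_model(s, cfg0)
    intact <- train_gabor_model(s, config)
    evc <- eval_gabor_model(collapsed)
    evi <- eval_gabor_model(intact)
    v_c <- mean(apply(evc$fwd$z_l5, 2, var))
    v_i <- mean(apply(evi$fwd$z_l5, 2, var))
    data.frame(seed = s, var_collapsed = v_c, var_intact = v_i,
               var_ratio = v_c / v_i, collapsed = v_c < 0.01 * v_i)
  }))
}

#' Knockout registry of the ablation experiments
#' @return Named list of `(flags, feedback_mode)` settings.
#' @export
knockout_registry <- function() {
  list(intact = list(flags = knockout_flags(), feedback = NULL),
       ko_l23_l5 = list(flags = knockout_flags(ko_l23_l5 = TRUE),
                        feedback = NULL),
       ko_thal_l5 = list(flags = knockout_flags(ko_thal_l5 = TRUE),
                         feedback = NULL),
       ko_topdown = list(flags = knockout_flags(ko_topdown = TRUE),
                         feedback = NULL),
       ko_delay = list(flags = knockout_flags(ko_delay = TRUE),
                       feedback = NULL),
       ko_l4_l23 = list(flags = knockout_flags(ko_l4_l23 = TRUE),
                        feedback = NULL),
       feedback_none = list(flags = knockout_flags(), feedback = "none"),
       feedback_random = list(flags = knockout_flags(), feedback = "random"))
}

exp_ablation <- function(config, seeds, knockouts = names(knockout_registry())) {
  reg <- knockout_registry()[knockouts]
  out <- list()
  for (ko in names(reg)) {
    cfg <- config
    if (!is.null(reg[[ko]]$feedback)) cfg$feedback_mode <- reg[[ko]]$feedback
    for (s in seeds) {
      model <- train_gabor_model(s, cfg, flags = reg[[ko]]$flags)
      ev <- eval_gabor_model(model)
      for (layer in c("l23", "l5")) {
        for (target in c("current", "past")) {
          dr <- decode_layer(ev$fwd, ev$stream, layer, target,
                             cfg$decode_split, seed = s)
          ch <- decode_layer(ev$fwd, ev$stream, layer, target,
                             cfg$decode_split, seed = s, shuffle = TRUE)
          out[[length(out) + 1L]] <- data.frame(
            knockout = ko, seed = s, layer = layer, target = target,
            accuracy = dr$accuracy, chance = ch$accuracy)
        }
      }
    }
  }
  do.call(rbind, out)
}

exp_feedback_sweep <- function(config, seeds,
                               probabilities = c(0, 0.1, 0.25, 0.5, 1),
                               modes = c("symmetric", "random", "none")) {
  grid <- rbind(
    data.frame(mode = "symmetric", p = probabilities),
    data.frame(mode = setdiff(modes, "symmetric"), p = 1))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$feedback_mode <- grid$mode[i]
    cfg$p_connectivity <- grid$p[i]
    for (s in seeds) {
      model <- train_gabor_model(s, cfg)
      ev <- eval_gabor_model(model)
      acc23 <- decode_layer(ev$fwd, ev$stream, "l23", "current",
                            cfg$decode_split, seed = s)
      acc5 <- decode_layer(ev$fwd, ev$stream, "l5", "current",
                           cfg$decode_split, seed = s)
      out[[length(out) + 1L]] <- data.frame(
        mode = grid$mode[i], p_connectivity = grid$p[i], seed = s,
        acc_l23 = acc23$accuracy, acc_l5 = acc5$accuracy,
        n90_l23 = explained_variance_profile(ev$fwd$zhat_l5)$n90,
        n90_l5 = explained_variance_profile(ev$fwd$z_l5)$n90)
    }
  }
  do.call(rbind, out)
}

exp_sparsity <- function(config, seeds, sizes = NULL,
                         conditions = c("intact", "noise_input",
                                        "ko_topdown", "ko_thal_l5",
                                        "ko_l23_l5", "ko_delay")) {
  if (is.null(sizes)) sizes <- config$n_l23
  out <- list()
  for (size in sizes) {
    cfg <- config
    cfg$n_l4 <- cfg$n_l23 <- cfg$n_l5 <- size
    for (cond in conditions) {
      flags <- if (startsWith(cond, "ko_")) {
        do.call(knockout_flags, stats::setNames(list(TRUE), cond))
      } else knockout_flags()
      for (s in seeds) {
        model <- train_gabor_model(s, cfg, flags = flags,
                                   noise_input = cond == "noise_input")
        ev <- eval_gabor_model(model)
        acc23 <- decode_layer(ev$fwd, ev$stream, "l23", "current",
                              cfg$decode_split, seed = s)
        acc5 <- decode_layer(ev$fwd, ev$stream, "l5", "current",
                             cfg$decode_split, seed = s)
        out[[length(out) + 1L]] <- data.frame(
          size = size, condition = cond, seed = s,
          s_l4 = sparseness_trial(ev$fwd$z_l4)$s_mean,
          s_l23 = sparseness_trial(ev$fwd$z_l23)$s_mean,
          s_l5 = sparseness_trial(ev$fwd$z_l5)$s_mean,
          acc_l23 = acc23$accuracy, acc_l5 = acc5$accuracy)
      }
    }
  }
  do.call(rbind, out)
}

#' Sparseness-accuracy correlation over a size-and-seed sweep
#'
#' Pools intact runs over network sizes and seeds and reports the Pearson
#' correlation between each layer's population sparseness and its
#' current-input decoding accuracy (L2/3 positive, L5 negative in the
#' trained model).
#'
#' @param sweep data.frame from the sparsity experiment (intact rows used).
#' @return Named vector with `r_l23` and `r_l5`.
#' @export
sparsity_accuracy_correlation <- function(sweep) {
  sweep <- sweep[sweep$condition == "intact", ]
  c(r_l23 = cor(sweep$s_l23, sweep$acc_l23),
    r_l5 = cor(sweep$s_l5, sweep$acc_l5))
}

exp_mismatch <- function(config, seeds, gains = c(1, 2, 4, 8)) {
  closed <- list()
  open <- list()
  stim <- list()
  for (s in seeds) {
    model <- train_visuomotor_model(s, config, "closed")
    stream <- eval_visuomotor_stream(model)
    rep <- mismatch_errors(model$weights, stream, config$lambda_p,
                           config$lambda_r)
    sc <- me_speed_correlation(model$weights, stream, config$lambda_p,
                               config$lambda_r)
    closed[[length(closed) + 1L]] <- data.frame(
      seed = s, mean_me_l23 = mean(rep$l23$me), mean_me_l5 = mean(rep$l5$me),
      frac_pos_l23 = rep$l23$sign_fractions[["positive"]],
      frac_neg_l5 = rep$l5$sign_fractions[["negative"]],
      cor_speed_l23 = sc$correlations[["signed_l23"]])
    for (g in gains) {
      for (layer in c("l5", "l23")) {
        st <- stimulation_experiment(model$weights, stream, layer, g,
                                     "all", config$lambda_p, config$lambda_r)
        stim[[length(stim) + 1L]] <- data.frame(
          seed = s, layer = layer, gain = g,
          mean_me_before = mean(st$before$me),
          mean_me_after = mean(st$after$me),
          frac_pos_after = st$after$sign_fractions[["positive"]])
      }
    }
    omodel <- train_visuomotor_model(s, config, "open")
    ostream <- eval_visuomotor_stream(omodel)
    orep <- mismatch_errors(omodel$weights, ostream, config$lambda_p,
                            config$lambda_r)
    open[[length(open) + 1L]] <- data.frame(
      seed = s, mean_me_l23 = mean(orep$l23$me),
      mean_me_l5 = mean(orep$l5$me),
      frac_pos_l23 = orep$l23$sign_fractions[["positive"]],
      frac_neg_l5 = orep$l5$sign_fractions[["negative"]])
  }
  list(closed = do.call(rbind, closed), open = do.call(rbind, open),
       stimulation = do.call(rbind, stim))
}

## ---------------------------------------------------------------------------
## registry, runner, aggregation, report IO

experiment_registry <- function() {
  list(gabor_prediction = exp_gabor_prediction,
       collapse_check = exp_collapse_check,
       ablation = exp_ablation,
       feedback_sweep = exp_feedback_sweep,
       sparsity = exp_sparsity,
       mismatch = exp_mismatch)
}

#' Run a named experiment over several initial conditions
#'
#' Executes one registered experiment (train + evaluation per seed), returns
#' per-seed tables and seed aggregates (mean and standard error of the mean
#' over initial conditions), and optionally writes CSV tables plus a JSON
#' provenance sidecar. Reproducible bit-for-bit from (name, config, seeds).
#'
#' @param name one of `"gabor_prediction"`, `"collapse_check"`,
#'   `"ablation"`, `"feedback_sweep"`, `"sparsity"`, `"mismatch"`.
#' @param config an [gabor_config()] or [visuomotor_config()]; defaults to
#'   the task's standard configuration.
#' @param seeds integer seeds; defaults to `1:config$n_seeds`.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param ... passed on to the experiment function (e.g. `sizes`, `gains`).
#' @return List of class `experiment_report`: `name`, `per_seed`,
#'   `aggregate`, `config`, `seeds`.
#' @export
run_experiment <- function(name, config = NULL, seeds = NULL, out_dir = NULL,
                           ...) {
  reg <- experiment_registry()
  if (!name %in% names(reg)) {
    stop("unknown experiment '", name, "'; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  if (is.null(config)) {
    config <- if (name == "mismatch") visuomotor_config() else gabor_config()
  }
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(seeds)) seeds <- seq_len(config$n_seeds)
  per_seed <- reg[[name]](config, seeds, ...)
  aggregate <- if (is.data.frame(per_seed)) {
    aggregate_seeds(per_seed)
  } else {
    lapply(per_seed, aggregate_seeds)
  }
  report <- structure(list(name = name, per_seed = per_seed,
                           aggregate = aggregate, config = config,
                           seeds = seeds),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_experiment_report(report, out_dir)
  report
}

#' Mean and standard error over seeds
#'
#' Collapses the `seed` column of a per-seed table: numeric columns are
#' reported as mean and s.e.m. within every combination of the remaining
#' (non-numeric or grouping) columns.
#'
#' @param df per-seed data.frame with a `seed` column.
#' @return Aggregated data.frame.
#' @export
aggregate_seeds <- function(df) {
  stopifnot(is.data.frame(df), "seed" %in% names(df))
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "seed")
  grp_cols <- setdiff(names(df), c(num_cols, "seed"))
  sem <- function(x) sd(x) / sqrt(length(x))
  if (!length(grp_cols)) {
    means <- vapply(df[num_cols], mean, numeric(1))
    sems <- vapply(df[num_cols], sem, numeric(1))
    out <- data.frame(t(c(means, stats::setNames(sems,
                                                 paste0(num_cols, "_sem")))))
    out$n_seeds <- nrow(df)
    return(out)
  }
  agg_m <- stats::aggregate(df[num_cols], df[grp_cols], mean)
  agg_s <- stats::aggregate(df[num_cols], df[grp_cols], sem)
  names(agg_s)[match(num_cols, names(agg_s))] <- paste0(num_cols, "_sem")
  out <- merge(agg_m, agg_s, by = grp_cols, sort = FALSE)
  out$n_seeds <- length(unique(df$seed))
  out
}

#' Write an experiment report to disk
#'
#' CSV tables (per-seed and aggregate) plus a JSON sidecar carrying the
#' resolved configuration and seeds.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tbl <- function(x, stem) {
    if (is.data.frame(x)) {
      write.csv(x, file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    } else {
      for (nm in names(x)) write_tbl(x[[nm]], paste(stem, nm, sep = "_"))
    }
  }
  write_tbl(report$per_seed, paste0(report$name, "_per_seed"))
  write_tbl(report$aggregate, paste0(report$name, "_aggregate"))
  jsonlite::write_json(
    list(experiment = report$name, seeds = report$seeds,
         config = unclass(report$config)),
    file.path(dir, paste0(report$name, "_config.json")),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
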