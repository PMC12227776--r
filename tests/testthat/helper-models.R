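# Trained models shared across acceptance tests. Training is the expensive
# step, so models are built once per session and cached. The intact runs use
# the package's default study conditions (128-unit layers, 30k online steps)
# with a 2500-step held-out evaluation sequence; the qualitative knockout
# checks and the size sweep use the smaller desk-scale conditions documented
# in the methods vignette (decoding metrics plateau there).

.model_cache <- new.env(parent = emptyenv())

acc_gabor_config <- function(...) {
  gabor_config(eval_steps = 2500, ...)
}

small_gabor_config <- function(...) {
  gabor_config(n_l4 = 64, n_l23 = 64, n_l5 = 64, train_steps = 15000,
               eval_steps = 2000, ...)
}

acc_vm_config <- function() {
  visuomotor_config(eval_steps = 12000)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, expr, envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# the five intact initial conditions used by the decoding and sparseness
# acceptance checks
intact_gabor_runs <- function(seeds = 1:5) {
  cached("intact_gabor", {
    lapply(seeds, function(s) {
      model <- train_gabor_model(s, acc_gabor_config())
      ev <- eval_gabor_model(model)
      list(model = model, ev = ev, seed = s)
    })
  })
}

closed_vm_runs <- function(seeds = 1:5) {
  cached("closed_vm", {
    lapply(seeds, function(s) {
      model <- train_visuomotor_model(s, acc_vm_config(), "closed")
      list(model = model, stream = eval_visuomotor_stream(model), seed = s)
    })
  })
}

open_vm_runs <- function(seeds = 1:5) {
  cached("open_vm", {
    lapply(seeds, function(s) {
      model <- train_visuomotor_model(s, acc_vm_config(), "open")
      list(model = model, stream = eval_visuomotor_stream(model), seed = s)
    })
  })
}

# size-and-seed sweep behind the sparseness-accuracy coupling check:
# 12k training steps per run (decoding plateaus), three seeds per size
sparsity_sweep_runs <- function(sizes = c(16, 32, 64, 128), seeds = 1:3) {
  cached("sparsity_sweep", {
    out <- NULL
    for (size in sizes) {
      cfg <- gabor_config(n_l4 = size, n_l23 = size, n_l5 = size,
                          train_steps = 12000, eval_steps = 1500)
      for (s in seeds) {
        model <- train_gabor_model(s, cfg)
        ev <- eval_gabor_model(model)
        out <- rbind(out, data.frame(
          size = size, seed = s,
          acc_l23 = decode_layer(ev$fwd, ev$stream, "l23", "current",
                                 seed = s)$accuracy,
          acc_l5 = decode_layer(ev$fwd, ev$stream, "l5", "current",
                                seed = s)$accuracy,
          sp_l23 = sparseness_index(ev$fwd$z_l23),
          sp_l5 = sparseness_index(ev$fwd$z_l5)))
      }
    }
    out
  })
}

# normalized sparseness index (degree of sparseness): 1 at one-hot, 0 at
# uniform; monotone decreasing in the Treves-Rolls activity ratio S
sparseness_index <- function(activations) {
  s <- sparseness_trial(activations)
  (1 - s$s_mean) / (1 - 1 / s$n_neurons)
}
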