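#' Treves-Rolls population sparseness
#'
#' S = \[sum_i r_i / N\]^2 / sum_i \[r_i^2 / N\] for one stimulus, where r_i
#' are the non-negative activation rates of the N neurons. S lies in
#' (1/N, 1\]: S = 1 for perfectly uniform rates, S = 1/N for a one-hot
#' population (only one active neuron), and smaller values mean sparser
#' activity. S is invariant under rescaling of the rates. In this model the
#' rates are the sigmoid activations, non-negative by construction.
#'
#' @param rates non-negative numeric vector, not all zero.
#' @return Scalar S.
#' @export
population_sparseness <- function(rates) {
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(rates == 0)) stop("rates must not be all zero", call. = FALSE)
  mean(rates)^2 / mean(rates^2)
}

#' Trial-averaged population sparseness of a layer
#'
#' Applies [population_sparseness()] to every timestep (row) of an
#' activation matrix and averages over the trial.
#'
#' @param activations T x N matrix of non-negative rates.
#' @param layer optional layer label stored in the result.
#' @return An object of class `sparseness_result`: `s_per_stimulus` (length
#'   T), `s_mean`, `layer`, `n_neurons`.
#' @export
sparseness_trial <- function(activations, layer = NA_character_) {
  stopifnot(is.matrix(activations))
  s <- apply(activations, 1, population_sparseness)
  structure(list(s_per_stimulus = s, s_mean = mean(s), layer = layer,
                 n_neurons = ncol(activations)),
            class = "sparseness_result")
}

#' @export
print.sparseness_result <- function(x, ...) {
  cat(sprintf("<sparseness_result> %s: S = %.3f (N = %d, %d stimuli)\n",
              ifelse(is.na(x$layer), "?", x$layer), x$s_mean, x$n_neurons,
              length(x$s_per_stimulus)))
  invisible(x)
}
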