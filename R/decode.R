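#' Linear decoding of layer outputs
#'
#' Fits a linear classifier (multinomial logistic regression by default, or
#' a linear-kernel SVM as used for the occlusion analysis) on a stratified
#' train split of per-timestep layer outputs and reports held-out accuracy
#' and the confusion matrix. "Output of L2/3" in the decoding analyses means
#' the prediction vector zhat^L5 (W_l23_l5 z^L2/3); "output of L5" means
#' z^L5.
#'
#' @param features numeric matrix, one row per timestep.
#' @param labels vector of class labels (coerced to factor).
#' @param split_fraction fraction of each class used for training
#'   (default 0.8).
#' @param seed RNG seed for the stratified split.
#' @param method `"multinom"` or `"svm"`.
#' @param shuffle permute labels before splitting (empirical chance control).
#' @param target,source_layer optional annotations stored in the result.
#' @return An object of class `decode_result`: `accuracy`, `confusion`
#'   (rows = true class, columns = predicted, held-out counts), `n_train`,
#'   `n_test`, plus the annotations.
#' @export
linear_decode <- function(features, labels, split_fraction = 0.8, seed = 1L,
                          method = c("multinom", "svm"), shuffle = FALSE,
                          target = NA_character_,
                          source_layer = NA_character_) {
  method <- match.arg(method)
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            split_fraction > 0, split_fraction < 1)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes to decode", call. = FALSE)

  split <- with_local_seed(seed, {
    if (shuffle) y <- y[sample.int(length(y))]
    tr <- logical(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_tr <- max(1L, floor(split_fraction * length(idx)))
      tr[sample(idx, n_tr)] <- TRUE
    }
    tr
  })
  if (nlevels(droplevels(y[split])) < 2 || nlevels(droplevels(y[!split])) < 2) {
    stop("both splits must contain at least 2 classes", call. = FALSE)
  }

  if (method == "multinom") {
    df <- data.frame(y = y[split], features[split, , drop = FALSE])
    fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200,
                          MaxNWts = 1e6)
    newdf <- data.frame(features[!split, , drop = FALSE])
    names(newdf) <- names(df)[-1]
    pred <- predict(fit, newdata = newdf)
  } else {
    fit <- e1071::svm(x = features[split, , drop = FALSE], y = y[split],
                      kernel = "linear", scale = FALSE)
    pred <- predict(fit, features[!split, , drop = FALSE])
  }
  truth <- y[!split]
  confusion <- table(truth = truth, predicted = factor(pred,
                                                       levels = levels(y)))
  acc <- mean(pred == truth)
  structure(list(accuracy = acc, confusion = unclass(confusion),
                 n_train = sum(split), n_test = sum(!split),
                 method = method, shuffled = isTRUE(shuffle),
                 target = target, source_layer = source_layer),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> accuracy = %.3f (%d train / %d test, %s%s)\n",
              x$accuracy, x$n_train, x$n_test, x$method,
              if (x$shuffled) ", shuffled labels" else ""))
  invisible(x)
}

#' Cumulative explained-variance profile of a representation
#'
#' Principal-component decomposition of the mean-centred feature matrix;
#' returns the cumulative fraction of variance explained per component count
#' and the number of components needed to reach 90%. A (near) zero-variance
#' input is returned flagged as degenerate rather than an error.
#'
#' @param features numeric matrix, one row per sample (>= 2 rows).
#' @return An object of class `ev_profile`: `cum_var`, `n90`, `degenerate`.
#' @export
explained_variance_profile <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 2)
  centred <- scale(features, center = TRUE, scale = FALSE)
  total <- sum(centred^2)
  if (total < .Machine$double.eps * length(centred)) {
    return(structure(list(cum_var = rep(NA_real_, ncol(features)), n90 = NA,
                          degenerate = TRUE), class = "ev_profile"))
  }
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  cum_var <- cumsum(vars) / sum(vars)
  structure(list(cum_var = cum_var, n90 = which(cum_var >= 0.9)[1],
                 degenerate = FALSE),
            class = "ev_profile")
}
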