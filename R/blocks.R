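# Reference R implementations of the network building blocks. The fitted
# model runs the compiled equivalents; these functions document the exact
# arithmetic and serve block-level use and testing.

#' Gated residual block forward pass
#'
#' Transforms the values of a single input feature through its gated
#' residual block: a nonlinear ELU layer `f1 = ELU(W1 x + b1)`, dropout on
#' the nonlinear path, a linear unit `h = W2 f2 + b2`, a gate
#' `g = sigma(W3 f2 + b3)` (sigmoid or hard sigmoid), the residual mix
#' `z = g * h + (1 - g) * x_skip` with a learned skip projection of the
#' scalar input to the hidden width, and layer normalization of `z`
#' across the hidden units.
#'
#' @param x numeric vector: the values of one feature over samples.
#' @param block list with elements `W1`, `b1` (length-H vectors),
#'   `W2`, `W3` (H x H matrices), `b2`, `b3`, `skip`, `gain`, `bias`
#'   (length-H vectors).
#' @param gate `"sigmoid"` or `"hard_sigmoid"`.
#' @param elu_gamma ELU saturation constant.
#' @param training apply dropout (requires `dropout_mask`).
#' @param dropout_mask 0/1 matrix (samples x H) of kept units.
#' @param keep keep probability used for inverted dropout scaling.
#' @return samples x H matrix of normalized block outputs `zhat`.
#' @export
gr_block_forward <- function(x, block, gate = c("sigmoid", "hard_sigmoid"),
                             elu_gamma = 1, training = FALSE,
                             dropout_mask = NULL, keep = 1) {
  gate <- match.arg(gate)
  H <- length(block$W1)
  stopifnot(length(block$b1) == H, length(block$skip) == H,
            all(dim(block$W2) == c(H, H)), all(dim(block$W3) == c(H, H)))
  n <- length(x)
  out <- matrix(0, n, H)
  gfun <- if (gate == "sigmoid") function(a) 1 / (1 + exp(-a)) else hard_sigmoid
  for (i in seq_len(n)) {
    f1 <- elu(block$W1 * x[i] + block$b1, elu_gamma)
    f2 <- if (training) {
      if (is.null(dropout_mask)) stop("training mode requires 'dropout_mask'")
      f1 * dropout_mask[i, ] / keep
    } else f1
    h <- drop(block$W2 %*% f2) + block$b2
    g <- gfun(drop(block$W3 %*% f2) + block$b3)
    xs <- block$skip * x[i]
    z <- g * h + (1 - g) * xs
    out[i, ] <- layer_norm(z, block$gain, block$bias)
  }
  out
}

# layer normalization of a vector with learned gain/bias (eps matches the
# compiled core)
layer_norm <- function(z, gain = 1, bias = 0, eps = 1e-5) {
  mu <- mean(z)
  v <- mean((z - mu)^2)
  gain * (z - mu) / sqrt(v + eps) + bias
}

#' Variable selection block
#'
#' Applies the global softmax over per-feature scores and re-weights them:
#' `w_i = softmax(s)_i`, `z'_i = w_i * s_i`. Weights are non-negative, sum
#' to one and are invariant to adding a constant to all scores.
#'
#' @param scores numeric vector of per-feature scores, or a matrix with one
#'   row per sample.
#' @return list with `weights` and `reweighted`, shaped like the input.
#' @export
vs_block <- function(scores) {
  if (is.matrix(scores)) {
    if (any(!is.finite(scores))) stop("scores contain non-finite values")
    e <- exp(scores - apply(scores, 1, max))
    w <- e / rowSums(e)
    return(list(weights = w, reweighted = w * scores))
  }
  if (any(!is.finite(scores))) stop("scores contain non-finite values")
  w <- softmax(scores)
  list(weights = w, reweighted = w * scores)
}

#' Joint multi-task squared-error loss
#'
#' Mean of squared differences over all observed trait entries. The mean
#' (rather than sum) convention makes the loss scale invariant to batch
#' size; all traits are weighted equally. Entries with `NA` in `y` are
#' excluded from the mean.
#'
#' @param y observed responses (vector or samples x traits matrix).
#' @param yhat predictions, same shape.
#' @return non-negative scalar.
#' @export
multitask_loss <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("y and yhat must have identical shape")
  m <- is.finite(y)
  if (!any(m)) stop("no observed entries in y")
  mean((y[m] - yhat[m])^2)
}

#' Feature importance report
#'
#' Per-feature importance from the variable-selection block: the raw
#' importance of feature i is its softmax weight averaged over samples
#' (inference mode), which is non-negative and sums to one over features.
#' Because raw weights over thousands of features are O(1/P), selection
#' thresholds the max-rescaled relative importance
#' (`raw / max(raw)`, so the top feature scores exactly 1): a feature is
#' selected when its relative importance meets `threshold`.
#'
#' @param object a fitted `grvsnn`.
#' @param x feature matrix over which to average the softmax weights;
#'   defaults to the training data.
#' @param threshold selection threshold on relative importance (default
#'   0.05).
#' @return data.frame with columns `feature`, `category`, `raw_weight`,
#'   `relative_importance`, `selected`.
#' @export
importance <- function(object, x = NULL, threshold = 0.05) {
  stopifnot(inherits(object, "grvsnn"))
  raw <- if (is.null(x)) {
    if (is.null(object$importance_raw)) {
      if (is.null(object$x)) stop("untrained model: supply 'x'")
      colMeans(grvsnn_forward(object, object$x)$weights)
    } else object$importance_raw
  } else {
    if (nrow(as.matrix(x)) < 1L) stop("'x' must contain at least one sample")
    colMeans(grvsnn_forward(object, x)$weights)
  }
  rel <- raw / max(raw)
  data.frame(feature = object$feature_names,
             category = object$provenance,
             raw_weight = as.numeric(raw),
             relative_importance = as.numeric(rel),
             selected = as.numeric(rel) >= threshold,
             stringsAsFactors = FALSE)
}

#' Write an importance report to CSV
#'
#' @param imp data.frame from [importance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(imp, path) {
  atomic_write(path, function(f)
    utils::write.table(imp, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Save / load a fitted model
#'
#' Serializes the full parameter set, configuration and column provenance
#' to a single versioned checkpoint file.
#'
#' @param object a `grvsnn` object.
#' @param path checkpoint path.
#' @return `path` invisibly for `save_grvsnn`; the restored `grvsnn` object
#'   for `load_grvsnn`.
#' @export
save_grvsnn <- function(object, path) {
  stopifnot(inherits(object, "grvsnn"))
  saveRDS(list(format = "grvsnn-checkpoint", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname save_grvsnn
#' @export
load_grvsnn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "grvsnn-checkpoint")) {
    stop("not a grvsnn checkpoint file: ", path)
  }
  obj$model
}
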