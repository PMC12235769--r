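# Model fitting: parameter initialization, Adam loop with early stopping,
# and the S3 surface of the fitted model.

GATE_KINDS <- c(sigmoid = 0L, hard_sigmoid = 1L)

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# parameter matrices for P features, H hidden units, T traits
init_params <- function(P, H, T) {
  list(
    W1 = matrix(rnorm(P * H), P, H),
    b1 = matrix(0, P, H),
    W2 = matrix(rnorm(P * H * H, sd = 1 / sqrt(H)), P, H * H),
    b2 = matrix(0, P, H),
    W3 = matrix(rnorm(P * H * H, sd = 1 / sqrt(H)), P, H * H),
    b3 = matrix(0, P, H),
    skip = matrix(1, P, H),
    gain = matrix(1, P, H),
    bias = matrix(0, P, H),
    red = matrix(rnorm(P * H, sd = 1 / sqrt(H)), P, H),
    red_b = numeric(P),
    # the head reads P-scaled re-weighted features (unit order at uniform
    # softmax weights), so standard 1/sqrt(P) initialization applies
    Wout = matrix(rnorm(T * P, sd = 1 / sqrt(P)), T, P),
    bout = numeric(T)
  )
}

# parameters subject to weight decay (not biases or normalization terms)
DECAYED <- c("W1", "W2", "W3", "skip", "red", "red_b", "Wout")

masked_mse <- function(Y, Yhat, M) {
  sum(((Y - Yhat) * M)^2) / sum(M)
}

eval_loss <- function(params, X, Y, M, gate_kind, elu_gamma) {
  fw <- .cpp_grvsnn_forward(params, X, gate_kind, elu_gamma, FALSE)
  masked_mse(Y, fw$yhat, M)
}

#' Fit a gated residual variable selection network
#'
#' Trains a multi-task phenotype prediction network on a feature matrix
#' (marker dosages, pedigree loadings, or the joint input from
#' [assemble_features()]). Every feature is transformed by its own gated
#' residual block; a global softmax variable-selection layer re-weights the
#' per-feature scores, and a linear head maps them to the traits. The joint
#' mean squared error over all traits (missing entries excluded) is
#' minimised with mini-batch Adam plus weight decay; training stops early
#' when the validation loss has not improved for `patience` consecutive
#' epochs, and the parameters of the best validation epoch are kept.
#'
#' Features and responses are standardized to zero mean and unit variance
#' (statistics computed on the data passed here, i.e. the training fold)
#' unless `standardize = FALSE`. All randomness (initialization, batch
#' shuffling, dropout, validation split) is governed by `seed`; identical
#' calls reproduce identical loss traces.
#'
#' @param x numeric feature matrix, one row per individual.
#' @param y numeric response vector or matrix (one column per trait); `NA`
#'   entries are excluded from the loss.
#' @param provenance per-column category (`"marker"`/`"loading"`); taken
#'   from `x`'s provenance attribute by default.
#' @param hidden_width hidden units per gated residual block.
#' @param gate gate activation, `"hard_sigmoid"` (faster convergence,
#'   exact saturation) or `"sigmoid"`.
#' @param elu_gamma ELU saturation constant (> 0).
#' @param dropout_rate dropout probability on the block's nonlinear path.
#' @param learning_rate,batch_size,weight_decay Adam settings.
#' @param l2_gate optional L2 penalty on the nonlinear-layer and gate
#'   weights (W1, W3).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs.
#' @param validation fraction of rows carved out (seeded) as the inner
#'   validation set for early stopping, or a `list(x =, y =)` with explicit
#'   validation data; `0` disables early stopping.
#' @param standardize standardize features and responses internally.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param verbose print per-epoch losses.
#' @return an object of class `grvsnn` with components `params`, `config`,
#'   `scaler`, `trace` (per-epoch train/validation loss), `best_epoch`,
#'   `importance_raw` (mean softmax weight per feature) and the training
#'   data. Methods: [predict.grvsnn()], `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `plot`, plus [importance()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 8), 100, 8)
#' y <- x[, 1] - x[, 2] + rnorm(100, sd = 0.3)
#' fit <- grvsnn(x, y, hidden_width = 4, max_epochs = 30, seed = 1)
#' head(importance(fit))
#' @export
grvsnn <- function(x, y, provenance = NULL,
                   hidden_width = 8,
                   gate = c("hard_sigmoid", "sigmoid"),
                   elu_gamma = 1,
                   dropout_rate = 0.1,
                   learning_rate = 1e-3,
                   batch_size = 64,
                   weight_decay = 1e-2,
                   l2_gate = 0,
                   max_epochs = 500,
                   patience = 25,
                   validation = 0.2,
                   standardize = TRUE,
                   seed = 1L,
                   verbose = FALSE) {
  gate <- match.arg(gate)
  gate_kind <- GATE_KINDS[[gate]]
  if (elu_gamma <= 0) stop("'elu_gamma' must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)")
  if (patience < 1) stop("'patience' must be at least 1")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(provenance)) provenance <- feature_provenance(x)
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (nrow(x) < 2L) stop("need at least two samples")
  P <- ncol(x); T <- ncol(y)
  feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(P))
  trait_names <- colnames(y)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(T))

  scaler <- NULL
  xs <- x; ys <- y
  if (standardize) {
    scaler <- standardize_fit(x, y)
    std <- standardize_apply(scaler, x, y)
    xs <- std$x; ys <- std$y
  }
  M <- 1 * is.finite(ys)
  ys[!is.finite(ys)] <- 0

  fit <- with_seed(seed, {
    params <- init_params(P, hidden_width, T)
    # validation split
    if (is.list(validation)) {
      xv <- as.matrix(validation$x); yv <- as.matrix(validation$y)
      if (standardize) {
        stdv <- standardize_apply(scaler, xv, yv)
        xv <- stdv$x; yv <- stdv$y
      }
      Mv <- 1 * is.finite(yv); yv[!is.finite(yv)] <- 0
      tr_idx <- seq_len(nrow(xs))
    } else if (is.numeric(validation) && validation > 0) {
      nval <- max(1L, floor(validation * nrow(xs)))
      val_idx <- sample(nrow(xs), nval)
      tr_idx <- setdiff(seq_len(nrow(xs)), val_idx)
      xv <- xs[val_idx, , drop = FALSE]; yv <- ys[val_idx, , drop = FALSE]
      Mv <- M[val_idx, , drop = FALSE]
    } else {
      xv <- NULL; tr_idx <- seq_len(nrow(xs))
    }
    Xtr <- xs[tr_idx, , drop = FALSE]
    Ytr <- ys[tr_idx, , drop = FALSE]
    Mtr <- M[tr_idx, , drop = FALSE]
    ntr <- nrow(Xtr)

    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    step <- 0L
    keep <- 1 - dropout_rate
    use_dropout <- dropout_rate > 0
    dummy <- array(1, c(1, 1, 1))

    trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
    best <- params; best_loss <- Inf; best_epoch <- 0L; stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(ntr)
      nb <- ceiling(ntr / batch_size)
      epoch_loss <- 0; nseen <- 0
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1) * batch_size + 1):min(b * batch_size, ntr)]
        nbatch <- length(idx)
        dm <- if (use_dropout) {
          array(as.double(runif(P * hidden_width * nbatch) < keep),
                c(P, hidden_width, nbatch))
        } else dummy
        res <- .cpp_grvsnn_loss_grad(params, Xtr[idx, , drop = FALSE],
                                     Ytr[idx, , drop = FALSE],
                                     Mtr[idx, , drop = FALSE],
                                     dm, keep, gate_kind, elu_gamma,
                                     use_dropout, l2_gate)
        if (!is.finite(res$loss)) {
          stop("training loss is not finite at epoch ", epoch,
               "; try a lower learning rate")
        }
        epoch_loss <- epoch_loss + res$loss * nbatch
        nseen <- nseen + nbatch
        g <- res$grads
        step <- step + 1L
        bc1 <- 1 - b1a^step; bc2 <- 1 - b2a^step
        for (nm in names(params)) {
          gn <- g[[nm]]
          if (weight_decay > 0 && nm %in% DECAYED) gn <- gn + weight_decay * params[[nm]]
          mstate[[nm]] <- b1a * mstate[[nm]] + (1 - b1a) * gn
          vstate[[nm]] <- b2a * vstate[[nm]] + (1 - b2a) * gn^2
          params[[nm]] <- params[[nm]] -
            learning_rate * (mstate[[nm]] / bc1) / (sqrt(vstate[[nm]] / bc2) + eps)
        }
      }
      train_loss <- epoch_loss / nseen
      val_loss <- if (!is.null(xv)) {
        eval_loss(params, xv, yv, Mv, gate_kind, elu_gamma)
      } else train_loss
      if (!is.finite(val_loss)) {
        stop("validation loss is not finite at epoch ", epoch,
             "; try a lower learning rate")
      }
      trace <- rbind(trace, data.frame(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %d: train %.5f val %.5f", epoch, train_loss, val_loss))
      }
      if (val_loss < best_loss) {
        best_loss <- val_loss; best <- params; best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (!is.null(xv) && stall >= patience) break
      }
    }
    list(params = best, trace = trace, best_epoch = best_epoch,
         best_loss = best_loss)
  })

  object <- structure(list(
    params = fit$params,
    config = list(hidden_width = hidden_width, gate = gate,
                  elu_gamma = elu_gamma, dropout_rate = dropout_rate,
                  learning_rate = learning_rate, batch_size = batch_size,
                  weight_decay = weight_decay, l2_gate = l2_gate,
                  max_epochs = max_epochs, patience = patience,
                  validation = if (is.list(validation)) "external" else validation,
                  standardize = standardize, seed = seed),
    scaler = scaler,
    provenance = provenance,
    feature_names = feature_names,
    trait_names = trait_names,
    n_features = P,
    n_traits = T,
    trace = fit$trace,
    best_epoch = fit$best_epoch,
    best_val_loss = fit$best_loss,
    x = x, y = y,
    call = match.call()
  ), class = "grvsnn")
  object$importance_raw <- colMeans(grvsnn_forward(object, x)$weights)
  names(object$importance_raw) <- feature_names
  object
}

#' Untrained network with random initial parameters
#'
#' Constructs a `grvsnn` object without fitting, useful for inspecting the
#' architecture, forward-pass experiments and tests. Parameters can be
#' modified in place before calling [grvsnn_forward()].
#'
#' @param n_features,n_traits input and output dimensions.
#' @param hidden_width hidden units per gated residual block.
#' @param gate gate activation kind.
#' @param elu_gamma ELU saturation constant.
#' @param provenance optional per-feature category labels.
#' @param seed RNG seed for the random initialization.
#' @return an untrained object of class `grvsnn`.
#' @export
grvsnn_init <- function(n_features, hidden_width = 4, n_traits = 1,
                        gate = c("hard_sigmoid", "sigmoid"), elu_gamma = 1,
                        provenance = NULL, seed = NULL) {
  gate <- match.arg(gate)
  params <- with_seed(seed, init_params(n_features, hidden_width, n_traits))
  if (is.null(provenance)) provenance <- rep("marker", n_features)
  structure(list(
    params = params,
    config = list(hidden_width = hidden_width, gate = gate,
                  elu_gamma = elu_gamma, dropout_rate = 0,
                  standardize = FALSE),
    scaler = NULL,
    provenance = provenance,
    feature_names = paste0("f", seq_len(n_features)),
    trait_names = paste0("trait", seq_len(n_traits)),
    n_features = n_features,
    n_traits = n_traits,
    trace = NULL, best_epoch = 0L,
    call = match.call()
  ), class = "grvsnn")
}

#' Forward pass of a network
#'
#' Evaluates the network in inference mode (no dropout) and returns the
#' multi-task predictions together with the variable-selection softmax
#' weights, the per-feature scores and the re-weighted features; with
#' `intermediates = TRUE` also the layer-normalized gated residual block
#' outputs (`zhat`, a features x hidden x samples array).
#'
#' @param object a `grvsnn` object.
#' @param x feature matrix on the original scale (the model's scaler, if
#'   any, is applied) unless `standardized = TRUE`.
#' @param intermediates also return block-level outputs.
#' @param standardized `x` is already on the model's internal scale.
#' @return list with `yhat` (standardized scale), `weights`, `scores`,
#'   `reweighted` and optionally `zhat`.
#' @export
grvsnn_forward <- function(object, x, intermediates = FALSE, standardized = FALSE) {
  stopifnot(inherits(object, "grvsnn"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != object$n_features) {
    stop("x has ", ncol(x), " columns but the model expects ", object$n_features)
  }
  if (!standardized && !is.null(object$scaler)) {
    x <- standardize_apply(object$scaler, x)$x
  }
  fw <- .cpp_grvsnn_forward(object$params, x,
                            GATE_KINDS[[object$config$gate]],
                            object$config$elu_gamma, intermediates)
  fw
}

#' Predict phenotypes from a fitted network
#'
#' @param object a fitted `grvsnn`.
#' @param newx feature matrix with the same columns as the training input;
#'   defaults to the training data.
#' @param scale `"response"` returns predictions on the original trait
#'   scale; `"standardized"` on the internal zero-mean/unit-variance scale
#'   used for training and evaluation.
#' @param ... unused.
#' @return numeric matrix, one column per trait.
#' @export
predict.grvsnn <- function(object, newx = NULL, scale = c("response", "standardized"),
                           ...) {
  scale <- match.arg(scale)
  if (is.null(newx)) newx <- object$x
  yhat <- grvsnn_forward(object, newx)$yhat
  colnames(yhat) <- object$trait_names
  if (scale == "response" && !is.null(object$scaler)) {
    yhat <- sweep(sweep(yhat, 2, object$scaler$y_scale, "*"), 2,
                  object$scaler$y_center, "+")
  }
  yhat
}

#' @export
fitted.grvsnn <- function(object, ...) predict(object, object$x)

#' @export
residuals.grvsnn <- function(object, ...) object$y - fitted(object)

#' @export
coef.grvsnn <- function(object, ...) {
  out <- t(object$params$Wout)
  dimnames(out) <- list(object$feature_names, object$trait_names)
  rbind(`(Intercept)` = object$params$bout, out)
}

#' @export
print.grvsnn <- function(x, ...) {
  cat("Gated residual variable selection network\n")
  cat(sprintf("  features: %d (%s)\n", x$n_features,
              paste(sprintf("%d %s", table(x$provenance),
                            names(table(x$provenance))), collapse = ", ")))
  cat(sprintf("  traits: %d, hidden width: %d, gate: %s\n",
              x$n_traits, x$config$hidden_width, x$config$gate))
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat(sprintf("  trained %d epochs (best epoch %d, validation loss %.4f)\n",
                nrow(x$trace), x$best_epoch, x$best_val_loss))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.grvsnn <- function(object, threshold = 0.05, ...) {
  imp <- importance(object, threshold = threshold)
  sel <- imp[imp$selected, , drop = FALSE]
  res <- list(model = object, importance = imp,
              n_selected = nrow(sel),
              n_selected_by_category = table(sel$category),
              threshold = threshold)
  class(res) <- "summary.grvsnn"
  res
}

#' @export
print.summary.grvsnn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  selected features (relative importance >= %.2f): %d\n",
              x$threshold, x$n_selected))
  if (length(x$n_selected_by_category) > 1) {
    cat("   ", paste(sprintf("%s: %d", names(x$n_selected_by_category),
                             x$n_selected_by_category), collapse = ", "), "\n")
  }
  top <- head(x$importance[order(-x$importance$relative_importance), ], 10)
  cat("  top features:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
plot.grvsnn <- function(x, which = c("trace", "importance"), threshold = 0.05, ...) {
  which <- match.arg(which)
  if (which == "trace") {
    if (is.null(x$trace) || !nrow(x$trace)) stop("model has no training trace")
    rng <- range(c(x$trace$train_loss, x$trace$val_loss))
    graphics::plot(x$trace$epoch, x$trace$train_loss, type = "l", ylim = rng,
                   xlab = "epoch", ylab = "loss", ...)
    graphics::lines(x$trace$epoch, x$trace$val_loss, col = "red")
    graphics::abline(v = x$best_epoch, lty = 2)
    graphics::legend("topright", c("train", "validation"),
                     col = c("black", "red"), lty = 1, bty = "n")
  } else {
    imp <- importance(x, threshold = threshold)
    graphics::plot(imp$relative_importance, type = "h",
                   xlab = "feature", ylab = "relative importance", ...)
    graphics::abline(h = threshold, lty = 2, col = "red")
  }
  invisible(x)
}
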