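# Sequential model-based hyperparameter search: a compact tree-structured
# Parzen estimator (TPE) over the training configuration, with random
# startup draws and early termination when the incumbent stalls.

#' Hyperparameter search space
#'
#' Each dimension is either a `list(min =, max =, log =, integer =)`
#' continuous/integer range or a plain vector of candidate values
#' (categorical). The defaults are the tuned ranges of the training
#' protocol: batch size 64-512, learning rate 1e-5 to 1e-3 (log scale),
#' dropout rate 0.1-0.5 and hidden width over a small grid.
#'
#' @param learning_rate,batch_size,dropout_rate,hidden_width,weight_decay
#'   dimension specifications (see description).
#' @return named list usable as `space` in [tune_grvsnn()].
#' @export
tune_space <- function(learning_rate = list(min = 1e-5, max = 1e-3, log = TRUE),
                       batch_size = list(min = 64, max = 512, integer = TRUE),
                       dropout_rate = list(min = 0.1, max = 0.5),
                       hidden_width = c(4, 8, 16),
                       weight_decay = list(min = 1e-6, max = 1e-3, log = TRUE)) {
  list(learning_rate = learning_rate, batch_size = batch_size,
       dropout_rate = dropout_rate, hidden_width = hidden_width,
       weight_decay = weight_decay)
}

is_range <- function(dim) is.list(dim)

sample_dim <- function(dim) {
  if (!is_range(dim)) return(sample(dim, 1L))
  lo <- dim$min; hi <- dim$max
  v <- if (isTRUE(dim$log)) exp(runif(1, log(lo), log(hi))) else runif(1, lo, hi)
  if (isTRUE(dim$integer)) v <- as.integer(round(v))
  v
}

# gaussian KDE log-density at x given observations obs (1-D)
kde_logdens <- function(x, obs, lo, hi) {
  n <- length(obs)
  bw <- stats::sd(obs) * 1.06 * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 10
  log(mean(stats::dnorm(x, obs, bw)) + 1e-300)
}

#' Tune training hyperparameters with a tree-structured Parzen estimator
#'
#' Sequential model-based search: after a few random startup draws, the
#' evaluated configurations are split at the objective's lower quartile
#' into "good" and "bad" sets; new proposals are sampled from a kernel
#' density estimate of the good set and ranked by the good/bad density
#' ratio (per dimension, combined multiplicatively; categorical dimensions
#' use Laplace-smoothed frequencies). The search stops early when the best
#' objective value has not improved for `stall_patience` consecutive
#' proposals, and the incumbent configuration is returned.
#'
#' The default objective trains [grvsnn()] on `x`/`y` with the candidate
#' configuration and returns its best inner-validation loss. A custom
#' `objective(config)` can be supplied instead (then `x`/`y` are unused).
#'
#' @param x,y training data (standardized internally by [grvsnn()]).
#' @param space search space from [tune_space()].
#' @param budget maximum number of configurations to evaluate (>= 1).
#' @param stall_patience stop after this many consecutive non-improving
#'   evaluations (default 30).
#' @param objective optional function `config -> scalar` to minimise.
#' @param n_startup random draws before the TPE model is used.
#' @param seed RNG seed for the search.
#' @param verbose print per-evaluation progress.
#' @param ... fixed arguments passed on to [grvsnn()] by the default
#'   objective (e.g. `max_epochs`, `gate`).
#' @return list of class `grvsnn_tune`: `best_config`, `best_value`,
#'   `history` (one row per evaluation), `n_eval`.
#' @export
tune_grvsnn <- function(x = NULL, y = NULL, space = tune_space(), budget = 50,
                        stall_patience = 30, objective = NULL, n_startup = 10,
                        seed = 1L, verbose = FALSE, ...) {
  if (budget < 1) stop("'budget' must be at least 1")
  if (!length(space)) stop("empty search space")
  fixed <- list(...)
  if (is.null(objective)) {
    if (is.null(x) || is.null(y)) stop("supply x and y, or an 'objective' function")
    objective <- function(cfg) {
      fit <- do.call(grvsnn, c(list(x = x, y = y), cfg, fixed))
      fit$best_val_loss
    }
  }
  with_seed(seed, {
    history <- list()
    values <- numeric(0)
    best_value <- Inf; best_config <- NULL; stall <- 0L
    n_cand <- 24L
    for (it in seq_len(budget)) {
      if (it <= n_startup || length(values) < 4L) {
        cfg <- lapply(space, sample_dim)
      } else {
        q <- stats::quantile(values, 0.25, names = FALSE)
        good <- which(values <= q)
        bad <- setdiff(seq_along(values), good)
        if (!length(bad)) bad <- good
        cand <- vector("list", n_cand)
        score <- numeric(n_cand)
        for (ci in seq_len(n_cand)) {
          cfg_c <- list()
          lr <- 0
          for (nm in names(space)) {
            dim <- space[[nm]]
            obs <- vapply(history, function(h) as.numeric(h[[nm]]), 0)
            if (is_range(dim)) {
              tf <- if (isTRUE(dim$log)) log else identity
              itf <- if (isTRUE(dim$log)) exp else identity
              og <- tf(obs[good]); ob <- tf(obs[bad])
              lo <- tf(dim$min); hi <- tf(dim$max)
              bw <- stats::sd(og) * 1.06 * length(og)^(-1 / 5)
              if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 10
              v <- stats::rnorm(1, og[sample.int(length(og), 1)], bw)
              v <- min(max(v, lo), hi)
              lr <- lr + kde_logdens(v, og, lo, hi) - kde_logdens(v, ob, lo, hi)
              v <- min(max(itf(v), dim$min), dim$max)
              if (isTRUE(dim$integer)) v <- as.integer(round(v))
            } else {
              pg <- (tabulate(match(obs[good], dim), length(dim)) + 1)
              pb <- (tabulate(match(obs[bad], dim), length(dim)) + 1)
              pg <- pg / sum(pg); pb <- pb / sum(pb)
              k <- sample.int(length(dim), 1, prob = pg)
              lr <- lr + log(pg[k]) - log(pb[k])
              v <- dim[k]
            }
            cfg_c[[nm]] <- v
          }
          cand[[ci]] <- cfg_c
          score[ci] <- lr
        }
        cfg <- cand[[which.max(score)]]
      }
      val <- objective(cfg)
      history[[it]] <- c(cfg, list(value = val))
      values <- c(values, val)
      if (verbose) message(sprintf("eval %d: %.5f (best %.5f)", it, val,
                                   min(best_value, val)))
      if (val < best_value - 1e-12) {
        best_value <- val; best_config <- cfg; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= stall_patience) break
      }
    }
    hdf <- do.call(rbind, lapply(history, function(h)
      as.data.frame(h, stringsAsFactors = FALSE)))
    structure(list(best_config = best_config, best_value = best_value,
                   history = hdf, n_eval = length(values)),
              class = "grvsnn_tune")
  })
}

#' @export
print.grvsnn_tune <- function(x, ...) {
  cat(sprintf("TPE search: %d evaluations, best objective %.5f\n",
              x$n_eval, x$best_value))
  cat("best configuration:\n")
  for (nm in names(x$best_config)) {
    cat(sprintf("  %s = %s\n", nm, format(x$best_config[[nm]])))
  }
  invisible(x)
}
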