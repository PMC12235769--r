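# Standardization, stratified fold construction and repeated cross-validation.

#' Fit a standardization scaler
#'
#' Computes per-column means and sample standard deviations (n - 1
#' denominator) of features and, optionally, responses on the training data
#' only. Columns with zero variance are centered but not scaled (SD set to
#' 1, with a warning). `NA` entries are ignored in the statistics.
#'
#' @param x feature matrix (>= 2 rows).
#' @param y optional response vector/matrix.
#' @return an object of class `grvsnn_scaler`.
#' @export
standardize_fit <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two samples to standardize")
  col_stats <- function(m, what) {
    ctr <- colMeans(m, na.rm = TRUE)
    scl <- apply(m, 2, stats::sd, na.rm = TRUE)
    zero <- !is.finite(scl) | scl == 0
    if (any(zero)) {
      warning(sum(zero), " constant ", what,
              " column(s): centered but not scaled")
      scl[zero] <- 1
    }
    list(center = ctr, scale = scl)
  }
  xs <- col_stats(x, "feature")
  out <- list(x_center = xs$center, x_scale = xs$scale)
  if (!is.null(y)) {
    ys <- col_stats(as.matrix(y), "response")
    out$y_center <- ys$center
    out$y_scale <- ys$scale
  }
  structure(out, class = "grvsnn_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler object from [standardize_fit()].
#' @param x feature matrix.
#' @param y optional response vector/matrix.
#' @return list with standardized `x` and (if given) `y`.
#' @export
standardize_apply <- function(scaler, x, y = NULL) {
  stopifnot(inherits(scaler, "grvsnn_scaler"))
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, scaler$x_center, "-"), 2, scaler$x_scale, "/")
  out <- list(x = xs)
  if (!is.null(y)) {
    y <- as.matrix(y)
    out$y <- sweep(sweep(y, 2, scaler$y_center, "-"), 2, scaler$y_scale, "/")
  }
  out
}

#' Stratified k-fold assignment for a continuous response
#'
#' Partitions samples into `k` folds whose response distributions match the
#' full sample: the response is cut into quantile bins and samples are
#' dealt round-robin (after shuffling within bins) into folds. Fold sizes
#' differ by at most one and every sample lands in exactly one fold.
#'
#' @param y numeric response (a matrix uses its first column).
#' @param k number of folds.
#' @param bins number of quantile bins used for stratification.
#' @param seed RNG seed for the within-bin shuffles.
#' @return integer vector of fold labels in `1..k`.
#' @export
stratified_folds <- function(y, k = 5, bins = 10, seed = NULL) {
  y <- as.matrix(y)[, 1]
  n <- length(y)
  if (n < k) stop("need at least ", k, " samples for ", k, " folds")
  with_seed(seed, {
    bins <- max(1L, min(bins, floor(n / k)))
    # quantile bins on ranks (ties broken at random for exchangeability)
    r <- rank(y, ties.method = "random")
    bin <- ceiling(r * bins / n)
    k <- as.integer(k)
    fold <- integer(n)
    counter <- sample.int(k, 1L) - 1L   # random fold phase
    for (b in sort(unique(bin))) {
      idx <- which(bin == b)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- as.integer((counter + seq_along(idx) - 1L) %% k + 1L)
      counter <- counter + length(idx)
    }
    fold
  })
}

#' Cross-validation plan
#'
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats number of repeats with different random seeds
#'   (default 10, giving 50 runs).
#' @param seeds one seed per repeat; derived from `base_seed` when `NULL`.
#' @param base_seed integer used to derive per-repeat seeds.
#' @param stratify_bins quantile bins for stratification on the first trait.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5, n_repeats = 10, seeds = NULL,
                    base_seed = 1L, stratify_bins = 10) {
  if (is.null(seeds)) seeds <- base_seed * 1000L + seq_len(n_repeats)
  if (length(seeds) != n_repeats) stop("need one seed per repeat")
  structure(list(n_folds = n_folds, n_repeats = n_repeats, seeds = seeds,
                 stratify_bins = stratify_bins), class = "cv_plan")
}

#' Repeated stratified cross-validation of a network
#'
#' Runs the full evaluation protocol: for each repeat, samples are
#' partitioned into stratified folds (quantile bins on the first trait);
#' each fold serves once as the untouched test set while the model is
#' trained on the remaining folds (the scaler is fitted on the training
#' fold only, and an inner validation split carved from it drives early
#' stopping). Test predictions are scored per trait with MSE, Pearson r and
#' distance correlation on the standardized scale, and the number of
#' selected features (total and per provenance category) is recorded.
#'
#' @param x feature matrix (optionally with provenance from
#'   [assemble_features()]).
#' @param y response vector or matrix (one column per trait).
#' @param plan a [cv_plan()].
#' @param threshold relative-importance selection threshold.
#' @param verbose print per-fold progress.
#' @param ... training settings passed to [grvsnn()] (e.g. `hidden_width`,
#'   `learning_rate`, `max_epochs`).
#' @return object of class `grvsnn_cv`: `results` is a tidy data.frame with
#'   one row per repeat x fold x trait (`repeat_`, `fold`, `trait`, `mse`,
#'   `pearson_r`, `dcor`, `n_selected`, `n_selected_markers`,
#'   `n_selected_loadings`); `summary()` aggregates mean and SD over all
#'   runs.
#' @export
cv_grvsnn <- function(x, y, plan = cv_plan(), threshold = 0.05,
                      verbose = FALSE, ...) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (nrow(x) < plan$n_folds) stop("fewer samples than folds")
  prov <- feature_provenance(x)
  trait_names <- colnames(y)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(y)))
  rows <- list()
  folds_used <- list()
  for (r in seq_len(plan$n_repeats)) {
    seed_r <- plan$seeds[r]
    fold <- stratified_folds(y, k = plan$n_folds, bins = plan$stratify_bins,
                             seed = seed_r)
    folds_used[[r]] <- fold
    for (f in seq_len(plan$n_folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      fit <- grvsnn(x[train, , drop = FALSE], y[train, , drop = FALSE],
                    provenance = prov, seed = seed_r * 10L + f, ...)
      scaler <- fit$scaler
      yhat <- grvsnn_forward(fit, x[test, , drop = FALSE])$yhat
      ytest <- if (!is.null(scaler)) {
        standardize_apply(scaler, x[test, , drop = FALSE],
                          y[test, , drop = FALSE])$y
      } else y[test, , drop = FALSE]
      imp <- importance(fit, threshold = threshold)
      nsel <- sum(imp$selected)
      nsel_m <- sum(imp$selected & imp$category == "marker")
      nsel_l <- sum(imp$selected & imp$category == "loading")
      for (t in seq_len(ncol(y))) {
        ok <- is.finite(ytest[, t])
        mr <- metric_row(ytest[ok, t], yhat[ok, t])
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = r, fold = f, trait = trait_names[t],
          mse = mr[["mse"]], pearson_r = mr[["pearson_r"]],
          dcor = mr[["dcor"]], n_selected = nsel,
          n_selected_markers = nsel_m, n_selected_loadings = nsel_l,
          stringsAsFactors = FALSE)
      }
      if (verbose) {
        message(sprintf("repeat %d fold %d: test mse %s", r, f,
                        paste(sprintf("%.3f", rows[[length(rows)]]$mse),
                              collapse = " ")))
      }
    }
  }
  structure(list(results = do.call(rbind, rows), plan = plan,
                 folds = folds_used, threshold = threshold),
            class = "grvsnn_cv")
}

#' @export
print.grvsnn_cv <- function(x, ...) {
  cat(sprintf("grvsnn cross-validation: %d folds x %d repeats (%d runs)\n",
              x$plan$n_folds, x$plan$n_repeats,
              x$plan$n_folds * x$plan$n_repeats))
  print(summary(x))
  invisible(x)
}

#' Aggregate cross-validation results
#'
#' @param object a `grvsnn_cv` object.
#' @param ... unused.
#' @return data.frame with per-trait mean and SD (over all runs) of MSE,
#'   Pearson r, dCor and selected-feature counts, shaped like a published
#'   results table.
#' @export
summary.grvsnn_cv <- function(object, ...) {
  res <- object$results
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  out <- do.call(rbind, lapply(split(res, res$trait), function(d) {
    data.frame(trait = d$trait[1], n_runs = nrow(d),
               mse_mean = agg(d$mse)[1], mse_sd = agg(d$mse)[2],
               r_mean = agg(d$pearson_r)[1], r_sd = agg(d$pearson_r)[2],
               dcor_mean = agg(d$dcor)[1], dcor_sd = agg(d$dcor)[2],
               n_selected = mean(d$n_selected),
               n_selected_markers = mean(d$n_selected_markers),
               n_selected_loadings = mean(d$n_selected_loadings))
  }))
  rownames(out) <- NULL
  out
}

#' Write tidy cross-validation results to CSV
#'
#' @param cv a `grvsnn_cv` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_results <- function(cv, path) {
  atomic_write(path, function(f)
    utils::write.table(cv$results, f, sep = ",", quote = FALSE,
                       row.names = FALSE))
  invisible(path)
}
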