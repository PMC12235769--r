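#' Eigendecomposition of a relationship matrix
#'
#' Symmetric eigendecomposition `A = Q diag(lambda) Q'` with eigenvalues in
#' descending order. Eigenvector signs are fixed so that the
#' largest-magnitude entry of each eigenvector is positive, making the
#' decomposition deterministic across linear-algebra backends.
#'
#' @param A symmetric relationship matrix (e.g. from
#'   [pedigree_relationship()]).
#' @param sym_tol maximum allowed asymmetry `max|A - t(A)|`.
#' @return list with class `relationship_eigen`: `values` (descending),
#'   `vectors` (orthonormal columns), `ids` (rownames of `A`).
#' @export
relationship_eigen <- function(A, sym_tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("relationship matrix must be square")
  if (max(abs(A - t(A))) > sym_tol) stop("relationship matrix is not symmetric")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  # eigen() already sorts descending for symmetric input; fix signs
  Q <- e$vectors
  for (k in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, k]))
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  rownames(Q) <- ids
  structure(list(values = e$values, vectors = Q, ids = ids),
            class = "relationship_eigen")
}

#' Pedigree loadings from an eigendecomposition
#'
#' Computes the loadings `L = Q sqrt(Lambda)`, the square-root factor of the
#' relationship matrix: at full rank `L %*% t(L)` reproduces A. Columns are
#' ordered by descending eigenvalue and named `PC1..PCm`. Rows of L are
#' usable directly as per-individual input features.
#'
#' Tiny negative eigenvalues (floating-point noise on a PSD matrix) are
#' clamped to zero; negatives beyond `clamp_tol * max(values)` signal a
#' non-PSD matrix and raise an error.
#'
#' @param x a `relationship_eigen`, or a relationship matrix (which is then
#'   decomposed internally).
#' @param rank number of leading columns to keep; `NULL` selects the scree
#'   elbow via [select_rank()]; `Inf` or `nrow` keeps all.
#' @param clamp_tol relative tolerance for negative eigenvalues.
#' @return n x m loadings matrix with individual IDs as rownames and an
#'   attribute `eigenvalues` (the full descending spectrum).
#' @examples
#' A <- pedigree_relationship(data.frame(id = c("p", "q", "x"),
#'                                       sire = c(0, 0, "p"), dam = c(0, 0, "q")))
#' L <- pedigree_loadings(A, rank = 3)
#' max(abs(L %*% t(L) - A))
#' @export
pedigree_loadings <- function(x, rank = NULL, clamp_tol = 1e-8) {
  e <- if (inherits(x, "relationship_eigen")) x else relationship_eigen(x)
  lam <- e$values
  lmax <- max(lam, 0)
  if (any(lam < -clamp_tol * max(lmax, 1))) {
    stop("relationship matrix is not positive semi-definite ",
         "(eigenvalue ", format(min(lam)), ")")
  }
  lam <- pmax(lam, 0)
  n <- length(lam)
  m <- if (is.null(rank)) select_rank(lam) else min(as.integer(rank), n)
  if (m < 1L) stop("'rank' must be at least 1")
  L <- e$vectors[, seq_len(m), drop = FALSE] *
    rep(sqrt(lam[seq_len(m)]), each = nrow(e$vectors))
  dimnames(L) <- list(e$ids, paste0("PC", seq_len(m)))
  attr(L, "eigenvalues") <- e$values
  L
}

#' Scree elbow rank selection
#'
#' Chooses the reduced rank m at the elbow of the descending eigenvalue
#' scree curve, the point beyond which eigenvalues are no longer decreasing
#' appreciably. The elbow is the index with maximum perpendicular distance
#' to the chord joining the first and last scree points (Kneedle-style
#' criterion); ties take the smallest index. A degenerate scree with zero
#' chord distance everywhere (e.g. a constant spectrum) returns `length(values)`
#' with a warning, meaning no reduction.
#'
#' @param values non-increasing eigenvalue sequence (length >= 2).
#' @param rank optional fixed rank overriding the elbow (used to reproduce a
#'   published choice exactly).
#' @return integer rank in `[1, length(values)]`.
#' @examples
#' select_rank(c(4, 2, 1, 1, 1))
#' @export
select_rank <- function(values, rank = NULL) {
  n <- length(values)
  if (n < 2L) stop("need at least two eigenvalues")
  if (any(diff(values) > 1e-8 * max(abs(values), 1))) {
    stop("eigenvalues must be non-increasing")
  }
  if (!is.null(rank)) {
    rank <- as.integer(rank)
    if (rank < 1L || rank > n) stop("'rank' must be in [1, ", n, "]")
    return(rank)
  }
  # perpendicular distance from (i, values[i]) to the chord
  # joining (1, values[1]) and (n, values[n])
  i <- seq_len(n)
  dx <- n - 1
  dy <- values[n] - values[1]
  d <- abs(dy * (i - 1) - dx * (values - values[1])) / sqrt(dx^2 + dy^2)
  if (max(d) <= 1e-12 * max(abs(values), 1)) {
    warning("degenerate scree curve: no elbow, keeping all ", n, " components")
    return(n)
  }
  which.max(d)
}

#' Subset loadings to the genotyped individuals
#'
#' Restricts the rows of a loadings matrix to the individuals that have
#' genomic markers, in the row order of the genotype matrix. The
#' decomposition is performed on the full pedigree first and subset after,
#' preserving the directionality (eigenvectors) and variance weighting
#' (eigenvalues) of the complete relationship structure; columns are
#' unchanged.
#'
#' @param L loadings matrix with individual IDs as rownames.
#' @param genotyped_ids character vector of IDs, in genotype row order.
#' @return loadings matrix with `length(genotyped_ids)` rows.
#' @export
subset_loadings <- function(L, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  missing <- setdiff(genotyped_ids, rownames(L))
  if (length(missing)) {
    stop("genotyped IDs absent from the pedigree loadings: ",
         paste(missing, collapse = ", "))
  }
  L[genotyped_ids, , drop = FALSE]
}

#' Assemble the joint model input
#'
#' Column-concatenates pedigree loadings and genomic markers into the joint
#' tabular input `X = [L_r, M]` and records column provenance (`"loading"`
#' or `"marker"`), used downstream to report selected-feature counts per
#' category. Either part may be omitted for single-source models.
#'
#' @param markers genotype dosage matrix (individuals x markers), or `NULL`.
#' @param loadings loadings matrix from [subset_loadings()], or `NULL`.
#' @return numeric matrix with attribute `provenance` (character vector,
#'   one entry per column).
#' @export
assemble_features <- function(markers, loadings = NULL) {
  if (is.null(markers) && is.null(loadings)) stop("no input features")
  if (!is.null(loadings) && ncol(loadings) == 0L) loadings <- NULL
  if (!is.null(markers) && !is.null(loadings)) {
    if (nrow(markers) != nrow(loadings) ||
        (!is.null(rownames(markers)) && !is.null(rownames(loadings)) &&
         !identical(rownames(markers), rownames(loadings)))) {
      stop("row IDs of loadings and markers must be identical and in the same order")
    }
  }
  X <- cbind(loadings, markers)
  prov <- c(rep("loading", if (is.null(loadings)) 0L else ncol(loadings)),
            rep("marker", if (is.null(markers)) 0L else ncol(markers)))
  attr(X, "provenance") <- prov
  X
}

#' Column provenance of a feature matrix
#'
#' @param x a matrix built by [assemble_features()] (or any matrix; columns
#'   without recorded provenance are tagged `"marker"`).
#' @return character vector with one entry per column.
#' @export
feature_provenance <- function(x) {
  prov <- attr(x, "provenance")
  if (is.null(prov)) prov <- rep("marker", ncol(x))
  prov
}

#' Scree plot with the selected rank
#'
#' @param values descending eigenvalue sequence.
#' @param rank rank to mark; `NULL` computes the elbow via [select_rank()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return the marked rank, invisibly.
#' @export
plot_scree <- function(values, rank = NULL, ...) {
  if (is.null(rank)) rank <- select_rank(values)
  graphics::plot(seq_along(values), values, type = "b", pch = 20,
                 xlab = "component", ylab = "eigenvalue", ...)
  graphics::abline(v = rank, lty = 2, col = "red")
  invisible(rank)
}
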