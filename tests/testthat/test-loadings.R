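test_that("eigendecomposition is descending, orthonormal and reconstructs A", {
  expect_equal(relationship_eigen(diag(3))$values, rep(1, 3))
  # closed form for [[1, .5], [.5, 1]]: eigenvalues 1.5 and 0.5
  e2 <- relationship_eigen(matrix(c(1, .5, .5, 1), 2))
  expect_equal(e2$values, c(1.5, 0.5))

  set.seed(5)
  A <- pedigree_relationship(random_pedigree(20))
  e <- relationship_eigen(A)
  expect_true(all(diff(e$values) <= 1e-12))
  Q <- e$vectors
  expect_lt(max(abs(crossprod(Q) - diag(nrow(A)))), 1e-8)
  rec <- Q %*% diag(e$values) %*% t(Q)
  expect_lt(norm(rec - A, "F") / norm(A, "F"), 1e-8)
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (k in seq_len(ncol(Q))) expect_gt(Q[which.max(abs(Q[, k])), k], 0)
  expect_error(relationship_eigen(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("loadings are the square-root factor of A", {
  # identity input: loadings are the identity up to column sign
  L <- pedigree_loadings(diag(3), rank = 3)
  expect_equal(unname(L %*% t(L)), diag(3), ignore_attr = TRUE)
  perm <- abs(unname(L))
  expect_true(all(perm %in% c(0, 1)) && all(rowSums(perm) == 1) &&
                all(colSums(perm) == 1))

  A <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  L2 <- pedigree_loadings(A, rank = 2)
  expect_lt(max(abs(L2 %*% t(L2) - A)), 1e-10)
  expect_identical(colnames(L2), c("PC1", "PC2"))

  # tiny negative eigenvalues are clamped, larger ones are an error
  e <- relationship_eigen(diag(2))
  e$values <- c(1, -1e-14)
  expect_silent(Lc <- pedigree_loadings(e, rank = 2))
  expect_equal(Lc[, 2], c(a = 0, b = 0), ignore_attr = TRUE)
  e$values <- c(1, -0.5)
  expect_error(pedigree_loadings(e, rank = 2), "positive semi-definite")
})

test_that("full pipeline reconstruction error is non-increasing in rank", {
  set.seed(7)
  A <- pedigree_relationship(random_pedigree(15))
  e <- relationship_eigen(A)
  errs <- sapply(seq_len(nrow(A)), function(m) {
    L <- pedigree_loadings(e, rank = m)
    norm(A - L %*% t(L), "F")
  })
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[nrow(A)] / norm(A, "F"), 1e-8)
})

test_that("scree elbow matches brute-force distance-to-chord enumeration", {
  brute <- function(v) {
    n <- length(v)
    x1 <- c(1, v[1]); x2 <- c(n, v[n])
    d <- sapply(seq_len(n), function(i) {
      p <- c(i, v[i])
      abs((x2[2] - x1[2]) * (p[1] - x1[1]) - (x2[1] - x1[1]) * (p[2] - x1[2])) /
        sqrt(sum((x2 - x1)^2))
    })
    which.max(d)
  }
  v1 <- c(4, 2, 1, 1, 1)
  expect_identical(select_rank(v1), brute(v1))
  v2 <- 2^-(0:9)
  expect_identical(select_rank(v2), brute(v2))
  set.seed(9)
  for (i in 1:10) {
    v <- sort(rexp(sample(5:40, 1)), decreasing = TRUE)
    expect_identical(select_rank(v), brute(v))
  }
  # degenerate flat scree keeps everything, with a warning
  expect_warning(m <- select_rank(c(5, 5, 5, 5)), "degenerate")
  expect_identical(m, 4L)
  # explicit rank overrides the elbow
  expect_identical(select_rank(v2, rank = 7), 7L)
})

test_that("subsetting loadings preserves rows and order", {
  set.seed(13)
  A <- pedigree_relationship(random_pedigree(10))
  L <- pedigree_loadings(A, rank = 4)
  ids <- rownames(L)
  expect_equal(subset_loadings(L, ids), L, ignore_attr = TRUE)
  rev_ids <- rev(ids)
  expect_equal(subset_loadings(L, rev_ids), L[rev_ids, ])
  pick <- ids[c(2, 5, 9)]
  Ls <- subset_loadings(L, pick)
  expect_equal(dim(Ls), c(3L, 4L))
  expect_equal(Ls, L[pick, ])
  expect_error(subset_loadings(L, c(ids[1], "nobody")), "nobody")
})

test_that("feature assembly concatenates loadings then markers with provenance", {
  L <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("PC1", "PC2")))
  M <- matrix(0:11, 3, 4, dimnames = list(c("a", "b", "c"), paste0("M", 1:4)))
  X <- assemble_features(markers = M, loadings = L)
  expect_equal(dim(X), c(3L, 6L))
  expect_identical(feature_provenance(X),
                   c(rep("loading", 2), rep("marker", 4)))
  expect_equal(X[, 1:2], L)
  # markers-only mode
  Xm <- assemble_features(markers = M)
  expect_equal(unname(Xm), unname(M), ignore_attr = TRUE)
  expect_identical(feature_provenance(Xm), rep("marker", 4))
  # row mismatch
  expect_error(assemble_features(markers = M[c(2, 1, 3), ], loadings = L),
               "identical")
})

test_that("loadings pipeline is invariant to pedigree record order", {
  set.seed(17)
  ped <- random_pedigree(18)
  run <- function(p) {
    A <- pedigree_relationship(p)
    pedigree_loadings(A, rank = 5)
  }
  L1 <- run(ped)
  L2 <- run(ped[sample(nrow(ped)), ])
  expect_equal(L1, L2)
})
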