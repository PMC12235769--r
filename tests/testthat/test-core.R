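test_that("activation functions evaluate their defining formulas", {
  expect_identical(elu(0, 1), 0)
  expect_identical(elu(2, 1), 2)
  expect_equal(elu(-1, 1), exp(-1) - 1)
  expect_equal(elu(-2, 0.5), 0.5 * (exp(-2) - 1))
  expect_error(elu(1, gamma = 0), "positive")
  expect_error(elu(1, gamma = -1), "positive")

  expect_identical(hard_sigmoid(0), 0.5)
  expect_identical(hard_sigmoid(2.5), 1)
  expect_identical(hard_sigmoid(-2.5), 0)
  expect_identical(hard_sigmoid(5), 1)
  expect_equal(hard_sigmoid(1), 0.7)
  a <- seq(-4, 4, by = 0.25)
  expect_true(all(hard_sigmoid(a) >= 0 & hard_sigmoid(a) <= 1))
})

test_that("variable selection block is a softmax re-weighting", {
  # symmetry: equal scores give uniform weights
  v <- vs_block(rep(2.5, 6))
  expect_equal(v$weights, rep(1 / 6, 6))
  # saturation
  v2 <- vs_block(c(50, 0, 0))
  expect_gt(v2$weights[1], 0.999)
  expect_lt(max(abs(v2$reweighted[2:3])), 1e-12)
  # against an independent exp/normalize computation
  s <- c(1, 2, 3)
  expect_equal(vs_block(s)$weights, exp(s) / sum(exp(s)), tolerance = 1e-10)
  expect_equal(vs_block(s)$reweighted, s * exp(s) / sum(exp(s)),
               tolerance = 1e-10)
  # distribution invariants and shift invariance
  set.seed(3)
  for (i in 1:20) {
    s <- rnorm(sample(2:30, 1), sd = 5)
    w <- vs_block(s)$weights
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_equal(w, vs_block(s + 123.4)$weights, tolerance = 1e-9)
  }
  expect_error(vs_block(c(1, NaN)), "finite")
})

test_that("multi-task loss is the mean squared error over observed entries", {
  Y <- matrix(rnorm(12), 4, 3)
  expect_identical(multitask_loss(Y, Y), 0)
  expect_identical(multitask_loss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  set.seed(4)
  Yh <- matrix(rnorm(12), 4, 3)
  brute <- 0
  for (i in 1:4) for (j in 1:3) brute <- brute + (Y[i, j] - Yh[i, j])^2
  expect_equal(multitask_loss(Y, Yh), brute / 12, tolerance = 1e-12)
  # missing entries are excluded from the mean
  Yna <- Y; Yna[1, 1] <- NA
  expect_equal(multitask_loss(Yna, Yh),
               mean((Y[-1] - Yh[-1])[!is.na(Yna[-1])]^2),
               tolerance = 1e-12)
  expect_error(multitask_loss(Y, Yh[1:3, ]), "shape")
})

test_that("gate identities hold: g = 0 gives the skip path, g = 1 the linear unit", {
  set.seed(8)
  P <- 4; H <- 3
  for (rep in 1:5) {
    pars <- random_params(P, H, 1)
    X <- matrix(rnorm(3 * P), 3, P)
    # hard-sigmoid saturates exactly: b3 = -20 forces g = 0, +20 forces g = 1
    p0 <- pars; p0$W3[] <- 0; p0$b3[] <- -20
    m0 <- model_from_params(p0, gate = "hard_sigmoid")
    z0 <- grvsnn_forward(m0, X, intermediates = TRUE)$zhat
    # at g = 0 the block output is LayerNorm(skip-projected input),
    # independent of W1 and W2
    p0b <- p0; p0b$W1 <- matrix(rnorm(P * H), P, H); p0b$W2 <- matrix(rnorm(P * H * H), P, H * H)
    z0b <- grvsnn_forward(model_from_params(p0b, gate = "hard_sigmoid"), X,
                          intermediates = TRUE)$zhat
    expect_identical(z0, z0b)
    for (n in 1:3) for (j in 1:P) {
      xs <- p0$skip[j, ] * X[n, j]
      mu <- mean(xs); v <- mean((xs - mu)^2)
      ln <- p0$gain[j, ] * (xs - mu) / sqrt(v + 1e-5) + p0$bias[j, ]
      expect_equal(z0[j, , n], ln, tolerance = 1e-12)
    }
    # g = 1: output is LayerNorm(h), independent of the skip projection
    p1 <- pars; p1$W3[] <- 0; p1$b3[] <- 20
    z1 <- grvsnn_forward(model_from_params(p1, gate = "hard_sigmoid"), X,
                         intermediates = TRUE)$zhat
    p1b <- p1; p1b$skip <- matrix(rnorm(P * H), P, H)
    z1b <- grvsnn_forward(model_from_params(p1b, gate = "hard_sigmoid"), X,
                          intermediates = TRUE)$zhat
    expect_identical(z1, z1b)
    for (n in 1:3) for (j in 1:P) {
      f1 <- elu(p1$W1[j, ] * X[n, j] + p1$b1[j, ])
      h <- drop(matrix(p1$W2[j, ], H, H, byrow = TRUE) %*% f1) + p1$b2[j, ]
      mu <- mean(h); v <- mean((h - mu)^2)
      ln <- p1$gain[j, ] * (h - mu) / sqrt(v + 1e-5) + p1$bias[j, ]
      expect_equal(z1[j, , n], ln, tolerance = 1e-10)
    }
  }
})

test_that("sigmoid gate stays strictly inside (0,1), hard sigmoid saturates", {
  set.seed(12)
  pars <- random_params(3, 2, 1)
  x <- rnorm(10)
  block <- list(W1 = pars$W1[1, ], b1 = pars$b1[1, ],
                W2 = matrix(pars$W2[1, ], 2, 2, byrow = TRUE), b2 = pars$b2[1, ],
                W3 = matrix(pars$W3[1, ], 2, 2, byrow = TRUE), b3 = pars$b3[1, ],
                skip = pars$skip[1, ], gain = pars$gain[1, ], bias = pars$bias[1, ])
  # block outputs are finite for both gate kinds
  expect_true(all(is.finite(gr_block_forward(x, block, gate = "sigmoid"))))
  expect_true(all(is.finite(gr_block_forward(x, block, gate = "hard_sigmoid"))))
  g <- 1 / (1 + exp(-rnorm(100, sd = 5)))
  expect_true(all(g > 0 & g < 1))
  hs <- hard_sigmoid(c(-2.51, 2.51, -100, 100))
  expect_identical(hs, c(0, 1, 0, 1))
})

test_that("layer-normalized block outputs have zero mean and unit variance", {
  set.seed(14)
  P <- 5; H <- 4
  pars <- random_params(P, H, 1)
  pars$gain[] <- 1; pars$bias[] <- 0   # identity normalization parameters
  m <- model_from_params(pars)
  X <- matrix(rnorm(6 * P), 6, P)
  zh <- grvsnn_forward(m, X, intermediates = TRUE)$zhat
  for (n in 1:6) for (j in 1:P) {
    expect_lt(abs(mean(zh[j, , n])), 1e-6)
    expect_lt(abs(mean(zh[j, , n]^2) - 1), 1e-3)
  }
})

test_that("model forward matches the straight-line oracle and is deterministic", {
  set.seed(16)
  for (rep in 1:10) {
    P <- sample(2:5, 1); H <- sample(2:3, 1); T <- sample(1:2, 1)
    gate <- sample(c("sigmoid", "hard_sigmoid"), 1)
    pars <- random_params(P, H, T)
    m <- model_from_params(pars, gate = gate)
    X <- matrix(rnorm(4 * P), 4, P)
    fw <- grvsnn_forward(m, X)
    or <- oracle_forward(pars, X, gate = gate)
    expect_lt(max(abs(fw$yhat - or$yhat)), 1e-6)
    expect_lt(max(abs(fw$weights - or$weights)), 1e-6)
    # eval-mode determinism is exact
    expect_identical(fw$yhat, grvsnn_forward(m, X)$yhat)
  }
  # zero samples give an empty prediction matrix
  m <- grvsnn_init(3, 2, 2, seed = 1)
  expect_equal(dim(grvsnn_forward(m, matrix(0, 0, 3))$yhat), c(0L, 2L))
  expect_error(grvsnn_forward(m, matrix(0, 2, 4)), "expects")
})

test_that("analytic gradients match finite differences", {
  set.seed(18)
  P <- 3; H <- 2; T <- 2; N <- 5
  pars <- random_params(P, H, T)
  X <- matrix(rnorm(N * P), N, P)
  Y <- matrix(rnorm(N * T), N, T)
  Mk <- matrix(1, N, T); Mk[2, 1] <- 0
  dm <- array(as.double(runif(P * H * N) < 0.8), c(P, H, N))
  for (gate in c(0L, 1L)) {
    res <- grvsnn:::.cpp_grvsnn_loss_grad(pars, X, Y, Mk, dm, 0.8, gate, 1,
                                          TRUE, 1e-3)
    lossfun <- function(p) grvsnn:::.cpp_grvsnn_loss_grad(
      p, X, Y, Mk, dm, 0.8, gate, 1, TRUE, 1e-3)$loss
    for (nm in names(pars)) {
      idx <- seq_along(pars[[nm]])
      if (length(idx) > 5) idx <- sample(idx, 5)
      for (i in idx) {
        eps <- 1e-6
        pp <- pars; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- pars; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
        expect_lt(abs(res$grads[[nm]][i] - num), 1e-5 * max(1, abs(num)))
      }
    }
  }
})

test_that("importance report satisfies its invariants", {
  set.seed(22)
  P <- 6
  m <- grvsnn_init(P, hidden_width = 3, n_traits = 1, seed = 2)
  m$x <- matrix(rnorm(20 * P), 20, P)
  imp <- importance(m, m$x)
  expect_true(all(imp$raw_weight >= 0))
  expect_equal(sum(imp$raw_weight), 1, tolerance = 1e-6)
  expect_equal(max(imp$relative_importance), 1)
  expect_true(all(imp$relative_importance >= 0 & imp$relative_importance <= 1))
  expect_identical(imp$selected, imp$relative_importance >= 0.05)
  # threshold 0 selects everything; threshold 1 selects only the argmax
  expect_true(all(importance(m, m$x, threshold = 0)$selected))
  imp1 <- importance(m, m$x, threshold = 1)
  expect_identical(which(imp1$selected),
                   which(imp1$relative_importance == 1))
  # identical blocks and constant input give uniform weights
  pars <- random_params(1, 3, 1)
  parsP <- lapply(pars, function(p) {
    if (is.matrix(p) && nrow(p) == 1) matrix(rep(p, each = P), P, ncol(p))
    else if (length(p) == 1) rep(p, P)
    else p
  })
  parsP$Wout <- matrix(1, 1, P); parsP$bout <- 0
  mu <- model_from_params(parsP)
  Xc <- matrix(1, 5, P)
  impu <- importance(mu, Xc)
  expect_equal(impu$raw_weight, rep(1 / P, P), tolerance = 1e-10)
  expect_true(all(impu$selected))
  expect_error(importance(mu, Xc[0, , drop = FALSE]), "at least one")
})
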