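# Independent oracles used across the test suite. These re-derive expected
# values from first principles (path counting, Monte-Carlo gene dropping,
# straight-line arithmetic) and deliberately share no code with the package
# internals they check.

# Straight-line re-computation of the full network forward pass:
# nonlinear ELU layer -> (identity dropout in eval mode) -> linear unit and
# gate -> residual mix with skip projection -> layer normalization ->
# scalar reduction -> softmax re-weighting -> linear multi-task head.
oracle_forward <- function(pars, X, gate = "sigmoid", gamma = 1) {
  N <- nrow(X); P <- nrow(pars$W1); H <- ncol(pars$W1); T <- nrow(pars$Wout)
  gfun <- if (gate == "sigmoid") function(a) 1 / (1 + exp(-a)) else
    function(a) pmax(0, pmin(1, 0.2 * a + 0.5))
  yhat <- matrix(0, N, T); wts <- matrix(0, N, P)
  zhat <- array(0, c(P, H, N))
  for (n in seq_len(N)) {
    sc <- numeric(P)
    for (j in seq_len(P)) {
      a1 <- pars$W1[j, ] * X[n, j] + pars$b1[j, ]
      f1 <- ifelse(a1 > 0, a1, gamma * (exp(a1) - 1))
      f2 <- f1
      W2j <- matrix(pars$W2[j, ], H, H, byrow = TRUE)   # column (k-1)*H+l = [k,l]
      W3j <- matrix(pars$W3[j, ], H, H, byrow = TRUE)
      h <- drop(W2j %*% f2) + pars$b2[j, ]
      g <- gfun(drop(W3j %*% f2) + pars$b3[j, ])
      xs <- pars$skip[j, ] * X[n, j]
      z <- g * h + (1 - g) * xs
      mu <- sum(z) / H
      v <- sum((z - mu)^2) / H
      zh <- pars$gain[j, ] * (z - mu) / sqrt(v + 1e-5) + pars$bias[j, ]
      zhat[j, , n] <- zh
      sc[j] <- sum(pars$red[j, ] * zh) + pars$red_b[j]
    }
    e <- exp(sc - max(sc)); w <- e / sum(e)
    zp <- w * sc
    # linear multi-task head on the P-scaled re-weighted features
    yhat[n, ] <- drop(pars$Wout %*% (P * zp)) + pars$bout
    wts[n, ] <- w
  }
  list(yhat = yhat, weights = wts, zhat = zhat)
}

# Monte-Carlo gene dropping: founders get unique allele labels, offspring
# inherit one random allele per parent; the additive relationship of a pair
# is twice the probability that randomly drawn alleles are identical by
# descent. 'ped' must be a data.frame with parents preceding offspring and
# NA for unknown parents.
gene_drop_A <- function(ped, nrep = 1e5) {
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  al1 <- matrix(0L, nrep, n); al2 <- matrix(0L, nrep, n)
  lab <- 0L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) { lab <- lab + 1L; al1[, i] <- lab } else {
      j <- pos[[s]]; pick <- runif(nrep) < 0.5
      al1[, i] <- ifelse(pick, al1[, j], al2[, j])
    }
    if (is.na(d)) { lab <- lab + 1L; al2[, i] <- lab } else {
      j <- pos[[d]]; pick <- runif(nrep) < 0.5
      al2[, i] <- ifelse(pick, al1[, j], al2[, j])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + mean(al1[, i] == al2[, i])
    if (i < n) for (j in (i + 1):n) {
      k <- (mean(al1[, i] == al1[, j]) + mean(al1[, i] == al2[, j]) +
            mean(al2[, i] == al1[, j]) + mean(al2[, i] == al2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * k
    }
  }
  A
}

# random pedigree with parents drawn among earlier individuals (possibly
# unknown); returned with parents before offspring
random_pedigree <- function(n, p_unknown = 0.25) {
  id <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  nf <- max(2L, ceiling(n * 0.3))
  for (i in seq.int(nf + 1L, n)) {
    cand <- id[seq_len(i - 1L)]
    if (runif(1) > p_unknown) sire[i] <- sample(cand, 1)
    if (runif(1) > p_unknown) dam[i] <- sample(cand, 1)
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# naive four-term double-centering distance correlation (explicit loops)
dcor_naive <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  dmat <- function(m) {
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    d
  }
  center <- function(d) {
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      out[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
    }
    out
  }
  A <- center(dmat(x)); B <- center(dmat(y))
  dcov2 <- mean(A * B)
  dvx <- mean(A^2); dvy <- mean(B^2)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# random tiny-model parameter list in the package's layout
random_params <- function(P, H, T) {
  list(W1 = matrix(rnorm(P * H), P, H), b1 = matrix(rnorm(P * H), P, H),
       W2 = matrix(rnorm(P * H * H), P, H * H), b2 = matrix(rnorm(P * H), P, H),
       W3 = matrix(rnorm(P * H * H), P, H * H), b3 = matrix(rnorm(P * H), P, H),
       skip = matrix(rnorm(P * H), P, H), gain = matrix(rnorm(P * H), P, H),
       bias = matrix(rnorm(P * H), P, H), red = matrix(rnorm(P * H), P, H),
       red_b = rnorm(P), Wout = matrix(rnorm(T * P), T, P), bout = rnorm(T))
}

# build a grvsnn object around a given parameter list
model_from_params <- function(pars, gate = "sigmoid", elu_gamma = 1) {
  m <- grvsnn_init(n_features = nrow(pars$W1), hidden_width = ncol(pars$W1),
                   n_traits = nrow(pars$Wout), gate = gate,
                   elu_gamma = elu_gamma, seed = 1)
  m$params <- pars
  m
}

# small linear single-trait problem with sparse causal features
sim_linear <- function(n, p, n_causal, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rnorm(n_causal), rep(0, p - n_causal))
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  list(X = X, y = y, beta = beta, causal = seq_len(n_causal))
}
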