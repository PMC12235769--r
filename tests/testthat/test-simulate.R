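test_that("simulated pedigrees have the prescribed generation structure", {
  # a single generation is founders only
  p1 <- sim_pedigree(n_founders = 8, n_generations = 1, seed = 1)
  expect_identical(nrow(p1), 8L)
  expect_true(all(is.na(p1$sire)) && all(is.na(p1$dam)))

  # same seed, same table
  expect_identical(sim_pedigree(10, 3, 2, seed = 5), sim_pedigree(10, 3, 2, seed = 5))

  # mating arithmetic: 10 founders -> 5 matings x 2 offspring per generation
  p3 <- sim_pedigree(n_founders = 10, n_generations = 3,
                     offspring_per_mating = 2, seed = 7)
  gen <- attr(p3, "generation")
  expect_identical(as.integer(table(gen)), c(10L, 10L, 10L))
  expect_identical(nrow(p3), 30L)
  # validity: as_pedigree re-checks acyclicity and parent declarations
  expect_silent(as_pedigree(as.data.frame(p3)))
  expect_error(sim_pedigree(n_founders = 1), "two founders")
})

test_that("gene-dropped genotypes are Mendelian-consistent dosages", {
  set.seed(50)
  ped <- sim_pedigree(12, 3, 2, seed = 3)
  M <- sim_genotypes(ped, n_markers = 60, seed = 9)
  expect_true(all(M %in% 0:2))
  expect_identical(rownames(M), ped$id)
  # offspring dosages are compatible with parental transmission
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  for (i in which(!is.na(ped$sire) & !is.na(ped$dam))) {
    s <- M[pos[[ped$sire[i]]], ]; d <- M[pos[[ped$dam[i]]], ]
    kid <- M[i, ]
    # homozygous parents pin down the transmitted allele
    expect_true(all(kid[s == 0 & d == 0] == 0))
    expect_true(all(kid[s == 2 & d == 2] == 2))
    expect_true(all(kid[s == 0 & d == 2] == 1))
    expect_true(all(kid >= (s == 2) + (d == 2)))
    expect_true(all(kid <= 2 - ((s == 0) + (d == 0))))
  }
})

test_that("founder allele frequencies match the requested MAF distribution", {
  founders <- sim_pedigree(n_founders = 200, n_generations = 1, seed = 11)
  M <- sim_genotypes(founders, n_markers = 2000, maf_range = c(0.2, 0.2),
                     seed = 13)
  freq <- colMeans(M) / 2
  # binomial sampling: mean frequency within 0.01 of the target
  expect_lt(abs(mean(freq) - 0.2), 0.01)
  expect_error(sim_genotypes(founders, 10, maf_range = c(0, 0.5)), "MAF")
})

test_that("phenotype variance decomposition matches the requested shares", {
  set.seed(52)
  ped <- sim_pedigree(40, 3, 2, seed = 15)
  M <- sim_genotypes(ped, 80, seed = 17)
  A <- pedigree_relationship(ped)

  # pure noise: no marker or pedigree variance
  ph0 <- sim_phenotypes(M, A, n_causal = 5, h2_marker = 0, h2_pedigree = 0,
                        seed = 19)
  expect_lt(abs(cor(ph0$y[, 1], scale(M[, ph0$truth$causal_index[1]]))), 0.35)

  # noiseless single causal marker: phenotype is that marker column
  ph1 <- sim_phenotypes(M, A, n_causal = 1, h2_marker = 1, h2_pedigree = 0,
                        seed = 21)
  expect_gte(abs(cor(ph1$y[, 1], M[, ph1$truth$causal_index])), 0.99)

  # realized marker share tracks the configured share across seeds
  shares <- sapply(1:10, function(s) {
    ph <- sim_phenotypes(M, A, n_causal = 10, h2_marker = 0.4,
                         h2_pedigree = 0.2, seed = 100 + s)
    g <- scale(M[, ph$truth$causal_index]) %*% ph$truth$effects[, 1]
    summary(lm(ph$y[, 1] ~ g))$r.squared
  })
  expect_lt(abs(mean(shares) - 0.4), 0.05)
  expect_error(sim_phenotypes(M, A, h2_marker = 0.7, h2_pedigree = 0.5),
               "shares")
})

test_that("relatives have more similar breeding values than non-relatives", {
  set.seed(54)
  ped <- sim_pedigree(30, 4, 2, seed = 23)
  M <- sim_genotypes(ped, 50, seed = 25)
  A <- pedigree_relationship(ped)
  ph <- sim_phenotypes(M, A, n_causal = 10, h2_marker = 0.2, h2_pedigree = 0.6,
                       seed = 27)
  bv <- ph$truth$breeding_values[, 1]
  iu <- which(upper.tri(A), arr.ind = TRUE)
  rel <- A[upper.tri(A)]
  prod_bv <- bv[iu[, 1]] * bv[iu[, 2]]
  # covariance of breeding values increases with relatedness
  hi <- rel >= 0.5; lo <- rel < 0.1
  expect_gt(mean(prod_bv[hi]), mean(prod_bv[lo]))
  expect_gt(cor(rel, prod_bv), 0)
})

test_that("multi-trait effects are correlated as configured", {
  set.seed(56)
  ped <- sim_pedigree(60, 2, 2, seed = 29)
  M <- sim_genotypes(ped, 400, seed = 31)
  ph <- sim_phenotypes(M, NULL, n_causal = 200, n_traits = 2,
                       trait_correlation = 0.8, h2_marker = 0.5,
                       h2_pedigree = 0, seed = 33)
  expect_gt(cor(ph$truth$effects[, 1], ph$truth$effects[, 2]), 0.6)
})

test_that("sim_dataset wires pedigree, loadings and phenotypes together", {
  d <- sim_dataset(n_founders = 16, n_generations = 3, n_markers = 40,
                   n_causal = 5, n_traits = 2, seed = 35)
  expect_identical(rownames(d$features), rownames(d$genotypes))
  expect_identical(ncol(d$features), ncol(d$genotypes) + ncol(d$loadings))
  expect_setequal(unique(feature_provenance(d$features)), c("loading", "marker"))
  expect_identical(nrow(d$y), nrow(d$genotypes))
  # genotyped = "last": pedigree larger than the genotyped set
  dl <- sim_dataset(n_founders = 16, n_generations = 3, n_markers = 30,
                    genotyped = "last", seed = 37)
  expect_lt(nrow(dl$genotypes), nrow(dl$pedigree))
  expect_identical(rownames(dl$loadings), rownames(dl$genotypes))
})

test_that("the full pipeline runs end to end at moderate size with finite metrics", {
  # simulate -> relationship -> loadings -> assemble -> cross-validate
  t0 <- Sys.time()
  d <- sim_dataset(n_founders = 75, n_generations = 3, offspring_per_mating = 2,
                   n_markers = 200, genotyped = "all", seed = 61,
                   n_causal = 10, n_traits = 1, h2_marker = 0.3,
                   h2_pedigree = 0.3)
  expect_gte(nrow(d$features), 140)
  cv <- cv_grvsnn(d$features, d$y, plan = cv_plan(n_folds = 5, n_repeats = 1,
                                                  base_seed = 3),
                  hidden_width = 4, weight_decay = 0.1, max_epochs = 120,
                  batch_size = 128)
  expect_identical(nrow(cv$results), 5L)
  expect_true(all(is.finite(cv$results$mse)))
  expect_true(all(is.finite(cv$results$dcor)))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "mins")), 5)
})
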