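# Synthetic pedigrees, genotypes and phenotypes with the statistical
# structure the model assumes: sparse causal markers, an A-correlated
# polygenic component, optional non-additive effects and Gaussian noise.

#' Simulate a multi-generation pedigree
#'
#' Builds non-overlapping generations: `n_founders` unrelated founders, then
#' in each later generation the previous generation is shuffled into
#' disjoint sire/dam pairs, each producing `offspring_per_mating` offspring.
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations total number of generations including the founders.
#' @param offspring_per_mating offspring per mating pair.
#' @param seed RNG seed.
#' @return a `pedigree_table` with an attribute `generation` (integer per
#'   individual, founders = 1).
#' @export
sim_pedigree <- function(n_founders = 20, n_generations = 3,
                         offspring_per_mating = 2, seed = NULL) {
  if (n_founders < 2) stop("need at least two founders")
  if (n_generations < 1) stop("'n_generations' must be at least 1")
  if (offspring_per_mating < 1) stop("'offspring_per_mating' must be at least 1")
  with_seed(seed, {
    id <- sprintf("G1_%03d", seq_len(n_founders))
    recs <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                       stringsAsFactors = FALSE)
    gen <- rep(1L, n_founders)
    prev <- id
    for (g in seq_len(n_generations - 1L) + 1L) {
      shuffled <- prev[sample.int(length(prev))]
      n_pairs <- floor(length(shuffled) / 2)
      if (n_pairs < 1) break
      sires <- shuffled[seq_len(n_pairs)]
      dams <- shuffled[n_pairs + seq_len(n_pairs)]
      kid_id <- sprintf("G%d_%03d", g, seq_len(n_pairs * offspring_per_mating))
      recs <- rbind(recs, data.frame(
        id = kid_id,
        sire = rep(sires, each = offspring_per_mating),
        dam = rep(dams, each = offspring_per_mating),
        stringsAsFactors = FALSE))
      gen <- c(gen, rep(g, length(kid_id)))
      prev <- kid_id
    }
    ped <- as_pedigree(recs)
    attr(ped, "generation") <- gen[match(ped$id, recs$id)]
    ped
  })
}

#' Drop genotypes through a pedigree
#'
#' Gene dropping: founder allele counts are drawn from Binomial(2, MAF)
#' with per-locus allele frequencies uniform in `maf_range`; each offspring
#' receives one allele per parent per locus (a heterozygous parent
#' transmits the alternate allele with probability 1/2). Dosages are coded
#' 0/1/2 and are Mendelian-consistent by construction.
#'
#' @param ped pedigree accepted by [as_pedigree()].
#' @param n_markers number of unlinked loci.
#' @param maf_range minor-allele-frequency range for founders, in (0, 0.5].
#' @param seed RNG seed.
#' @return integer dosage matrix (individuals x markers) with individual
#'   IDs as rownames and markers named `M1..`.
#' @export
sim_genotypes <- function(ped, n_markers = 100, maf_range = c(0.05, 0.5),
                          seed = NULL) {
  ped <- as_pedigree(ped)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("MAF bounds must be in (0, 0.5]")
  n <- nrow(ped)
  with_seed(seed, {
    maf <- runif(n_markers, maf_range[1], maf_range[2])
    pos <- seq_len(n); names(pos) <- ped$id
    # alleles stored separately so transmission is genuinely Mendelian
    a1 <- matrix(0L, n, n_markers)
    a2 <- matrix(0L, n, n_markers)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      a1[i, ] <- if (is.na(s)) rbinom(n_markers, 1L, maf) else {
        j <- pos[[s]]
        ifelse(runif(n_markers) < 0.5, a1[j, ], a2[j, ])
      }
      a2[i, ] <- if (is.na(d)) rbinom(n_markers, 1L, maf) else {
        j <- pos[[d]]
        ifelse(runif(n_markers) < 0.5, a1[j, ], a2[j, ])
      }
    }
    M <- a1 + a2
    dimnames(M) <- list(ped$id, paste0("M", seq_len(n_markers)))
    attr(M, "maf") <- maf
    M
  })
}

#' Simulate multi-trait phenotypes
#'
#' Generates `n_traits` continuous traits over the rows of a genotype
#' matrix as the sum of (i) sparse additive effects of `n_causal` randomly
#' chosen markers, (ii) optional dominance deviations and pairwise
#' epistatic products at causal loci, (iii) a pedigree-correlated polygenic
#' term `L u` with `u` standard normal (using the loadings of the
#' relationship matrix, so its covariance is proportional to A), and (iv)
#' Gaussian noise. Each component is rescaled so its realized variance
#' share matches the requested decomposition and the phenotypic variance
#' is approximately 1. Traits share the causal loci; their effect vectors
#' are correlated at `trait_correlation`.
#'
#' @param M dosage matrix (individuals x markers).
#' @param A additive relationship matrix over (at least) the rows of `M`,
#'   or a precomputed loadings matrix; `NULL` with `h2_pedigree > 0` is an
#'   error.
#' @param n_causal number of causal markers.
#' @param n_traits number of traits.
#' @param trait_correlation correlation of causal effect sizes across
#'   traits, in `[-1, 1]`.
#' @param h2_marker phenotypic variance share of the causal-marker term.
#' @param h2_pedigree variance share of the polygenic term.
#' @param dominance_fraction fraction of the marker share realized as
#'   dominance deviations at the causal loci.
#' @param epistasis_pairs number of causal-pair product interactions.
#' @param seed RNG seed.
#' @return list with `y` (individuals x traits matrix) and `truth`
#'   (`causal_ids`, `effects`, `breeding_values`, `variance_shares`).
#' @export
sim_phenotypes <- function(M, A = NULL, n_causal = 10, n_traits = 1,
                           trait_correlation = 0.5,
                           h2_marker = 0.3, h2_pedigree = 0.3,
                           dominance_fraction = 0, epistasis_pairs = 0,
                           seed = NULL) {
  if (h2_marker < 0 || h2_pedigree < 0 || h2_marker + h2_pedigree > 1) {
    stop("variance shares must be non-negative with h2_marker + h2_pedigree <= 1")
  }
  if (n_causal > ncol(M)) stop("more causal markers than markers")
  n <- nrow(M)
  ids <- rownames(M)
  with_seed(seed, {
    causal <- sort(sample.int(ncol(M), n_causal))
    causal_ids <- colnames(M)[causal]
    # correlated effect vectors across traits
    shared <- rnorm(n_causal)
    rho <- trait_correlation
    beta <- sapply(seq_len(n_traits), function(t)
      rho * shared + sqrt(max(0, 1 - rho^2)) * rnorm(n_causal))
    beta <- matrix(beta, n_causal, n_traits)
    Mc <- scale(M[, causal, drop = FALSE])
    Mc[is.nan(Mc)] <- 0
    # unit-variance component helper
    unitize <- function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) return(v * 0)
      (v - mean(v)) / s
    }
    poly_raw <- NULL
    if (h2_pedigree > 0) {
      if (is.null(A)) stop("h2_pedigree > 0 requires a relationship matrix or loadings")
      L <- if (!is.null(attr(A, "eigenvalues")) || ncol(A) != nrow(A) ||
               max(abs(A - t(A))) > 1e-8) {
        A  # already a loadings matrix
      } else {
        pedigree_loadings(A, rank = nrow(A))
      }
      if (!is.null(ids) && !is.null(rownames(L))) {
        L <- L[ids, , drop = FALSE]
      }
      if (nrow(L) != n) stop("relationship information does not cover all genotyped rows")
      poly_raw <- sapply(seq_len(n_traits), function(t) L %*% rnorm(ncol(L)))
    }
    h2_dom <- h2_marker * dominance_fraction
    h2_add <- h2_marker - h2_dom
    y <- matrix(0, n, n_traits)
    bv <- matrix(0, n, n_traits)
    for (t in seq_len(n_traits)) {
      add <- unitize(drop(Mc %*% beta[, t])) * sqrt(h2_add)
      dom <- if (h2_dom > 0) {
        D <- 1 * (M[, causal, drop = FALSE] == 1)
        unitize(drop(D %*% rnorm(n_causal))) * sqrt(h2_dom)
      } else 0
      epi <- 0
      if (epistasis_pairs > 0) {
        pr <- replicate(epistasis_pairs, sample(seq_len(n_causal), 2))
        E <- sapply(seq_len(epistasis_pairs), function(k)
          Mc[, pr[1, k]] * Mc[, pr[2, k]])
        # epistasis borrows a fifth of the additive share
        epi <- unitize(drop(E %*% rnorm(epistasis_pairs))) * sqrt(h2_add / 5)
      }
      poly <- if (h2_pedigree > 0) unitize(poly_raw[, t]) * sqrt(h2_pedigree) else 0
      noise_share <- max(0, 1 - h2_add - h2_dom - h2_pedigree -
                           ifelse(epistasis_pairs > 0, h2_add / 5, 0))
      eps <- unitize(rnorm(n)) * sqrt(noise_share)
      y[, t] <- add + dom + epi + poly + eps
      bv[, t] <- add + poly
    }
    dimnames(y) <- list(ids, paste0("trait", seq_len(n_traits)))
    dimnames(bv) <- dimnames(y)
    list(y = y,
         truth = list(causal_ids = causal_ids, causal_index = causal,
                      effects = beta, breeding_values = bv,
                      variance_shares = c(marker = h2_marker,
                                          pedigree = h2_pedigree,
                                          dominance = h2_dom)))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: pedigree, gene-dropped genotypes, relationship
#' matrix, loadings and phenotypes in one call. With
#' `genotyped = "last"` only the final generation carries markers (the
#' pedigree is then larger than the genotyped set, as in real breeding
#' data); loadings are computed on the full pedigree and subset afterwards.
#'
#' @param n_founders,n_generations,offspring_per_mating pedigree shape.
#' @param n_markers,maf_range genotype settings.
#' @param genotyped `"all"` or `"last"` (only the last generation carries
#'   markers).
#' @param rank reduced rank for the loadings (`NULL` = scree elbow).
#' @param seed RNG seed; the stage seeds are derived from it.
#' @param ... phenotype settings passed to [sim_phenotypes()].
#' @return list with `pedigree`, `A`, `loadings` (reduced rank, genotyped
#'   rows), `genotypes`, `features` (joint `[L_r, M]` input), `y`, `truth`.
#' @export
sim_dataset <- function(n_founders = 30, n_generations = 4,
                        offspring_per_mating = 2, n_markers = 200,
                        maf_range = c(0.05, 0.5), genotyped = c("all", "last"),
                        rank = NULL, seed = 1L, ...) {
  genotyped <- match.arg(genotyped)
  ped <- sim_pedigree(n_founders, n_generations, offspring_per_mating,
                      seed = seed)
  M <- sim_genotypes(ped, n_markers, maf_range, seed = seed + 1L)
  A <- pedigree_relationship(ped)
  gen <- attr(ped, "generation")
  keep <- if (genotyped == "last") ped$id[gen == max(gen)] else ped$id
  Mg <- M[keep, , drop = FALSE]
  Lfull <- pedigree_loadings(A, rank = nrow(A))
  phe <- sim_phenotypes(Mg, Lfull, seed = seed + 2L, ...)
  m <- if (is.null(rank)) select_rank(attr(Lfull, "eigenvalues")) else rank
  Lr <- subset_loadings(Lfull[, seq_len(m), drop = FALSE], keep)
  X <- assemble_features(markers = Mg, loadings = Lr)
  list(pedigree = ped, A = A, loadings = Lr, genotypes = Mg,
       features = X, y = phe$y, truth = phe$truth)
}
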