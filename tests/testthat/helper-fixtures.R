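# Small in-code fixtures shared across test files.

# Random binomial genotype matrix with optional population labels.
rand_geno <- function(n, p, seed = 1, maf = c(0.1, 0.9), pops = NULL) {
  withr::with_seed(seed, {
    freq <- stats::runif(p, maf[1], maf[2])
    m <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), n, p)
    geno_matrix(m, population = pops)
  })
}

# Continuous matrix with one dominant variance axis; used where the first
# principal component must carry almost all the signal in every subset.
dominant_axis_matrix <- function(n, p, strength = 8, seed = 1) {
  withr::with_seed(seed, {
    z <- stats::rnorm(n)
    w <- stats::rnorm(p)
    w <- w / sqrt(sum(w^2))
    m <- strength * outer(z, w) + matrix(stats::rnorm(n * p), n, p)
    rownames(m) <- sprintf("a%03d", seq_len(n))
    colnames(m) <- sprintf("s%03d", seq_len(p))
    m
  })
}

# Three-generation toy pedigree: o3's parents are half sibs through f1.
toy_pedigree <- function() {
  tibble::tibble(
    animal_id = c("f1", "f2", "f3", "o1", "o2", "o3"),
    sire_id = c(NA, NA, NA, "f1", "f1", "o1"),
    dam_id = c(NA, NA, NA, "f2", "f3", "o2")
  )
}

# Monte-Carlo gene-dropping kinship (probability two random alleles are IBD),
# an oracle for the tabular A matrix: A = 2 * kinship.
gene_drop_kinship <- function(ped, n_rep = 2e4, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(ped)
    si <- match(ped$sire_id, ped$animal_id)
    di <- match(ped$dam_id, ped$animal_id)
    a1 <- matrix(0L, n_rep, n)
    a2 <- matrix(0L, n_rep, n)
    next_allele <- 0L
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        a1[, i] <- next_allele + 1L
        a2[, i] <- next_allele + 2L
        next_allele <- next_allele + 2L
      } else {
        pick1 <- stats::runif(n_rep) < 0.5
        pick2 <- stats::runif(n_rep) < 0.5
        a1[, i] <- ifelse(pick1, a1[, si[i]], a2[, si[i]])
        a2[, i] <- ifelse(pick2, a1[, di[i]], a2[, di[i]])
      }
    }
    K <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        K[i, j] <- mean(
          (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
            (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
        ) / 4
      }
    }
    K
  })
}

# Dense-matrix restricted log-likelihood of y = 1*mu + u + e, the
# independent oracle for the eigen-rotated evaluation.
dense_reml_loglik <- function(y, G, sigma_u2, sigma_e2) {
  n <- length(y)
  V <- sigma_u2 * G + diag(sigma_e2, n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- drop(t(X) %*% Vi %*% X)
  mu <- drop(t(X) %*% Vi %*% y) / XtViX
  r <- y - mu
  -0.5 * ((n - 1) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
    log(XtViX) + drop(t(r) %*% Vi %*% r))
}

small_sim_config <- function(seed = 7, ...) {
  sim_config(
    population_sizes = c(A = 25, B = 28, C = 22, D = 30, E = 35),
    n_snps = 250, n_qtl = 40, seed = seed, ...
  )
}
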