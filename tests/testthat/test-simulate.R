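test_that("founder frequencies follow the drift model's first two moments", {
  # near-zero drift: population frequencies collapse onto the ancestral ones
  fr <- draw_founder_frequencies(500, fst = c(1e-9, 1e-9), seed = 42)
  expect_lt(mean(abs(fr$freq[, 1] - fr$ancestral)), 1e-3)
  expect_lt(mean(abs(fr$freq[, 2] - fr$ancestral)), 1e-3)

  # degenerate base interval pins the ancestral frequency
  fr0 <- draw_founder_frequencies(50, fst = 0.1, base_maf_range = c(0.5, 0.5), seed = 1)
  expect_equal(fr0$ancestral, rep(0.5, 50))

  # variance of drifted frequencies around ancestral ~ F p (1 - p)
  n_rep <- 60
  f <- 0.05
  dev2 <- vapply(seq_len(n_rep), function(r) {
    fr <- draw_founder_frequencies(1000, fst = f, seed = 1000 + r)
    mean((fr$freq[, 1] - fr$ancestral)^2 / (fr$ancestral * (1 - fr$ancestral)))
  }, numeric(1))
  expect_equal(mean(dev2), f, tolerance = 0.05)
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  ped <- random_mating_pedigree(c(A = 20, B = 20), n_generations = 2, seed = 5)
  g <- gene_drop(ped, draw_founder_frequencies(300, c(A = 0.05, B = 0.05), seed = 5)$freq, seed = 9)
  m <- unclass(g)
  si <- match(ped$sire_id, ped$animal_id)
  di <- match(ped$dam_id, ped$animal_id)
  off <- which(!is.na(si))
  # offspring dosage bounded by what the parents can transmit at every SNP
  lower <- (m[si[off], ] == 2) + (m[di[off], ] == 2)
  upper <- 2 - ((m[si[off], ] == 0) + (m[di[off], ] == 0))
  expect_true(all(m[off, ] >= lower & m[off, ] <= upper))

  g2 <- gene_drop(ped, draw_founder_frequencies(300, c(A = 0.05, B = 0.05), seed = 5)$freq, seed = 9)
  expect_identical(unclass(g), unclass(g2))
})

test_that("full sibs realize a mean genomic relationship near 0.5", {
  # two founders, many full-sib offspring, many SNPs
  n_sib <- 60
  ped <- tibble::tibble(
    animal_id = c("s", "d", sprintf("k%02d", seq_len(n_sib))),
    sire_id = c(NA, NA, rep("s", n_sib)),
    dam_id = c(NA, NA, rep("d", n_sib)),
    population = "A", generation = c(0, 0, rep(1, n_sib)), sex = "F"
  )
  freq <- draw_founder_frequencies(6000, c(A = 0.02), seed = 3)$freq
  g <- gene_drop(ped, freq, seed = 4)
  # use the founder-population frequencies for Z: within-group centering
  # would shift all sib-pair relationships downward
  m <- unclass(g[-(1:2), ])
  Z <- sweep(m, 2, 2 * freq[, "A"])
  Gp <- tcrossprod(Z) / (2 * sum(freq[, "A"] * (1 - freq[, "A"])))
  expect_equal(mean(Gp[upper.tri(Gp)]), 0.5, tolerance = 0.03)
})

test_that("phenotypes realize the configured heritability", {
  h2 <- 0.3
  reps <- 25
  real <- vapply(seq_len(reps), function(r) {
    g <- rand_geno(600, 400, seed = 100 + r)
    ph <- assign_phenotypes(g, n_qtl = 60, heritability = c(y = h2), seed = 200 + r)
    bv <- ph$true_breeding_values$y
    stats::var(bv) / stats::var(ph$phenotypes$y)
  }, numeric(1))
  expect_equal(mean(real), h2, tolerance = 0.03)

  # regression of phenotype on breeding value is 1 (unbiased additive model)
  g <- rand_geno(2000, 300, seed = 31)
  ph <- assign_phenotypes(g, 50, c(y = 0.3), seed = 32)
  slope <- stats::coef(stats::lm(ph$phenotypes$y ~ ph$true_breeding_values$y))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
})

test_that("heritability limits and single-QTL arithmetic are exact", {
  g <- rand_geno(50, 20, seed = 8)
  ph <- assign_phenotypes(g, 5, c(y = 0.999999), seed = 9)
  expect_equal(ph$phenotypes$y, ph$true_breeding_values$y, tolerance = 1e-2)

  ph1 <- assign_phenotypes(g, 1, c(y = 0.5), seed = 10)
  qtl <- unique(ph1$qtl_effects$snp_id)
  eff <- ph1$qtl_effects$effect
  x <- unclass(g)[, qtl]
  expect_equal(ph1$true_breeding_values$y, unname((x - mean(x)) * eff))

  expect_error(assign_phenotypes(g, 5, c(y = 1.5)), "heritability")
  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(n_qtl = 10, n_snps = 5), "n_qtl")
})

test_that("the default configuration yields 1609 animals in five populations", {
  cfg <- sim_config(n_snps = 200, n_qtl = 30, seed = 1)
  expect_equal(sum(cfg$population_sizes), 1609)
  st <- simulate_study(cfg, quiet = TRUE)
  expect_equal(nrow(st$genotypes), 1609)
  expect_equal(length(unique(populations(st$genotypes))), 5)
  expect_setequal(unique(populations(st$genotypes)), c("UK_1", "UK_2", "SWE", "IRL", "NLD"))
  # genotyped animals all appear in the pedigree
  expect_true(all(rownames(st$genotypes) %in% st$pedigree$animal_id))
})

test_that("simulation is bit-reproducible and drift separates a population on PC1", {
  cfg <- small_sim_config(seed = 21)
  s1 <- simulate_study(cfg, quiet = TRUE)
  s2 <- simulate_study(cfg, quiet = TRUE)
  expect_identical(unclass(s1$genotypes), unclass(s2$genotypes))
  expect_identical(s1$phenotypes, s2$phenotypes)

  cfg_drift <- sim_config(
    population_sizes = c(A = 40, B = 40, C = 40),
    n_snps = 400, n_qtl = 40, fst = c(0.02, 0.02, 0.15), seed = 13
  )
  st <- simulate_study(cfg_drift, quiet = TRUE)
  dec <- pc_decompose(center_genotypes(impute_missing(st$genotypes)), k = 2)
  pc1 <- dec$scores[, 1]
  pops <- populations(st$genotypes)
  gap <- abs(mean(pc1[pops == "C"]) - mean(pc1[pops != "C"]))
  spread <- max(stats::sd(pc1[pops == "C"]), stats::sd(pc1[pops != "C"]))
  expect_gt(gap, 2 * spread)
})
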