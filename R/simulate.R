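#' Configuration for a simulated multi-population study
#'
#' Defaults emulate a five-herd Holstein design: final-generation sizes
#' 206/210/181/394/618 (total 1609), a 50k-chip-like panel thinned to 5000
#' SNPs, three milk-production-like traits with heritabilities inside the
#' 0.13-0.59 band typical of pre-adjusted yield phenotypes, and modest
#' between-population differentiation (Fst 0.05) so populations are weakly
#' related but distinguishable on leading principal components.
#'
#' @param population_sizes Named integer vector of final-generation sizes.
#' @param n_snps Number of biallelic SNPs.
#' @param n_qtl Number of causal SNPs (subset of the panel).
#' @param fst Per-population differentiation in (0,1); recycled.
#' @param heritability Named per-trait heritability, each in (0,1).
#' @param n_generations Pedigree depth (random-mating generations after the
#'   founders), at least 1.
#' @param base_maf_range Interval within (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn (then mirrored at random).
#' @param missing_rate Fraction of genotype calls masked at random, in `[0,1)`.
#' @param migration Probability that a parent is drawn from another
#'   population, tuning between-population relationships (default 0).
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(population_sizes = c(UK_1 = 206, UK_2 = 210, SWE = 181, IRL = 394, NLD = 618),
                       n_snps = 5000,
                       n_qtl = 300,
                       fst = 0.05,
                       heritability = c(milk = 0.30, fat = 0.45, protein = 0.15),
                       n_generations = 3,
                       base_maf_range = c(0.05, 0.5),
                       missing_rate = 0,
                       migration = 0,
                       seed = 20260930) {
  if (is.null(names(population_sizes))) {
    names(population_sizes) <- sprintf("pop%d", seq_along(population_sizes))
  }
  if (any(population_sizes < 1)) stop("population sizes must be positive", call. = FALSE)
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps", call. = FALSE)
  fst <- rep_len(fst, length(population_sizes))
  if (any(fst <= 0) || any(fst >= 1)) stop("each fst must lie strictly in (0, 1)", call. = FALSE)
  if (any(heritability <= 0) || any(heritability >= 1)) {
    stop("heritability must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(names(heritability))) {
    names(heritability) <- sprintf("trait%d", seq_along(heritability))
  }
  if (n_generations < 1) stop("n_generations must be >= 1", call. = FALSE)
  if (length(base_maf_range) != 2 || base_maf_range[1] > base_maf_range[2] ||
    base_maf_range[1] <= 0 || base_maf_range[2] > 0.5) {
    stop("base_maf_range must be an interval within (0, 0.5]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(
    list(
      population_sizes = population_sizes, n_snps = n_snps, n_qtl = n_qtl,
      fst = fst, heritability = heritability, n_generations = n_generations,
      base_maf_range = base_maf_range, missing_rate = missing_rate,
      migration = migration, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw per-population allele frequencies under a drift model
#'
#' Ancestral frequencies are uniform on `base_maf_range`, mirrored to the
#' upper half at random. Each population's frequency is then Beta-distributed
#' with mean p and variance F p(1-p) (the Balding-Nichols construction), so
#' F acts as the Fst-style differentiation of that population.
#'
#' @param n_snps Number of SNPs.
#' @param fst Differentiation per population, each in (0,1).
#' @param base_maf_range Interval within (0, 0.5].
#' @param seed Integer seed.
#' @return List with `ancestral` (length `n_snps`) and `freq`, an
#'   `n_snps` x `n_populations` matrix of allele-2 frequencies.
#' @export
draw_founder_frequencies <- function(n_snps, fst, base_maf_range = c(0.05, 0.5), seed = 1) {
  if (any(fst <= 0) || any(fst >= 1)) stop("each fst must lie strictly in (0, 1)", call. = FALSE)
  if (length(base_maf_range) != 2 || base_maf_range[1] > base_maf_range[2]) {
    stop("base_maf_range must be a nonempty interval", call. = FALSE)
  }
  withr::with_seed(seed, {
    p0 <- stats::runif(n_snps, base_maf_range[1], base_maf_range[2])
    flip <- stats::runif(n_snps) < 0.5
    p0[flip] <- 1 - p0[flip]
    freq <- vapply(fst, function(f) {
      a <- p0 * (1 - f) / f
      b <- (1 - p0) * (1 - f) / f
      pmin(pmax(stats::rbeta(n_snps, a, b), 1e-6), 1 - 1e-6)
    }, numeric(n_snps))
    if (is.null(names(fst))) colnames(freq) <- sprintf("pop%d", seq_along(fst))
    rownames(freq) <- sprintf("snp_%d", seq_len(n_snps))
    list(ancestral = p0, freq = freq)
  })
}

#' Random-mating multi-population pedigree
#'
#' Founders (generation 0) are unrelated within and across populations; each
#' later generation is produced by sampling a sire and a dam from the previous
#' generation of the same population (or, with probability `migration`, from
#' another population). Generation sizes equal the final population sizes.
#'
#' @inheritParams sim_config
#' @return Tibble with columns `animal_id`, `sire_id`, `dam_id`,
#'   `population`, `generation`, `sex`.
#' @export
random_mating_pedigree <- function(population_sizes, n_generations = 3, migration = 0, seed = 1) {
  if (is.null(names(population_sizes))) {
    names(population_sizes) <- sprintf("pop%d", seq_along(population_sizes))
  }
  pops <- names(population_sizes)
  withr::with_seed(seed, {
    recs <- list()
    prev <- NULL
    for (g in 0:n_generations) {
      gen <- purrr::map_dfr(pops, function(pk) {
        nk <- population_sizes[[pk]]
        id <- sprintf("%s_G%d_%03d", pk, g, seq_len(nk))
        sex <- rep_len(c("M", "F"), nk)
        if (g == 0) {
          tibble::tibble(
            animal_id = id, sire_id = NA_character_, dam_id = NA_character_,
            population = pk, generation = g, sex = sex
          )
        } else {
          pick <- function(want_sex) {
            vapply(seq_len(nk), function(i) {
              src <- if (migration > 0 && stats::runif(1) < migration) {
                sample(setdiff(pops, pk), 1)
              } else {
                pk
              }
              pool <- prev$animal_id[prev$population == src & prev$sex == want_sex]
              sample(pool, 1)
            }, character(1))
          }
          tibble::tibble(
            animal_id = id, sire_id = pick("M"), dam_id = pick("F"),
            population = pk, generation = g, sex = sex
          )
        }
      })
      recs[[g + 1]] <- gen
      prev <- gen
    }
    dplyr::bind_rows(recs)
  })
}

#' Drop genes through a pedigree
#'
#' Founders draw two alleles per SNP from their population's allele
#' frequency; every non-founder inherits one uniformly chosen allele from
#' each parent, independently across SNPs (no linkage map). Pedigree rows
#' must be sorted so that parents precede offspring.
#'
#' @param pedigree Tibble as from [random_mating_pedigree()].
#' @param founder_freq SNP x population frequency matrix
#'   (`draw_founder_frequencies()$freq`).
#' @param seed Integer seed.
#' @param missing_rate Fraction of calls masked at random.
#' @return A [geno_matrix()] covering every pedigree animal.
#' @export
gene_drop <- function(pedigree, founder_freq, seed = 1, missing_rate = 0) {
  n <- nrow(pedigree)
  p <- nrow(founder_freq)
  idx <- seq_len(n)
  names(idx) <- pedigree$animal_id
  si <- idx[pedigree$sire_id]
  di <- idx[pedigree$dam_id]
  founder <- is.na(pedigree$sire_id) & is.na(pedigree$dam_id)
  if (any(xor(is.na(pedigree$sire_id), is.na(pedigree$dam_id)))) {
    stop("pedigree animals must have both parents known or both unknown", call. = FALSE)
  }
  if (any(!founder & (is.na(si) | is.na(di)))) {
    stop("pedigree refers to unknown parent ids", call. = FALSE)
  }
  if (any(!founder & (si >= idx | di >= idx))) {
    stop("pedigree not sorted: parents must precede offspring", call. = FALSE)
  }
  withr::with_seed(seed, {
    G <- matrix(0L, n, p, dimnames = list(pedigree$animal_id, rownames(founder_freq)))
    fpop <- pedigree$population[founder]
    for (pk in unique(fpop)) {
      rows <- which(founder)[fpop == pk]
      G[rows, ] <- matrix(
        stats::rbinom(length(rows) * p, 2L, rep(founder_freq[, pk], each = length(rows))),
        length(rows), p
      )
    }
    for (g in sort(unique(pedigree$generation[!founder]))) {
      rows <- which(!founder & pedigree$generation == g)
      S <- G[si[rows], , drop = FALSE]
      D <- G[di[rows], , drop = FALSE]
      a1 <- matrix(stats::rbinom(length(S), 1L, S / 2), nrow(S))
      a2 <- matrix(stats::rbinom(length(D), 1L, D / 2), nrow(D))
      G[rows, ] <- a1 + a2
    }
    if (missing_rate > 0) {
      G[matrix(stats::runif(length(G)) < missing_rate, nrow(G))] <- NA_integer_
    }
    geno_matrix(G, pedigree$population, validate = FALSE)
  })
}

#' Assign additive phenotypes from genotypes
#'
#' Samples `n_qtl` causal SNPs without replacement, draws i.i.d. standard
#' normal effects per trait, sets the breeding value to the centered QTL
#' genotypes times the effects, and adds normal residuals scaled so that
#' var(bv)/var(phenotype) equals the target heritability.
#'
#' @param genotypes Complete (no missing) [geno_matrix()].
#' @param n_qtl Number of causal SNPs.
#' @param heritability Named per-trait heritabilities in (0,1).
#' @param seed Integer seed.
#' @return List with tibbles `true_breeding_values` and `phenotypes`
#'   (columns `animal_id`, `population`, one per trait) and `qtl_effects`
#'   (`snp_id`, `trait`, `effect`).
#' @export
assign_phenotypes <- function(genotypes, n_qtl, heritability, seed = 1) {
  if (any(heritability <= 0) || any(heritability >= 1)) {
    stop("heritability must lie strictly in (0, 1)", call. = FALSE)
  }
  if (anyNA(genotypes)) stop("genotypes must be complete; impute first", call. = FALSE)
  if (n_qtl > ncol(genotypes)) stop("n_qtl must not exceed the number of SNPs", call. = FALSE)
  if (is.null(names(heritability))) {
    names(heritability) <- sprintf("trait%d", seq_along(heritability))
  }
  traits <- names(heritability)
  withr::with_seed(seed, {
    qtl <- sort(sample.int(ncol(genotypes), n_qtl))
    Xq <- unclass(genotypes)[, qtl, drop = FALSE]
    Zq <- sweep(Xq, 2, colMeans(Xq))
    effects <- matrix(stats::rnorm(n_qtl * length(traits)), n_qtl,
      dimnames = list(colnames(Xq), traits)
    )
    bv <- Zq %*% effects
    pheno <- bv
    for (t in traits) {
      h2 <- heritability[[t]]
      v_bv <- stats::var(bv[, t])
      sd_e <- sqrt(v_bv * (1 - h2) / h2)
      pheno[, t] <- bv[, t] + stats::rnorm(nrow(bv), 0, sd_e)
    }
    base <- tibble::tibble(
      animal_id = rownames(genotypes),
      population = unname(populations(genotypes))
    )
    list(
      true_breeding_values = dplyr::bind_cols(base, tibble::as_tibble(bv)),
      phenotypes = dplyr::bind_cols(base, tibble::as_tibble(pheno)),
      qtl_effects = tibble::as_tibble(effects) |>
        dplyr::mutate(snp_id = colnames(Xq), .before = 1) |>
        tidyr::pivot_longer(-"snp_id", names_to = "trait", values_to = "effect")
    )
  })
}

#' Simulate a complete multi-population study
#'
#' Composes [draw_founder_frequencies()], [random_mating_pedigree()],
#' [gene_drop()] and [assign_phenotypes()]. Phenotypes are generated from the
#' complete genotypes; the missingness mask is applied afterwards to the
#' returned genotype matrix of the final (genotyped) generation.
#'
#' @param config A [sim_config()].
#' @param quiet Suppress the summary message.
#' @return A `sim_study` list: `config`, `pedigree`, `genotypes` (final
#'   generation), `founder_freq`, `true_breeding_values`, `phenotypes`,
#'   `qtl_effects`.
#' @export
simulate_study <- function(config = sim_config(), quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  fst <- config$fst
  names(fst) <- names(config$population_sizes)
  freqs <- draw_founder_frequencies(config$n_snps, fst, config$base_maf_range, seed = seed)
  ped <- random_mating_pedigree(config$population_sizes, config$n_generations,
    migration = config$migration, seed = seed + 1L
  )
  geno_all <- gene_drop(ped, freqs$freq, seed = seed + 2L, missing_rate = 0)
  final <- ped$generation == config$n_generations
  geno <- geno_all[which(final), ]
  ph <- assign_phenotypes(geno, config$n_qtl, config$heritability, seed = seed + 3L)
  if (config$missing_rate > 0) {
    masked <- unclass(geno)
    withr::with_seed(seed + 4L, {
      masked[matrix(stats::runif(length(masked)) < config$missing_rate, nrow(masked))] <- NA_integer_
    })
    geno <- new_geno_matrix(masked, populations(geno))
  }
  study <- structure(
    list(
      config = config, pedigree = ped, genotypes = geno,
      founder_freq = freqs,
      true_breeding_values = ph$true_breeding_values,
      phenotypes = ph$phenotypes, qtl_effects = ph$qtl_effects
    ),
    class = "sim_study"
  )
  if (!quiet) {
    message(sprintf(
      "simulated %d animals in %d populations; %d SNPs (%d QTL), %d pedigree records",
      nrow(geno), length(config$population_sizes), config$n_snps, config$n_qtl, nrow(ped)
    ))
  }
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "<sim_study> %d genotyped animals, %d SNPs, traits: %s\n",
    nrow(x$genotypes), ncol(x$genotypes),
    paste(names(x$config$heritability), collapse = ", ")
  ))
  print(x$genotypes)
  invisible(x)
}
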