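test_that("the rotated restricted likelihood matches a dense evaluation", {
  g <- rand_geno(40, 120, seed = 31)
  G <- vanraden_G(g)$G
  G <- G + diag(1e-6, 40) # keep the dense solve well-posed
  y <- withr::with_seed(32, stats::rnorm(40))
  ee <- eigen(G, symmetric = TRUE)
  withr::with_seed(33, {
    for (i in 1:10) {
      su <- stats::runif(1, 0.05, 3)
      se <- stats::runif(1, 0.05, 3)
      expect_equal(reml_loglik(y, ee, su, se), dense_reml_loglik(y, G, su, se),
        tolerance = 1e-8
      )
    }
  })
})

test_that("REML finds the restricted-likelihood optimum", {
  g <- rand_geno(80, 300, seed = 34)
  ph <- assign_phenotypes(g, 50, c(y = 0.4), seed = 35)
  y <- ph$phenotypes$y
  G <- vanraden_G(g)$G
  fit <- reml_fit(y, G)
  expect_true(fit$converged)
  ee <- eigen(G, symmetric = TRUE)
  withr::with_seed(36, {
    for (i in 1:20) {
      su <- stats::runif(1, 0.01, 5) * stats::var(y)
      se <- stats::runif(1, 0.01, 5) * stats::var(y)
      expect_gte(fit$loglik, reml_loglik(y, ee, su, se) - 1e-6)
    }
  })
  # and it beats small perturbations of its own optimum
  expect_gte(fit$loglik, reml_loglik(y, ee, fit$sigma_u2 * 1.05, fit$sigma_e2) - 1e-9)
})

test_that("pure noise drives the genetic variance to the boundary", {
  g <- rand_geno(150, 400, seed = 37)
  G <- vanraden_G(g)$G
  y <- withr::with_seed(38, stats::rnorm(150))
  fit <- reml_fit(y, G)
  expect_lt(fit$heritability, 0.1)
  gebv <- predict_gebv(fit, G, rownames(g), rownames(g), y)
  expect_lt(stats::sd(gebv$gebv), 0.25 * stats::sd(y))

  # exactly zero genetic variance gives exactly constant predictions
  fit0 <- fit
  fit0$sigma_u2 <- 0
  expect_equal(predict_gebv(fit0, G, rownames(g), rownames(g)[1:5], y)$gebv, rep(0, 5))
})

test_that("a single REML fit recovers a simulated heritability", {
  g <- rand_geno(400, 1500, seed = 39)
  ph <- assign_phenotypes(g, 150, c(y = 0.3), seed = 40)
  fit <- reml_fit(ph$phenotypes$y, vanraden_G(g)$G)
  expect_lt(abs(fit$heritability - 0.3), 0.1)
})

test_that("GBLUP predictions equal SNP-BLUP ridge predictions", {
  n_r <- 60
  n_t <- 20
  g <- rand_geno(n_r + n_t, 120, seed = 41)
  gv <- vanraden_G(g)
  denom <- 2 * sum(gv$allele_freq * (1 - gv$allele_freq))
  Z <- sweep(unclass(g), 2, 2 * gv$allele_freq)
  ref <- rownames(g)[1:n_r]
  tst <- rownames(g)[-(1:n_r)]
  y <- withr::with_seed(42, drop(Z[1:n_r, ] %*% stats::rnorm(120, sd = 0.1)) + stats::rnorm(n_r))
  su <- 0.8
  se <- 1.3
  Vrr <- su * gv$G[ref, ref] + diag(se, n_r)
  mu_gls <- sum(solve(Vrr, y)) / sum(solve(Vrr, rep(1, n_r)))
  fit <- structure(list(sigma_u2 = su, sigma_e2 = se, mu = mu_gls), class = "greml_fit")
  gebv <- predict_gebv(fit, gv$G, ref, tst, y)
  ridge <- snp_blup(Z[1:n_r, ], y, lambda = denom * se / su, Z[-(1:n_r), ])
  expect_equal(mu_gls + gebv$gebv, unname(ridge$predictions), tolerance = 1e-6)
  expect_equal(unname(ridge$mu), mu_gls, tolerance = 1e-6)
})

test_that("reference-animal predictions equal the mixed-model-equation solutions", {
  g <- rand_geno(50, 200, seed = 43)
  G <- vanraden_G(g)$G + diag(1e-4, 50)
  ph <- assign_phenotypes(g, 40, c(y = 0.4), seed = 44)
  y <- ph$phenotypes$y
  fit <- reml_fit(y, G)
  u_v <- predict_gebv(fit, G, rownames(g), rownames(g), y)$gebv
  # Henderson form: (I + (se/su) G^-1) u = y - mu
  u_mme <- solve(
    diag(50) + (fit$sigma_e2 / fit$sigma_u2) * solve(G),
    y - fit$mu
  )
  expect_equal(u_v, unname(u_mme), tolerance = 1e-6)

  # invariance under joint permutation
  perm <- withr::with_seed(45, sample(50))
  u_p <- predict_gebv(fit, G[perm, perm], rownames(g)[perm], rownames(g), y[perm])
  expect_equal(
    u_p$gebv[match(rownames(g), u_p$animal_id)],
    u_v,
    tolerance = 1e-8
  )
})

test_that("ridge limits behave: infinite shrinkage to the mean, none to OLS", {
  g <- rand_geno(50, 10, seed = 46)
  Xc <- scale(unclass(g), scale = FALSE)
  y <- withr::with_seed(47, stats::rnorm(50))
  big <- snp_blup(Xc[1:40, ], y[1:40], lambda = 1e12, Xc[41:50, ])
  expect_equal(unname(big$predictions), rep(mean(y[1:40]), 10), tolerance = 1e-6)

  tiny <- snp_blup(Xc[1:40, ], y[1:40], lambda = 1e-10, Xc[41:50, ])
  ls <- stats::lm.fit(cbind(1, Xc[1:40, ]), y[1:40])
  expect_equal(unname(tiny$predictions),
    unname(drop(cbind(1, Xc[41:50, ]) %*% ls$coefficients)),
    tolerance = 1e-5
  )
})

test_that("mild blending toward A barely changes test predictions", {
  cfg <- small_sim_config(seed = 48)
  st <- simulate_study(cfg, quiet = TRUE)
  g <- impute_missing(st$genotypes)
  A <- pedigree_A(st$pedigree)[rownames(g), rownames(g)]
  Gvr <- vanraden_G(g)$G
  pops <- populations(g)
  ref <- rownames(g)[pops != "A"]
  tst <- rownames(g)[pops == "A"]
  y <- stats::setNames(st$phenotypes$milk, st$phenotypes$animal_id)[ref]
  pred_for <- function(b) {
    G <- blend_G(Gvr, A, b)
    fit <- reml_fit(y, G[ref, ref])
    predict_gebv(fit, G, ref, tst, y)$gebv
  }
  expect_gt(stats::cor(pred_for(1), pred_for(0.99)), 0.99)
})
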