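test_that("centering uses the defining set and reapplies its centers elsewhere", {
  g <- geno_matrix(matrix(c(0L, 2L, 2L, 0L), 2, dimnames = list(c("a", "b"), c("s1", "s2"))))
  xc <- center_genotypes(g)
  expect_equal(attr(xc, "centers"), c(s1 = 1, s2 = 1))
  expect_equal(unclass(xc), matrix(c(-1, 1, 1, -1), 2), ignore_attr = TRUE)

  gg <- rand_geno(12, 6, seed = 4)
  ref <- rownames(gg)[1:8]
  xc2 <- center_genotypes(gg, defining_ids = ref)
  manual <- sweep(unclass(gg), 2, colMeans(unclass(gg)[ref, ]))
  expect_equal(unclass(xc2), manual, ignore_attr = TRUE)
  # defining-set columns have mean zero
  expect_lt(max(abs(colMeans(unclass(xc2)[1:8, ]))), 1e-12)

  # constant column dropped with a warning when scaling
  m <- unclass(gg)
  m[, 2] <- 1L
  expect_warning(xs <- center_genotypes(geno_matrix(m), scale = TRUE), "constant")
  expect_equal(ncol(xs), 5)
})

test_that("a rank-1 matrix decomposes as computed by hand", {
  xc <- structure(matrix(c(-1, 1, 1, -1), 2),
    centers = c(1, 1), scales = NULL,
    class = c("centered_geno", "matrix", "array")
  )
  dec <- pc_decompose(xc)
  expect_equal(dec$rank, 1)
  expect_equal(dec$d, 2)
  expect_equal(dec$variance_prop, 1)
  # sign convention: first (largest-magnitude) loading entry positive
  expect_equal(unname(dec$v[, 1]), c(1, -1) / sqrt(2))
  expect_equal(unname(dec$scores[, 1]), c(-sqrt(2), sqrt(2)))
})

test_that("scores are orthogonal and reconstruct the input at full rank", {
  g <- rand_geno(25, 40, seed = 6)
  dec <- pc_decompose(center_genotypes(g))
  TtT <- crossprod(dec$scores)
  expect_lt(max(abs(TtT - diag(dec$d[seq_len(dec$k)]^2))), 1e-8)
  expect_lt(max(abs(unclass(center_genotypes(g)) - dec$scores %*% t(dec$v))), 1e-8)
  # score columns also have mean zero (column-centered input)
  expect_lt(max(abs(colMeans(dec$scores))) / dec$d[1], 1e-10)
})

test_that("the decomposition agrees with an eigendecomposition of the covariance", {
  for (s in 1:5) {
    n <- sample(10:50, 1)
    p <- sample(10:80, 1)
    g <- rand_geno(n, p, seed = 100 + s)
    xc <- center_genotypes(g)
    dec <- pc_decompose(xc)
    ee <- eigen(crossprod(unclass(xc)), symmetric = TRUE)
    for (j in seq_len(min(dec$k, 5))) {
      v_o <- ee$vectors[, j]
      if (sum(v_o * dec$v[, j]) < 0) v_o <- -v_o
      expect_lt(max(abs(dec$v[, j] - v_o)), 1e-6)
      expect_equal(dec$d[j]^2, ee$values[j], tolerance = 1e-8)
    }
  }
})

test_that("projection is consistent with the decomposition's own scores", {
  g <- rand_geno(20, 30, seed = 7)
  xc <- center_genotypes(g, defining_ids = rownames(g)[1:15])
  dec <- pc_decompose(xc[1:15, ])
  # projecting the defining rows reproduces the scores (relative scale)
  expect_lt(max(abs(pc_project(dec, xc[1:15, ]) - dec$scores)) / dec$d[1], 1e-10)
  # a test row equal to a reference row gets the same score row
  x_dup <- xc[c(3, 3), ]
  proj <- pc_project(dec, x_dup)
  expect_equal(proj[1, ], proj[2, ])
  expect_lt(max(abs(proj[1, ] - dec$scores[3, ])) / dec$d[1], 1e-10)
  # a row at the defining mean projects to zero
  zero_row <- xc[1, , drop = FALSE]
  zero_row[1, ] <- 0
  expect_equal(unname(pc_project(dec, zero_row)[1, ]), rep(0, dec$k))
  expect_error(pc_project(dec, xc[1:2, 1:5]), "column count")
})

test_that("semi-supervised decomposition degenerates and permutes correctly", {
  g <- rand_geno(18, 25, seed = 8, pops = rep(c("A", "B"), 9))
  # empty test set: identical to the plain reference decomposition
  ss <- pc_decompose_ss(g, rownames(g), character(0))
  dec <- pc_decompose(center_genotypes(g))
  expect_equal(ss$decomposition$v, dec$v)
  expect_equal(ss$T_r, dec$scores)
  expect_equal(nrow(ss$T_t), 0)

  ref <- rownames(g)[1:12]
  tst <- rownames(g)[13:18]
  ss1 <- pc_decompose_ss(g, ref, tst)
  perm <- c(5:18, 1:4)
  ss2 <- pc_decompose_ss(g[perm, ], ref, tst)
  expect_equal(ss1$T_r, ss2$T_r, tolerance = 1e-8)
  expect_equal(ss1$T_t, ss2$T_t, tolerance = 1e-8)
  expect_error(pc_decompose_ss(g, ref, c(tst, ref[1])), "overlap")
  expect_error(pc_decompose_ss(g, ref, tst[-1]), "cover")
})

test_that("cumulative variance is nondecreasing and reaches 1 at full rank", {
  g <- rand_geno(15, 10, seed = 9)
  dec <- pc_decompose(center_genotypes(g))
  cv <- cumulative_variance(dec)
  expect_true(all(diff(cv$cumulative_proportion) >= -1e-12))
  expect_equal(cv$cumulative_proportion[dec$rank], 1)

  # equal singular values: proportions k / r
  xc_id <- structure(diag(4) - 0.25,
    centers = rep(0.25, 4),
    class = c("centered_geno", "matrix", "array")
  )
  dec_id <- pc_decompose(xc_id)
  cv_id <- cumulative_variance(dec_id)
  expect_equal(cv_id$cumulative_proportion, seq_len(dec_id$rank) / dec_id$rank)
})
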