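# Restricted log-likelihood pieces in the eigenbasis of G.
# With V = sigma_u2 * G + sigma_e2 * I = Q (sigma_u2 L + sigma_e2 I) Q',
# the rotation y* = Q'y, x* = Q'1 makes every REML quantity a sum over
# eigenvalues; no dense solve is ever needed.
reml_rotated_parts <- function(ys, xs, lambda, sigma_u2, sigma_e2) {
  d <- sigma_u2 * lambda + sigma_e2
  sxx <- sum(xs^2 / d)
  mu <- sum(xs * ys / d) / sxx
  rss <- sum((ys - xs * mu)^2 / d)
  list(d = d, sxx = sxx, mu = mu, rss = rss)
}

#' Restricted log-likelihood of the one-random-effect animal model
#'
#' Evaluates the REML log-likelihood of `y = 1 mu + u + e`,
#' `u ~ N(0, G sigma_u2)`, `e ~ N(0, I sigma_e2)` at given variance
#' components, through the eigendecomposition of `G` (the fixed intercept is
#' profiled out analytically). Includes all constants, so the value is
#' directly comparable with a dense evaluation of the restricted likelihood.
#'
#' @param y Phenotype vector.
#' @param G Relationship matrix (symmetric PSD), or the precomputed
#'   `eigen(G, symmetric = TRUE)` for repeated evaluation.
#' @param sigma_u2,sigma_e2 Variance components (`sigma_e2 > 0`).
#' @return Restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, G, sigma_u2, sigma_e2) {
  ee <- if (is.list(G) && !is.null(G$vectors)) G else eigen(G, symmetric = TRUE)
  n <- length(y)
  ys <- drop(crossprod(ee$vectors, y))
  xs <- colSums(ee$vectors)
  parts <- reml_rotated_parts(ys, xs, pmax(ee$values, 0), sigma_u2, sigma_e2)
  -0.5 * ((n - 1) * log(2 * pi) + sum(log(parts$d)) + log(parts$sxx) + parts$rss)
}

#' REML fit of the one-random-effect animal model
#'
#' Maximises the restricted likelihood of `y = 1 mu + u + e` over
#' `(sigma_u2, sigma_e2)`. The eigendecomposition of `G` reduces the problem
#' to a one-dimensional profiled search over the variance ratio
#' `theta = sigma_u2 / sigma_e2` (Brent's method, tolerance 1e-8), with the
#' intercept and the residual scale profiled out analytically. A boundary
#' estimate `sigma_u2 = 0` is permitted and flagged.
#'
#' @param y Reference phenotypes.
#' @param G Relationship matrix of the same animals (symmetric; eigenvalues
#'   may dip to `-1e-6` times the largest and are clipped to zero, anything
#'   lower is an error).
#' @param theta_max Upper search bound for the variance ratio (default 1e4).
#' @param tol Brent tolerance on the ratio (default 1e-8).
#' @return A `greml_fit`: `sigma_u2`, `sigma_e2`, `mu`, `heritability`,
#'   `loglik`, `theta`, `boundary`, `converged`, `n_iterations`, `n`.
#' @export
reml_fit <- function(y, G, theta_max = 1e4, tol = 1e-8) {
  n <- length(y)
  if (nrow(G) != n) stop("G and y are misaligned", call. = FALSE)
  ee <- eigen(G, symmetric = TRUE)
  lmax <- max(abs(ee$values), 1)
  if (min(ee$values) < -1e-6 * lmax) {
    stop("G is not positive semidefinite beyond jitter tolerance", call. = FALSE)
  }
  lambda <- pmax(ee$values, 0)
  ys <- drop(crossprod(ee$vectors, y))
  xs <- colSums(ee$vectors)
  evals <- 0L
  profile_ll <- function(theta) {
    evals <<- evals + 1L
    w <- theta * lambda + 1
    sxx <- sum(xs^2 / w)
    mu <- sum(xs * ys / w) / sxx
    rss <- sum((ys - xs * mu)^2 / w)
    s2e <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2e) + sum(log(w)) +
      log(sxx) + (n - 1))
    list(ll = ll, mu = mu, s2e = s2e)
  }
  opt <- stats::optimize(function(th) profile_ll(th)$ll,
    interval = c(0, theta_max), maximum = TRUE, tol = tol
  )
  at0 <- profile_ll(0)
  theta <- opt$maximum
  ll <- opt$objective
  boundary <- FALSE
  if (at0$ll >= ll || theta < 1e-10) {
    theta <- 0
    ll <- at0$ll
    boundary <- TRUE
  }
  sol <- profile_ll(theta)
  sigma_e2 <- sol$s2e
  sigma_u2 <- theta * sigma_e2
  if (sigma_u2 < 1e-10) {
    sigma_u2 <- 0
    boundary <- TRUE
  }
  structure(
    list(
      sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, mu = sol$mu,
      heritability = sigma_u2 / (sigma_u2 + sigma_e2),
      loglik = ll, theta = theta, boundary = boundary,
      converged = TRUE, n_iterations = evals, n = n
    ),
    class = "greml_fit"
  )
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf(
    "<greml_fit> sigma_u2 = %.4g, sigma_e2 = %.4g (h2 = %.3f)%s\n",
    x$sigma_u2, x$sigma_e2, x$heritability,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' @export
tidy.greml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_u2", "sigma_e2", "mu"),
    estimate = c(x$sigma_u2, x$sigma_e2, x$mu)
  )
}

#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(
    heritability = x$heritability, logLik = x$loglik,
    converged = x$converged, boundary = x$boundary,
    n_iterations = x$n_iterations, nobs = x$n
  )
}

#' Predict genomic breeding values from a GREML fit
#'
#' Best linear unbiased prediction under the fitted model:
#' `u_hat = sigma_u2 * G[, ref] V_rr^{-1} (y_r - 1 mu_hat)` with
#' `V_rr = sigma_u2 G_rr + sigma_e2 I`. Reference-animal entries equal the
#' mixed-model-equation solutions.
#'
#' @param fit A [reml_fit()] result.
#' @param G Relationship matrix over reference and test animals, with animal
#'   ids as dimnames.
#' @param reference_ids,test_ids Animal id vectors (rows of `G`).
#' @param y_r Reference phenotypes, aligned with `reference_ids`.
#' @return Tibble (`animal_id`, `gebv`, `model = "greml"`) for `test_ids`.
#' @export
predict_gebv <- function(fit, G, reference_ids, test_ids, y_r) {
  ref <- match(reference_ids, rownames(G))
  tst <- match(test_ids, rownames(G))
  if (anyNA(ref) || anyNA(tst)) stop("ids missing from G", call. = FALSE)
  if (fit$sigma_e2 <= 0) stop("residual variance must be positive", call. = FALSE)
  r <- y_r - fit$mu
  if (fit$sigma_u2 == 0) {
    u <- rep(0, length(tst))
  } else {
    Vrr <- fit$sigma_u2 * G[ref, ref] + diag(fit$sigma_e2, length(ref))
    alpha <- solve(Vrr, r)
    u <- drop(fit$sigma_u2 * G[tst, ref, drop = FALSE] %*% alpha)
  }
  tibble::tibble(animal_id = test_ids, gebv = unname(u), model = "greml")
}

#' Ridge-regression (SNP-BLUP) predictions
#'
#' Penalised least squares for SNP effects with an unpenalised intercept:
#' the independent formulation whose predictions coincide with GBLUP when
#' `G = Z Z' / c` and `lambda = c * sigma_e2 / sigma_u2`.
#'
#' @param x_train Centered genotype matrix of the training animals.
#' @param y Training phenotypes.
#' @param lambda Ridge penalty (> 0).
#' @param x_test Centered genotype matrix of the animals to predict.
#' @return A `snp_blup` list: `mu`, `effects`, `predictions`.
#' @export
snp_blup <- function(x_train, y, lambda, x_test) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  Xtr <- cbind(1, unclass(x_train))
  M <- crossprod(Xtr)
  diag(M)[-1] <- diag(M)[-1] + lambda
  beta <- solve(M, crossprod(Xtr, y))
  preds <- drop(cbind(1, unclass(x_test)) %*% beta)
  structure(
    list(mu = beta[1], effects = drop(beta[-1]), predictions = preds),
    class = "snp_blup"
  )
}
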