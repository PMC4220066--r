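#' Rank principal components by eigenvalue
#'
#' Components are returned in order of nonincreasing singular value, ties
#' broken by original index — for a sorted decomposition this is the
#' identity order.
#'
#' @param decomp A [pc_decompose()] result.
#' @return A `pc_ranking`: list with `criterion = "eigen"` and `order`.
#' @export
rank_eigen <- function(decomp) {
  d <- decomp$d[seq_len(decomp$k)]
  structure(
    list(criterion = "eigen", order = order(-d, seq_along(d)), ss = NULL),
    class = "pc_ranking"
  )
}

#' Rank principal components by regression sum of squares
#'
#' For each component j the contribution is `(t_j' y~)^2 / (t_j' t_j)` with
#' `t_j` the mean-centered score column and `y~` the mean-centered
#' phenotype. When score columns are mutually orthogonal (always true on the
#' set that defined the decomposition) this equals the regression sum of
#' squares attributable to the component regardless of entry order. Ordering
#' is by nonincreasing contribution, ties by index; zero-variance columns
#' contribute 0.
#'
#' @param scores Score matrix of the reference animals.
#' @param y Phenotypes aligned with `scores` rows (at least 2).
#' @return A `pc_ranking` with `criterion = "ss"` and the per-component
#'   contributions in `ss`.
#' @export
rank_ss <- function(scores, y) {
  if (nrow(scores) != length(y)) stop("scores and phenotypes are misaligned", call. = FALSE)
  if (length(y) < 2) stop("need at least two animals", call. = FALSE)
  tc <- sweep(scores, 2, colMeans(scores))
  yt <- y - mean(y)
  tt <- colSums(tc^2)
  ss <- drop(crossprod(tc, yt))^2 / tt
  ss[tt <= .Machine$double.eps * max(tt, 1)] <- 0
  structure(
    list(criterion = "ss", order = order(-ss, seq_along(ss)), ss = unname(ss)),
    class = "pc_ranking"
  )
}

#' Fit a fixed-effect principal-component regression
#'
#' Ordinary least squares of `y` on an intercept plus the first `k`
#' components of a ranking: `y = 1 mu + T g + e`, the component effects
#' treated as fixed (no shrinkage). `k = 0` is the null model, in which
#' every animal receives the reference mean.
#'
#' @param scores Reference score matrix.
#' @param y Reference phenotypes.
#' @param ranking A `pc_ranking` (default: eigen order, i.e. column order).
#' @param k Number of components to include, `0 <= k < n - 1`.
#' @return A `pcr_model`: `mu`, `coefficients` (named by component),
#'   `pc_ids`, `k`, `fitted`, `residuals`.
#' @export
fit_pcr <- function(scores, y, ranking = NULL, k) {
  n <- length(y)
  if (nrow(scores) != n) stop("scores and phenotypes are misaligned", call. = FALSE)
  ord <- if (is.null(ranking)) seq_len(ncol(scores)) else ranking$order
  if (k < 0 || k > length(ord)) stop("k out of range", call. = FALSE)
  if (k > n - 1) stop("k exceeds the degrees of freedom (n - 1)", call. = FALSE)
  pcs <- ord[seq_len(k)]
  if (k == 0) {
    mu <- mean(y)
    fit <- list(mu = mu, coefficients = numeric(0), pc_ids = character(0))
    fitted <- rep(mu, n)
  } else {
    X <- cbind(1, scores[, pcs, drop = FALSE])
    ls <- stats::lm.fit(X, y)
    cf <- ls$coefficients
    cf[is.na(cf)] <- 0
    fit <- list(
      mu = unname(cf[1]), coefficients = stats::setNames(unname(cf[-1]), colnames(scores)[pcs]),
      pc_ids = colnames(scores)[pcs]
    )
    fitted <- unname(drop(X %*% cf))
  }
  structure(
    c(fit, list(k = k, n = n, fitted = fitted, residuals = y - fitted)),
    class = "pcr_model"
  )
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model> intercept %.4g + %d component(s)\n", x$mu, x$k))
  invisible(x)
}

#' @export
predict.pcr_model <- function(object, newscores, ...) {
  if (object$k == 0) {
    return(rep(object$mu, nrow(newscores)))
  }
  if (!all(object$pc_ids %in% colnames(newscores))) {
    stop("new scores lack the model's components", call. = FALSE)
  }
  unname(drop(object$mu + newscores[, object$pc_ids, drop = FALSE] %*% object$coefficients))
}

#' @export
tidy.pcr_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$pc_ids),
    estimate = c(x$mu, unname(x$coefficients))
  )
}

#' @export
glance.pcr_model <- function(x, ...) {
  tss <- sum((x$fitted + x$residuals - mean(x$fitted + x$residuals))^2)
  tibble::tibble(
    k = x$k, nobs = x$n,
    r.squared = if (tss > 0) 1 - sum(x$residuals^2) / tss else NA_real_,
    sigma = sqrt(sum(x$residuals^2) / max(x$n - x$k - 1, 1))
  )
}

# Predictions for k = 0..k_max in one sweep.
#
# Sequentially orthogonalises the ranked training score columns (classical
# Gram-Schmidt with one reorthogonalisation pass), applies the identical
# transform to the test columns, and accumulates predictions. With exactly
# collinear columns the dependent column gets a zero step, matching OLS with
# pivoting. Returns an n_test x (k_max + 1) matrix, column k + 1 holding the
# k-component prediction.
pcr_prediction_path <- function(train_scores, y, test_scores, order, k_max) {
  n <- nrow(train_scores)
  mu <- mean(y)
  r <- y - mu
  km <- min(k_max, length(order))
  preds <- matrix(mu, nrow(test_scores), km + 1)
  if (km == 0) return(preds)
  Q <- matrix(0, n, km)
  Qt <- matrix(0, nrow(test_scores), km)
  n2 <- numeric(km)
  m <- 0
  cur <- rep(mu, nrow(test_scores))
  for (jj in seq_len(km)) {
    j <- order[jj]
    cmj <- mean(train_scores[, j])
    a <- train_scores[, j] - cmj
    at <- test_scores[, j] - cmj
    nn0 <- sum(a * a)
    if (m > 0) {
      Qm <- Q[, seq_len(m), drop = FALSE]
      c1 <- drop(crossprod(Qm, a)) / n2[seq_len(m)]
      a <- a - drop(Qm %*% c1)
      c2 <- drop(crossprod(Qm, a)) / n2[seq_len(m)]
      a <- a - drop(Qm %*% c2)
      at <- at - drop(Qt[, seq_len(m), drop = FALSE] %*% (c1 + c2))
    }
    nn <- sum(a * a)
    if (nn > nn0 * 1e-20 && nn > 0) {
      m <- m + 1
      Q[, m] <- a
      Qt[, m] <- at
      n2[m] <- nn
      cur <- cur + (sum(a * r) / nn) * at
    }
    preds[, jj + 1] <- cur
  }
  preds
}

#' Test-set accuracy as components are added one by one
#'
#' Fits the principal-component regression on the reference animals at every
#' model size k = 0..`k_max` (in ranking order), predicts the test animals,
#' and records the Pearson correlation between predictions and test
#' phenotypes. The maximum over k is the best-case accuracy — an upper bound
#' that uses test phenotypes to pick k and is therefore unattainable in
#' practice. The incremental implementation reproduces per-k full refits.
#'
#' @param train_scores,y_r Reference scores and phenotypes.
#' @param test_scores,y_t Test scores (same decomposition/projection) and
#'   phenotypes.
#' @param ranking A `pc_ranking` (default eigen/column order).
#' @param k_max Largest model size (default all available components).
#' @return An `accuracy_trajectory` tibble (`k`, `accuracy`; `NA` where the
#'   predictions have zero variance, e.g. k = 0) with attributes `best_k`,
#'   `best_accuracy` and `predictions` (test predictions at every k).
#' @export
accuracy_trajectory <- function(train_scores, y_r, test_scores, y_t,
                                ranking = NULL, k_max = NULL) {
  ord <- if (is.null(ranking)) seq_len(ncol(train_scores)) else ranking$order
  km <- min(k_max %||% length(ord), length(ord))
  preds <- pcr_prediction_path(train_scores, y_r, test_scores, ord, km)
  acc <- apply(preds, 2, function(p) pearson_accuracy(p, y_t))
  out <- tibble::tibble(k = 0:km, accuracy = acc)
  best <- if (all(is.na(acc))) NA_integer_ else which.max(acc)
  structure(out,
    best_k = if (is.na(best)) NA_integer_ else out$k[best],
    best_accuracy = if (is.na(best)) NA_real_ else acc[best],
    criterion = if (is.null(ranking)) "eigen" else ranking$criterion,
    predictions = preds,
    class = c("accuracy_trajectory", class(out))
  )
}

#' @export
autoplot.accuracy_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$accuracy)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(
      data = df[which.max(df$accuracy), ],
      colour = "red", na.rm = TRUE
    ) +
    ggplot2::labs(x = "components in the model", y = "test-set accuracy") +
    ggplot2::theme_minimal()
}
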