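#' Cross-validation fold assignment
#'
#' Random k-fold folds partition the reference set with sizes differing by
#' at most one; stratified folds are the distinct population (or line)
#' labels, one fold per label.
#'
#' @param reference_ids Animal ids.
#' @param scheme `"random"` or `"stratified"`.
#' @param n_folds Number of random folds (default 5).
#' @param labels Population labels, required for the stratified scheme.
#' @param seed Integer seed (random scheme).
#' @return Named integer vector of fold ids with attributes `scheme` and
#'   `n_folds`.
#' @export
make_folds <- function(reference_ids, scheme = c("random", "stratified"),
                       n_folds = 5, labels = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  n <- length(reference_ids)
  if (scheme == "random") {
    if (n < n_folds) stop("fewer animals than folds", call. = FALSE)
    fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  } else {
    if (is.null(labels) || length(unique(labels)) < 2) {
      stop("stratified folds need at least two distinct labels", call. = FALSE)
    }
    fold <- as.integer(factor(labels, levels = unique(labels)))
    n_folds <- length(unique(labels))
  }
  structure(stats::setNames(fold, reference_ids), scheme = scheme, n_folds = n_folds)
}

# Per-fold training/held-out score pairs.
#
# mode "pcr": decomposition and centering from the training fold only, the
# held-out fold projected onto the training loadings — the CV-level mirror of
# reference -> test prediction (no leakage of held-out genotypes).
# mode "sspcr": decomposition from training + held-out genotypes together,
# i.e. the whole reference set; held-out phenotypes are never used.
cv_fold_scores <- function(genotypes, folds, mode = c("pcr", "sspcr"),
                           k_max = NULL, scale = FALSE) {
  mode <- match.arg(mode)
  ids <- names(folds)
  fold_ids <- sort(unique(folds))
  if (mode == "sspcr") {
    xc <- center_genotypes(genotypes, defining_ids = ids, scale = scale)
    dec <- pc_decompose(xc[match(ids, rownames(genotypes)), ], k = k_max)
    lapply(fold_ids, function(f) {
      tr <- folds != f
      list(
        train = dec$scores[tr, , drop = FALSE],
        heldout = dec$scores[!tr, , drop = FALSE],
        train_ids = ids[tr], heldout_ids = ids[!tr]
      )
    })
  } else {
    lapply(fold_ids, function(f) {
      tr_ids <- ids[folds != f]
      ho_ids <- ids[folds == f]
      xc <- center_genotypes(genotypes, defining_ids = tr_ids, scale = scale)
      dec <- pc_decompose(xc[match(tr_ids, rownames(genotypes)), ], k = k_max)
      list(
        train = dec$scores,
        heldout = pc_project(dec, xc[match(ho_ids, rownames(genotypes)), ]),
        train_ids = tr_ids, heldout_ids = ho_ids
      )
    })
  }
}

# MSE curve from prebuilt fold score objects (shared across traits/criteria).
cv_curve_from_folds <- function(fold_scores, y, criterion = c("eigen", "ss"), k_max) {
  criterion <- match.arg(criterion)
  ids <- unlist(lapply(fold_scores, `[[`, "heldout_ids"))
  k_eff <- min(
    k_max,
    vapply(fold_scores, function(fs) {
      min(ncol(fs$train), length(fs$train_ids) - 2)
    }, numeric(1))
  )
  k_eff <- max(k_eff, 0)
  preds <- matrix(NA_real_, length(ids), k_eff + 1, dimnames = list(ids, NULL))
  notes <- character(0)
  for (fs in fold_scores) {
    ytr <- y[fs$train_ids]
    ranking <- if (criterion == "ss") {
      if (stats::var(ytr) == 0) {
        notes <- c(notes, sprintf(
          "constant phenotype in a training fold: ss ranking undefined, eigen order used (%d animals)",
          length(ytr)
        ))
        NULL
      } else {
        rank_ss(fs$train, ytr)
      }
    } else {
      NULL
    }
    ord <- if (is.null(ranking)) seq_len(ncol(fs$train)) else ranking$order
    preds[fs$heldout_ids, ] <- pcr_prediction_path(fs$train, ytr, fs$heldout, ord, k_eff)
  }
  err <- (preds - y[ids])^2
  list(
    curve = tibble::tibble(k = 0:k_eff, mse = colMeans(err)),
    predictions = preds, notes = notes, k_max = k_eff
  )
}

#' Cross-validated MSE curve over the number of components
#'
#' For every fold the components are re-extracted (per `mode`), ranked on
#' the training animals, the regression fitted at every k = 0..`k_max`, and
#' the held-out animals predicted. The curve is the micro-averaged MSE over
#' all held-out predictions pooled across folds; the null model (k = 0) is
#' always included.
#'
#' @param genotypes Complete [geno_matrix()] of the reference animals.
#' @param y Named (or aligned) reference phenotypes.
#' @param criterion Component ranking, `"eigen"` or `"ss"`.
#' @param folds Assignment from [make_folds()].
#' @param mode `"pcr"` (per-fold decomposition of the training fold, with
#'   projection) or `"sspcr"` (single decomposition of training + held-out
#'   genotypes).
#' @param k_max Largest model size scanned (capped at what the smallest
#'   training fold supports).
#' @param scale Passed to [center_genotypes()].
#' @return A `cv_result`: `curve` tibble (`k`, `mse`), `selected_k`,
#'   held-out `predictions` (animals x k+1), `scheme`, `mode`, `criterion`,
#'   `fold_notes`.
#' @export
cv_mse_curve <- function(genotypes, y, criterion = c("eigen", "ss"), folds,
                         mode = c("pcr", "sspcr"), k_max = NULL, scale = FALSE) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  if (is.null(names(y))) names(y) <- rownames(genotypes)
  k_max <- k_max %||% (length(y) - 2)
  fs <- cv_fold_scores(genotypes, folds, mode, k_max = k_max, scale = scale)
  res <- cv_curve_from_folds(fs, y, criterion, k_max)
  for (msg in res$notes) warning(msg, call. = FALSE)
  structure(
    list(
      curve = res$curve,
      selected_k = res$curve$k[which.min(res$curve$mse)],
      predictions = res$predictions,
      scheme = attr(folds, "scheme"), mode = mode, criterion = criterion,
      k_max = res$k_max, fold_notes = res$notes
    ),
    class = "cv_result"
  )
}

#' Selected model size from a cross-validation curve
#'
#' The k minimising the pooled MSE; exact ties resolve to the smallest k
#' (parsimony).
#'
#' @param cv_result A [cv_mse_curve()] result.
#' @return Integer k.
#' @export
select_k <- function(cv_result) {
  cv_result$curve$k[which.min(cv_result$curve$mse)]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s CV, mode %s, %s ranking: selected k = %d (MSE %.4g)\n",
    x$scheme, x$mode, x$criterion, x$selected_k,
    min(x$curve$mse)
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  x$curve
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    selected_k = x$selected_k, min_mse = min(x$curve$mse),
    scheme = x$scheme, mode = x$mode, criterion = x$criterion,
    k_max = x$k_max
  )
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2, colour = "red") +
    ggplot2::labs(x = "components in the model", y = "cross-validated MSE") +
    ggplot2::theme_minimal()
}
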