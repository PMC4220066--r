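#' Center (and optionally scale) a genotype matrix
#'
#' Column centers (and, optionally, scales) are computed on a defining set
#' of animals and applied to every row, so held-out animals can be expressed
#' in the same coordinates as the set that defines the transform.
#'
#' @param genotypes Complete [geno_matrix()] or numeric matrix.
#' @param defining_ids Animal ids whose column means (and SDs) define the
#'   transform; defaults to all rows.
#' @param scale Divide by the defining-set column SD. Columns with zero SD
#'   are dropped with a warning. Default `FALSE` (center only), which keeps
#'   the matrix on the same footing as the VanRaden Z construction.
#' @return A `centered_geno` matrix (all rows transformed) with attributes
#'   `centers`, `scales`, `defining_ids` and `population`.
#' @export
center_genotypes <- function(genotypes, defining_ids = NULL, scale = FALSE) {
  m <- unclass(genotypes)
  pop <- attr(m, "population")
  attr(m, "population") <- NULL
  if (anyNA(m)) stop("genotypes contain missing values; impute first", call. = FALSE)
  if (is.null(defining_ids)) defining_ids <- rownames(m)
  def <- match(defining_ids, rownames(m))
  if (anyNA(def)) stop("defining_ids not all present in the matrix", call. = FALSE)
  if (!length(def)) stop("defining set is empty", call. = FALSE)
  centers <- colMeans(m[def, , drop = FALSE])
  out <- sweep(m, 2, centers)
  scales <- NULL
  if (scale) {
    scales <- apply(m[def, , drop = FALSE], 2, stats::sd)
    zero <- scales == 0
    if (any(zero)) {
      warning(sprintf("%d constant column(s) dropped when scaling", sum(zero)))
      out <- out[, !zero, drop = FALSE]
      centers <- centers[!zero]
      scales <- scales[!zero]
    }
    out <- sweep(out, 2, scales, "/")
  }
  structure(out,
    centers = centers, scales = scales, defining_ids = defining_ids,
    population = pop, class = c("centered_geno", "matrix", "array")
  )
}

#' @export
`[.centered_geno` <- function(x, i, j, ..., drop = FALSE) {
  at <- attributes(x)
  m <- unclass(x)
  for (a in c("centers", "scales", "defining_ids", "population")) attr(m, a) <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  pop <- at$population
  structure(out,
    centers = if (is.matrix(out)) at$centers[j] else NULL,
    scales = if (!is.null(at$scales)) at$scales[j] else NULL,
    defining_ids = at$defining_ids,
    population = if (!is.null(pop)) pop[i] else NULL,
    class = c("centered_geno", "matrix", "array")
  )
}

#' Principal-component decomposition of a centered genotype matrix
#'
#' Exact thin SVD `X = U S V'`, computed through the eigendecomposition of
#' the smaller Gram matrix (`X X'` when p >= n, `X' X` otherwise), which is
#' algebraically the same decomposition. Scores are `T = X V = U S`.
#' Singular values below `tol` times the largest are treated as zero and
#' dropped (numerical rank; the default reflects the noise floor of the
#' Gram-matrix route, whose eigenvalues carry relative error near machine
#' epsilon, i.e. ~1e-8 on the singular-value scale). The sign of each loading column is fixed by
#' making its largest-magnitude entry positive, so results are reproducible.
#'
#' @param x A `centered_geno` matrix (rows = the defining animal set).
#' @param k Keep at most `k` leading components (default: the full rank).
#'   Variance proportions are always computed from all nonzero singular
#'   values.
#' @param tol Relative singular-value cutoff (default 1e-7).
#' @return A `pc_decomp` list: `v` (p x k loadings), `d` (all nonzero
#'   singular values), `scores` (n x k, `T = U S`), `variance_prop`,
#'   `rank`, `animal_set`, `centers`, `scales`, `provenance`.
#' @export
pc_decompose <- function(x, k = NULL, tol = 1e-7) {
  n <- nrow(x)
  p <- ncol(x)
  if (n < 1 || p < 1) stop("need at least one row and one column", call. = FALSE)
  m <- unclass(x)
  for (a in c("centers", "scales", "defining_ids", "population")) attr(m, a) <- NULL
  if (p >= n) {
    ee <- eigen(tcrossprod(m), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    d <- sqrt(ev)
    r <- if (d[1] > 0) sum(d > tol * d[1]) else 0L
    kk <- min(k %||% r, r)
    d <- d[seq_len(r)]
    U <- ee$vectors[, seq_len(kk), drop = FALSE]
    V <- crossprod(m, U)
    if (kk > 0) V <- sweep(V, 2, d[seq_len(kk)], "/")
    scores <- sweep(U, 2, d[seq_len(kk)], "*")
  } else {
    ee <- eigen(crossprod(m), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    d <- sqrt(ev)
    r <- if (d[1] > 0) sum(d > tol * d[1]) else 0L
    kk <- min(k %||% r, r)
    d <- d[seq_len(r)]
    V <- ee$vectors[, seq_len(kk), drop = FALSE]
    scores <- m %*% V
  }
  # deterministic sign: largest-magnitude loading entry positive
  if (kk > 0) {
    for (j in seq_len(kk)) {
      i_max <- which.max(abs(V[, j]))
      if (V[i_max, j] < 0) {
        V[, j] <- -V[, j]
        scores[, j] <- -scores[, j]
      }
    }
  }
  pc_names <- sprintf("PC%d", seq_len(kk))
  dimnames(V) <- list(colnames(m), pc_names)
  dimnames(scores) <- list(rownames(m), pc_names)
  structure(
    list(
      v = V, d = d, scores = scores,
      variance_prop = if (r > 0) ev[seq_len(r)] / sum(ev) else numeric(0),
      rank = r, k = kk,
      animal_set = rownames(m),
      centers = attr(x, "centers"), scales = attr(x, "scales"),
      population = attr(x, "population"),
      provenance = "reference"
    ),
    class = "pc_decomp"
  )
}

#' @export
print.pc_decomp <- function(x, ...) {
  cat(sprintf(
    "<pc_decomp> %d animals, %d SNPs; rank %d, %d component(s) kept (%s)\n",
    length(x$animal_set), nrow(x$v), x$rank, x$k, x$provenance
  ))
  if (x$k > 0) {
    cat(sprintf(
      "leading variance proportions: %s\n",
      paste(sprintf("%.3f", utils::head(x$variance_prop, 5)), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Project centered genotypes onto reference loadings
#'
#' `T_t = X_t V`: held-out animals, centered with the defining set's
#' centers, expressed in the reference components.
#'
#' @param decomp A [pc_decompose()] result.
#' @param x Centered matrix whose columns match the decomposition's SNPs.
#' @return Score matrix (rows = animals, columns = components).
#' @export
pc_project <- function(decomp, x) {
  m <- unclass(x)
  for (a in c("centers", "scales", "defining_ids", "population")) attr(m, a) <- NULL
  if (ncol(m) != nrow(decomp$v)) stop("column count does not match the decomposition", call. = FALSE)
  m %*% decomp$v
}

#' Semi-supervised principal-component decomposition
#'
#' Centers over reference and test animals jointly, runs a single SVD on all
#' of them, and partitions the score rows by membership. The inclusion of
#' to-be-predicted genotypes in the decomposition is the defining feature of
#' semi-supervised PCR; only reference phenotypes ever train a model.
#'
#' @param genotypes Complete [geno_matrix()] holding every animal.
#' @param reference_ids,test_ids Disjoint id sets whose union is all rows.
#' @param scale Passed to [center_genotypes()].
#' @param k Components kept (default full rank).
#' @return List: `decomposition` (provenance "semi-supervised"), `T_r`,
#'   `T_t` (score rows of the reference and test animals).
#' @export
pc_decompose_ss <- function(genotypes, reference_ids, test_ids, scale = FALSE, k = NULL) {
  if (length(intersect(reference_ids, test_ids))) {
    stop("reference and test sets overlap", call. = FALSE)
  }
  all_ids <- rownames(genotypes)
  if (!setequal(c(reference_ids, test_ids), all_ids)) {
    stop("reference and test sets must together cover all animals", call. = FALSE)
  }
  xc <- center_genotypes(genotypes, defining_ids = all_ids, scale = scale)
  dec <- pc_decompose(xc, k = k)
  dec$provenance <- "semi-supervised"
  list(
    decomposition = dec,
    T_r = dec$scores[match(reference_ids, all_ids), , drop = FALSE],
    T_t = dec$scores[match(test_ids, all_ids), , drop = FALSE]
  )
}

#' Cumulative variance captured by leading components
#'
#' @param decomp A [pc_decompose()] result.
#' @param checkpoints Component counts to report (default every one up to
#'   the rank).
#' @return Tibble with `n_pcs` and `cumulative_proportion` (nondecreasing,
#'   1 at the full rank).
#' @export
cumulative_variance <- function(decomp, checkpoints = NULL) {
  cum <- cumsum(decomp$variance_prop)
  checkpoints <- checkpoints %||% seq_len(decomp$rank)
  checkpoints <- checkpoints[checkpoints >= 1 & checkpoints <= decomp$rank]
  tibble::tibble(n_pcs = as.integer(checkpoints), cumulative_proportion = cum[checkpoints])
}

#' @export
tidy.pc_decomp <- function(x, ...) {
  tibble::tibble(
    pc = seq_len(x$rank),
    singular_value = x$d,
    variance_prop = x$variance_prop,
    cumulative_prop = cumsum(x$variance_prop)
  )
}

#' @export
autoplot.pc_decomp <- function(object, ...) {
  if (object$k < 2) stop("need at least two components to plot", call. = FALSE)
  df <- tibble::tibble(
    PC1 = object$scores[, 1], PC2 = object$scores[, 2],
    population = object$population %||% rep("all", nrow(object$scores))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_prop[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_prop[2])
    ) +
    ggplot2::theme_minimal()
}
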