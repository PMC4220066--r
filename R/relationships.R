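#' Pedigree numerator relationship matrix (A)
#'
#' Tabular recursion: for animal i with parents s and d,
#' `A[i,i] = 1 + A[s,d]/2` and `A[i,j] = (A[j,s] + A[j,d])/2`, unknown
#' parents contributing zero. Rows are sorted topologically first; a cycle
#' in the pedigree is an error.
#'
#' @param pedigree Data frame with columns `animal_id`, `sire_id`, `dam_id`
#'   (`NA` for unknown parents).
#' @return Symmetric matrix with animal ids as dimnames.
#' @export
pedigree_A <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)[, c("animal_id", "sire_id", "dam_id")]
  n <- nrow(ped)
  if (anyDuplicated(ped$animal_id)) stop("duplicate animal ids in pedigree", call. = FALSE)
  # topological order (Kahn): place animals whose parents are already placed
  placed <- logical(n)
  pos <- match(ped$sire_id, ped$animal_id)
  pos_d <- match(ped$dam_id, ped$animal_id)
  known_s <- !is.na(ped$sire_id)
  known_d <- !is.na(ped$dam_id)
  if (any(known_s & is.na(pos)) || any(known_d & is.na(pos_d))) {
    stop("pedigree refers to parents absent from the table", call. = FALSE)
  }
  order_idx <- integer(0)
  safe_pos <- ifelse(is.na(pos), 1L, pos)
  safe_pos_d <- ifelse(is.na(pos_d), 1L, pos_d)
  repeat {
    ready <- !placed &
      (!known_s | placed[safe_pos]) &
      (!known_d | placed[safe_pos_d])
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_idx) < n) stop("pedigree contains a cycle", call. = FALSE)
  ped <- ped[order_idx, ]
  si <- match(ped$sire_id, ped$animal_id)
  di <- match(ped$dam_id, ped$animal_id)
  A <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' VanRaden genomic relationship matrix
#'
#' `G_VR = Z Z' / (2 * sum(p_i (1 - p_i)))` where `p_i` is the frequency of
#' the allele coded 2 at SNP i computed across all genotyped animals, and
#' `Z` subtracts `2 p_i` from each genotype column.
#'
#' @param genotypes Complete [geno_matrix()] (impute first).
#' @return List with `G` (n x n matrix) and `allele_freq` (per SNP).
#' @export
vanraden_G <- function(genotypes) {
  m <- unclass(genotypes)
  attr(m, "population") <- NULL
  if (anyNA(m)) stop("genotypes contain missing values; impute first", call. = FALSE)
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs are monomorphic; G denominator is zero", call. = FALSE)
  Z <- sweep(m, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(m), rownames(m))
  list(G = G, allele_freq = stats::setNames(p, colnames(m)))
}

#' Estimate the blending coefficient of G toward A
#'
#' Off-diagonal (i < j) pairs are sorted by their pedigree relationship and
#' split into `n_bins` equal-count bins. Within each bin the attenuation
#' `b = 1 - var(G - A) / var(G)` estimates the fraction of the variation in
#' the genomic relationships that is signal rather than deviation around the
#' pedigree expectation; values are clipped to `[0, 1]` and summarised by a
#' pair-count-weighted mean.
#'
#' @param G Genomic relationship matrix.
#' @param A Pedigree relationship matrix (same animals, same order).
#' @param n_bins Number of relationship bins (default 5).
#' @return List with scalar `b` and tibble `bins`
#'   (`bin`, `a_min`, `a_max`, `n_pairs`, `b`).
#' @export
estimate_blend <- function(G, A, n_bins = 5) {
  stopifnot(all(dim(G) == dim(A)), n_bins >= 1)
  ut <- upper.tri(G)
  g <- G[ut]
  a <- A[ut]
  ord <- order(a)
  g <- g[ord]
  a <- a[ord]
  m <- length(g)
  bin <- ceiling(seq_along(g) / m * n_bins)
  counts <- tabulate(bin, n_bins)
  # merge undersized bins into their left neighbour
  while (any(counts > 0 & counts < 2) && sum(counts > 0) > 1) {
    k <- which(counts > 0 & counts < 2)[1]
    nb <- if (k > 1) max(which(counts[seq_len(k - 1)] > 0)) else which(counts > 0)[2]
    warning(sprintf("relationship bin %d has <2 pairs; merged with neighbour", k))
    bin[bin == k] <- nb
    counts <- tabulate(bin, n_bins)
  }
  bins <- purrr::map_dfr(sort(unique(bin)), function(k) {
    gk <- g[bin == k]
    ak <- a[bin == k]
    vg <- stats::var(gk)
    vr <- stats::var(gk - ak)
    bk <- if (!is.finite(vg) || vg <= 0) 1 else min(max(1 - vr / vg, 0), 1)
    tibble::tibble(bin = k, a_min = min(ak), a_max = max(ak), n_pairs = length(gk), b = bk)
  })
  list(b = stats::weighted.mean(bins$b, bins$n_pairs), bins = bins)
}

#' Blend the genomic relationship matrix toward the pedigree matrix
#'
#' `G = b * G_VR + (1 - b) * A`, regressing marker-based relationships back
#' toward their pedigree expectation.
#'
#' @param G_VR Genomic relationship matrix.
#' @param A Pedigree relationship matrix.
#' @param b Blend coefficient in `[0, 1]`.
#' @return Blended matrix.
#' @export
blend_G <- function(G_VR, A, b) {
  if (b < 0 || b > 1) stop("b must lie in [0, 1]", call. = FALSE)
  if (!all(dim(G_VR) == dim(A))) stop("dimension mismatch between G and A", call. = FALSE)
  b * G_VR + (1 - b) * A
}

#' Within- and between-population relationship summaries
#'
#' For each population, "within" covers the off-diagonal pairs inside it and
#' "between" the pairs linking it to any other population.
#'
#' @param matrix Square relationship matrix.
#' @param population_labels One label per row of `matrix`.
#' @return Tibble with columns `population`, `scope` (within/between),
#'   `average`, `sd`, `n_pairs`. A population of size 1 reports `NA` within.
#' @export
relationship_summary <- function(matrix, population_labels) {
  stopifnot(nrow(matrix) == length(population_labels))
  pops <- unique(population_labels)
  purrr::map_dfr(pops, function(pk) {
    inside <- population_labels == pk
    w <- matrix[inside, inside, drop = FALSE]
    wv <- w[upper.tri(w)]
    bv <- as.vector(matrix[inside, !inside, drop = FALSE])
    tibble::tibble(
      population = pk,
      scope = c("within", "between"),
      average = c(if (length(wv)) mean(wv) else NA_real_, if (length(bv)) mean(bv) else NA_real_),
      sd = c(
        if (length(wv) > 1) stats::sd(wv) else NA_real_,
        if (length(bv) > 1) stats::sd(bv) else NA_real_
      ),
      n_pairs = c(length(wv), length(bv))
    )
  })
}
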