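#' Per-SNP call rate
#' @param genotypes A [geno_matrix()].
#' @return Named numeric vector in `[0,1]`, fraction of non-missing calls.
#' @export
snp_call_rate <- function(genotypes) {
  colMeans(!is.na(unclass(genotypes)))
}

#' Per-SNP, per-population minor allele frequency
#'
#' Computed on non-missing calls only. A SNP with no calls at all in a
#' population has an undefined frequency there, returned as `NA` (treated as
#' failing by [apply_qc()]).
#'
#' @param genotypes A [geno_matrix()].
#' @return Matrix (populations x SNPs) of minor allele frequencies in
#'   `[0, 0.5]`.
#' @export
snp_maf <- function(genotypes) {
  m <- unclass(genotypes)
  pops <- populations(genotypes)
  out <- t(vapply(unique(pops), function(pk) {
    sub <- m[pops == pk, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    f2 <- colSums(sub, na.rm = TRUE) / (2 * n_called)
    f2[n_called == 0] <- NA_real_
    pmin(f2, 1 - f2)
  }, numeric(ncol(m))))
  rownames(out) <- unique(pops)
  out
}

#' Per-SNP Hardy-Weinberg chi-square statistic
#'
#' Three-genotype-class Pearson statistic on calls pooled across all animals,
#' with expected counts n(q^2, 2pq, p^2) from the pooled allele frequency.
#' Monomorphic SNPs return 0 by convention.
#'
#' @param genotypes A [geno_matrix()].
#' @return Named numeric vector of chi-square statistics.
#' @export
snp_hwe <- function(genotypes) {
  m <- unclass(genotypes)
  n0 <- colSums(m == 0, na.rm = TRUE)
  n1 <- colSums(m == 1, na.rm = TRUE)
  n2 <- colSums(m == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- n * 2 * p * q
  e2 <- n * p^2
  chi <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  chi[p == 0 | p == 1 | n == 0] <- 0
  chi[is.na(chi)] <- 0
  names(chi) <- colnames(m)
  chi
}

#' Apply SNP quality control filters
#'
#' Filters are applied in a fixed order — call rate, then per-population
#' minor allele frequency, then Hardy-Weinberg — and each removed SNP is
#' attributed to the first filter it fails. A SNP is kept when its call rate
#' exceeds `call_rate`, its MAF exceeds `maf` in every population, and its
#' HWE chi-square is below `hwe_chisq`. Surviving SNPs keep their original
#' order.
#'
#' @param genotypes A [geno_matrix()].
#' @param call_rate Minimum call rate (kept if strictly greater). Default 0.95.
#' @param maf Minimum per-population minor allele frequency (strictly
#'   greater, in every population). Default 0.01.
#' @param hwe_chisq Maximum HWE chi-square (kept if strictly smaller).
#'   Default 600.
#' @return List with `genotypes` (filtered [geno_matrix()]) and `report`, a
#'   `qc_report`: tibbles `summary` (filter, threshold, n_removed) and
#'   `snps` (snp_id, call_rate, min_maf, hwe_chisq, removed_by), plus counts
#'   `n_before`/`n_after`.
#' @export
apply_qc <- function(genotypes, call_rate = 0.95, maf = 0.01, hwe_chisq = 600) {
  if (call_rate <= 0 || maf <= 0 || hwe_chisq <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  cr <- snp_call_rate(genotypes)
  mafs <- snp_maf(genotypes)
  min_maf <- suppressWarnings(apply(mafs, 2, min, na.rm = TRUE))
  min_maf[!is.finite(min_maf)] <- NA_real_
  any_na_maf <- colSums(is.na(mafs)) > 0
  hwe <- snp_hwe(genotypes)

  removed_by <- rep(NA_character_, ncol(genotypes))
  removed_by[cr <= call_rate] <- "call_rate"
  fail_maf <- is.na(removed_by) & (any_na_maf | min_maf <= maf)
  removed_by[fail_maf] <- "maf"
  removed_by[is.na(removed_by) & hwe >= hwe_chisq] <- "hwe"

  keep <- is.na(removed_by)
  if (!any(keep)) stop("all SNPs removed by quality control", call. = FALSE)
  report <- structure(
    list(
      summary = tibble::tibble(
        filter = c("call_rate", "maf", "hwe"),
        threshold = c(call_rate, maf, hwe_chisq),
        n_removed = c(
          sum(removed_by == "call_rate", na.rm = TRUE),
          sum(removed_by == "maf", na.rm = TRUE),
          sum(removed_by == "hwe", na.rm = TRUE)
        )
      ),
      snps = tibble::tibble(
        snp_id = colnames(genotypes), call_rate = unname(cr),
        min_maf = unname(min_maf), hwe_chisq = unname(hwe),
        removed_by = removed_by
      ),
      n_before = ncol(genotypes), n_after = sum(keep)
    ),
    class = "qc_report"
  )
  list(genotypes = genotypes[, which(keep)], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d SNPs in, %d retained\n", x$n_before, x$n_after))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  x$snps
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_before = x$n_before, n_after = x$n_after,
    n_removed_call_rate = x$summary$n_removed[1],
    n_removed_maf = x$summary$n_removed[2],
    n_removed_hwe = x$summary$n_removed[3]
  )
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call by the per-SNP mean of the observed calls (a
#' real number, so downstream centering is unaffected).
#'
#' @param genotypes A [geno_matrix()]; every SNP needs at least one call.
#' @return A [geno_matrix()] with no missing values (real-valued).
#' @export
impute_missing <- function(genotypes) {
  m <- unclass(genotypes)
  attr(m, "population") <- NULL
  if (!anyNA(m)) {
    return(genotypes)
  }
  mu <- colMeans(m, na.rm = TRUE)
  if (any(is.nan(mu))) stop("SNP with all calls missing cannot be imputed", call. = FALSE)
  na_idx <- which(is.na(m), arr.ind = TRUE)
  m[na_idx] <- mu[na_idx[, 2]]
  new_geno_matrix(m, populations(genotypes))
}
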