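#' SNP genotype matrix with population labels
#'
#' Container for an n x p matrix of additive-coded SNP genotypes (0, 1, 2
#' copies of the allele coded 2; `NA` for a missing call) with unique sample
#' and SNP identifiers and a population label per sample. Subsetting with
#' `[` keeps labels aligned with the rows.
#'
#' @param values Integer (or numeric, once imputed) matrix. Row names are
#'   sample ids, column names SNP ids; defaults are generated when absent.
#' @param population Character vector of population labels, one per row.
#'   Defaults to a single population.
#' @param validate Check that all values are in \{0, 1, 2, NA\}. Turned off
#'   internally for imputed (real-valued) matrices.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(values, population = NULL, validate = TRUE) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind_%d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("snp_%d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate SNP ids", call. = FALSE)
  if (validate) {
    v <- values[!is.na(values)]
    if (length(v) && !all(v %in% c(0, 1, 2))) {
      stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
    }
  }
  if (is.null(population)) population <- rep("pop1", nrow(values))
  population <- rep_len(as.character(population), nrow(values))
  names(population) <- rownames(values)
  structure(values, population = population, class = c("geno_matrix", "matrix", "array"))
}

new_geno_matrix <- function(values, population) {
  geno_matrix(values, population, validate = FALSE)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  pop <- attr(x, "population")
  m <- unclass(x)
  attr(m, "population") <- NULL
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  new_geno_matrix(m[i, j, drop = FALSE], pop[i])
}

#' Population labels of a genotype matrix
#' @param x A [geno_matrix()].
#' @return Named character vector, one label per sample.
#' @export
populations <- function(x) {
  attr(x, "population")
}

#' @export
print.geno_matrix <- function(x, ...) {
  pop <- table(populations(x))
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))
  ))
  cat("populations:", paste(sprintf("%s (%d)", names(pop), pop), collapse = ", "), "\n")
  invisible(x)
}

#' Read genotypes from disk
#'
#' Reads either the plain additive matrix format written by
#' [write_genotypes()] (tab-separated; columns `animal_id`, `population`,
#' then one 0/1/2/NA column per SNP) or a PLINK-style `.ped`/`.map` text
#' pair in which allele "A" counts 0 and allele "B" counts 2, `0 0` marking
#' a missing call and the family id carrying the population label.
#'
#' @param path File path. For `format = "ped"` give the path without
#'   extension, or the `.ped` file itself.
#' @param format `"matrix"` or `"ped"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix", "ped")) {
  format <- match.arg(format)
  if (format == "matrix") read_geno_matrix(path) else read_geno_ped(path)
}

read_geno_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype matrix file has no data rows", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "animal_id" || header[2] != "population") {
    stop("expected header starting with 'animal_id\tpopulation'", call. = FALSE)
  }
  snp_ids <- header[-(1:2)]
  n <- length(lines) - 1
  values <- matrix(NA_integer_, n, length(snp_ids))
  ids <- character(n)
  pop <- character(n)
  for (r in seq_len(n)) {
    fields <- strsplit(lines[[r + 1]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop(sprintf("line %d: expected %d fields, found %d", r + 1, length(header), length(fields)), call. = FALSE)
    }
    ids[r] <- fields[1]
    pop[r] <- fields[2]
    g <- fields[-(1:2)]
    bad <- !(g %in% c("0", "1", "2", "NA"))
    if (any(bad)) {
      stop(sprintf("line %d: invalid genotype code '%s'", r + 1, g[which(bad)[1]]), call. = FALSE)
    }
    values[r, ] <- suppressWarnings(as.integer(g))
  }
  rownames(values) <- ids
  colnames(values) <- snp_ids
  geno_matrix(values, pop)
}

read_geno_ped <- function(path) {
  base <- sub("\\.ped$", "", path)
  ped_path <- paste0(base, ".ped")
  map_path <- paste0(base, ".map")
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  snp_ids <- map[[2]]
  lines <- readLines(ped_path)
  n <- length(lines)
  values <- matrix(NA_integer_, n, length(snp_ids))
  ids <- character(n)
  pop <- character(n)
  for (r in seq_len(n)) {
    fields <- strsplit(trimws(lines[[r]]), "[ \t]+")[[1]]
    if (length(fields) != 6 + 2 * length(snp_ids)) {
      stop(sprintf("line %d: expected %d fields, found %d", r, 6 + 2 * length(snp_ids), length(fields)), call. = FALSE)
    }
    pop[r] <- fields[1]
    ids[r] <- fields[2]
    al <- fields[-(1:6)]
    bad <- !(al %in% c("A", "B", "0"))
    if (any(bad)) {
      stop(sprintf("line %d: unknown allele code '%s'", r, al[which(bad)[1]]), call. = FALSE)
    }
    a1 <- al[c(TRUE, FALSE)]
    a2 <- al[c(FALSE, TRUE)]
    g <- (a1 == "B") + (a2 == "B")
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    values[r, ] <- g
  }
  rownames(values) <- ids
  colnames(values) <- snp_ids
  geno_matrix(values, pop)
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()]; round-trips exactly for valid 0/1/2/NA
#' matrices.
#'
#' @param x A [geno_matrix()] with integer codes.
#' @param path Output path; for `format = "ped"` the basename, to which
#'   `.ped` and `.map` are appended.
#' @param format `"matrix"` or `"ped"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("matrix", "ped")) {
  format <- match.arg(format)
  if (format == "matrix") {
    codes <- matrix(as.character(unclass(x)), nrow(x))
    codes[is.na(codes)] <- "NA"
    header <- paste(c("animal_id", "population", colnames(x)), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(r) {
      paste(c(rownames(x)[r], populations(x)[r], codes[r, ]), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    base <- sub("\\.ped$", "", path)
    map <- data.frame(chr = 1L, snp = colnames(x), cm = 0, bp = seq_len(ncol(x)))
    utils::write.table(map, paste0(base, ".map"),
      quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE
    )
    allele_pairs <- c("0" = "A A", "1" = "A B", "2" = "B B")
    rows <- vapply(seq_len(nrow(x)), function(r) {
      g <- unclass(x)[r, ]
      al <- ifelse(is.na(g), "0 0", allele_pairs[as.character(g)])
      paste(c(populations(x)[r], rownames(x)[r], "0", "0", "0", "-9", al), collapse = " ")
    }, character(1))
    writeLines(rows, paste0(base, ".ped"))
  }
  invisible(path)
}
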