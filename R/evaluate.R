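#' Pearson prediction accuracy
#'
#' Correlation between predicted breeding values and (pre-adjusted)
#' phenotypes within a test set. When either vector has zero variance —
#' e.g. the null model, where every animal receives the same prediction —
#' the accuracy is undefined and `NA` is returned.
#'
#' @param gebv Predictions.
#' @param y_test Observed phenotypes, same length (>= 2).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_accuracy <- function(gebv, y_test) {
  if (length(gebv) != length(y_test)) stop("length mismatch", call. = FALSE)
  if (length(gebv) < 2) stop("need at least two animals", call. = FALSE)
  if (stats::var(gebv) == 0 || stats::var(y_test) == 0) {
    return(NA_real_)
  }
  stats::cor(gebv, y_test)
}

#' Rescale phenotype-correlation accuracy to the GEBV scale
#'
#' The correlation between predictions and phenotypes understates the
#' accuracy of the breeding values themselves; dividing by the square root
#' of the trait heritability converts between the two scales. The result
#' may exceed 1 and is reported as-is with a warning.
#'
#' @param accuracy Correlation(s) with phenotypes.
#' @param heritability Heritability in (0, 1].
#' @return Rescaled accuracy `accuracy / sqrt(heritability)`.
#' @export
rescale_accuracy <- function(accuracy, heritability) {
  if (any(heritability <= 0) || any(heritability > 1)) {
    stop("heritability must lie in (0, 1]", call. = FALSE)
  }
  out <- accuracy / sqrt(heritability)
  if (any(abs(out) > 1, na.rm = TRUE)) {
    warning("rescaled accuracy exceeds 1; reported as-is")
  }
  out
}

#' Run the full across-population prediction study
#'
#' Orchestrates the complete design on one dataset: SNP quality control and
#' mean imputation; pedigree A, VanRaden G and the blend toward A; then, for
#' every leave-one-population-out split and every trait, GREML prediction
#' plus the four PCR-family method combinations (PCR/SSPCR crossed with
#' eigen/ss component ranking) under both cross-validation schemes (5-fold
#' random and population-stratified), and the best-case accuracy scan over
#' the number of components. Deterministic given `seed`.
#'
#' @param data A [simulate_study()] result, or a list with elements
#'   `genotypes` ([geno_matrix()]), `phenotypes` (tibble: `animal_id`,
#'   `population`, one column per trait), optional `pedigree` and
#'   `true_breeding_values`.
#' @param k_max Largest number of components scanned in CV and in the
#'   best-case trajectories (capped by rank and fold sizes). Default 200.
#' @param schemes CV schemes to run.
#' @param n_folds Folds for the random scheme (default 5).
#' @param qc Apply [apply_qc()] first (default TRUE).
#' @param call_rate,maf,hwe_chisq QC thresholds.
#' @param n_bins Relationship bins for [estimate_blend()].
#' @param blend_b Fixed blend coefficient overriding the estimate (set 1 for
#'   no blending; used automatically when no pedigree is supplied).
#' @param seed Integer seed driving the random CV folds.
#' @param quiet Suppress progress messages.
#' @return A `study_report` list: `report` (one row per test population x
#'   trait x method cell), `trajectories` (best-case accuracy curves),
#'   `best_case` (their maxima), `summary_relationships`, `blend`, `qc`,
#'   `variance_components`, `seed`.
#' @export
run_study <- function(data, k_max = 200,
                      schemes = c("random", "stratified"), n_folds = 5,
                      qc = TRUE, call_rate = 0.95, maf = 0.01, hwe_chisq = 600,
                      n_bins = 5, blend_b = NULL, seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  g <- data$genotypes
  phenos <- tibble::as_tibble(data$phenotypes)
  traits <- setdiff(names(phenos), c("animal_id", "population"))
  tbv <- if (!is.null(data$true_breeding_values)) tibble::as_tibble(data$true_breeding_values)

  qc_report <- NULL
  if (qc) {
    qcd <- apply_qc(g, call_rate = call_rate, maf = maf, hwe_chisq = hwe_chisq)
    g <- qcd$genotypes
    qc_report <- qcd$report
    say("QC: %d of %d SNPs retained", qc_report$n_after, qc_report$n_before)
  }
  g <- impute_missing(g)
  ids <- rownames(g)
  pops <- populations(g)
  phenos <- phenos[match(ids, phenos$animal_id), ]
  stopifnot(!anyNA(phenos$animal_id))

  gvr <- vanraden_G(g)
  blend <- NULL
  if (!is.null(data$pedigree)) {
    A_full <- pedigree_A(data$pedigree)
    A <- A_full[ids, ids]
    if (is.null(blend_b)) {
      blend <- estimate_blend(gvr$G, A, n_bins = n_bins)
      b <- blend$b
    } else {
      b <- blend_b
    }
    G <- blend_G(gvr$G, A, b)
  } else {
    b <- blend_b %||% 1
    A <- NULL
    G <- gvr$G
  }
  say("relationships: blend b = %.4f", b)

  # SSPCR decomposition over all animals is split-independent: compute once.
  xc_all <- center_genotypes(g)
  k_all <- min(k_max, nrow(g) - 2)
  dec_all <- pc_decompose(xc_all, k = k_all)
  dec_all$provenance <- "semi-supervised"

  report <- list()
  trajectories <- list()
  best_case <- list()
  varcomp <- list()

  split_pops <- unique(pops)
  for (s in seq_along(split_pops)) {
    pk <- split_pops[s]
    test_ids <- ids[pops == pk]
    ref_ids <- ids[pops != pk]
    say("split %s: %d reference, %d test animals", pk, length(ref_ids), length(test_ids))

    xc_ref <- center_genotypes(g, defining_ids = ref_ids)
    k_ref <- min(k_max, length(ref_ids) - 2)
    dec_ref <- pc_decompose(xc_ref[match(ref_ids, ids), ], k = k_ref)
    T_test_proj <- pc_project(dec_ref, xc_ref[match(test_ids, ids), ])
    i_ref_all <- match(ref_ids, dec_all$animal_set)
    i_tst_all <- match(test_ids, dec_all$animal_set)

    scores_of <- function(mode) {
      if (mode == "pcr") {
        list(r = dec_ref$scores, t = T_test_proj)
      } else {
        list(r = dec_all$scores[i_ref_all, , drop = FALSE], t = dec_all$scores[i_tst_all, , drop = FALSE])
      }
    }

    # fold assignments and per-fold score objects, shared across traits
    fold_sets <- list()
    for (scheme in schemes) {
      folds <- if (scheme == "random") {
        make_folds(ref_ids, "random",
          n_folds = n_folds,
          seed = (seed + 7919L * s) %% .Machine$integer.max
        )
      } else {
        make_folds(ref_ids, "stratified", labels = pops[pops != pk])
      }
      for (mode in c("pcr", "sspcr")) {
        fold_sets[[paste(scheme, mode)]] <- list(
          folds = folds,
          scores = if (mode == "sspcr") {
            # training + held-out genotypes = the whole reference set:
            # identical to the reference decomposition, reuse it
            fold_ids <- sort(unique(folds))
            lapply(fold_ids, function(f) {
              tr <- folds != f
              list(
                train = dec_ref$scores[tr, , drop = FALSE],
                heldout = dec_ref$scores[!tr, , drop = FALSE],
                train_ids = ref_ids[tr], heldout_ids = ref_ids[!tr]
              )
            })
          } else {
            cv_fold_scores(g[match(ref_ids, ids), ], folds, "pcr", k_max = k_max)
          }
        )
      }
    }

    G_rr <- G[ref_ids, ref_ids]
    for (trait in traits) {
      y <- stats::setNames(phenos[[trait]], ids)
      y_r <- y[ref_ids]
      y_t <- y[test_ids]
      tbv_t <- if (!is.null(tbv)) tbv[[trait]][match(test_ids, tbv$animal_id)]
      acc_tbv <- function(pred) {
        if (is.null(tbv_t)) NA_real_ else pearson_accuracy(pred, tbv_t)
      }

      # GREML
      fit <- reml_fit(y_r, G_rr)
      gebv <- predict_gebv(fit, G, ref_ids, test_ids, y_r)
      varcomp[[length(varcomp) + 1]] <- tibble::tibble(
        test_population = pk, trait = trait,
        sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
        heritability = fit$heritability, loglik = fit$loglik,
        boundary = fit$boundary
      )
      report[[length(report) + 1]] <- tibble::tibble(
        test_population = pk, trait = trait, method = "greml",
        ranking = NA_character_, scheme = NA_character_, k = NA_integer_,
        accuracy = pearson_accuracy(gebv$gebv, y_t),
        accuracy_tbv = acc_tbv(gebv$gebv)
      )

      for (mode in c("pcr", "sspcr")) {
        sc <- scores_of(mode)
        for (criterion in c("eigen", "ss")) {
          ranking <- if (criterion == "eigen") NULL else rank_ss(sc$r, y_r)
          traj <- accuracy_trajectory(sc$r, y_r, sc$t, y_t,
            ranking = ranking, k_max = k_max
          )
          traj_preds <- attr(traj, "predictions")
          trajectories[[length(trajectories) + 1]] <- tibble::as_tibble(traj) |>
            dplyr::mutate(
              test_population = pk, trait = trait, method = mode,
              ranking = criterion, .before = 1
            )
          best_case[[length(best_case) + 1]] <- tibble::tibble(
            test_population = pk, trait = trait, method = mode, ranking = criterion,
            best_k = attr(traj, "best_k"), best_accuracy = attr(traj, "best_accuracy")
          )
          for (scheme in schemes) {
            fsset <- fold_sets[[paste(scheme, mode)]]
            cvres <- cv_curve_from_folds(fsset$scores, y_r, criterion, k_max)
            k_sel <- cvres$curve$k[which.min(cvres$curve$mse)]
            k_sel <- min(k_sel, nrow(traj) - 1)
            pred_sel <- traj_preds[, k_sel + 1]
            report[[length(report) + 1]] <- tibble::tibble(
              test_population = pk, trait = trait, method = mode,
              ranking = criterion,
              scheme = if (scheme == "random") sprintf("random%d", n_folds) else scheme,
              k = as.integer(k_sel),
              accuracy = traj$accuracy[k_sel + 1],
              accuracy_tbv = acc_tbv(pred_sel)
            )
          }
        }
      }
    }
  }

  structure(
    list(
      report = dplyr::bind_rows(report),
      trajectories = dplyr::bind_rows(trajectories),
      best_case = dplyr::bind_rows(best_case),
      summary_relationships = relationship_summary(G, pops),
      blend = list(b = b, detail = blend),
      qc = qc_report,
      variance_components = dplyr::bind_rows(varcomp),
      k_max = k_max, seed = seed
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d result cells over %d test populations, blend b = %.3f\n",
    nrow(x$report), length(unique(x$report$test_population)), x$blend$b
  ))
  print(summarize_study(x))
  invisible(x)
}

#' Average accuracy per trait and method across test populations
#'
#' @param report A `study_report` or its `report` tibble.
#' @return Tibble with `trait`, `method`, `ranking`, `scheme`, mean and SD
#'   of accuracy across test populations, and the count of undefined cells
#'   (excluded from the averages).
#' @export
summarize_study <- function(report) {
  tbl <- if (inherits(report, "study_report")) report$report else tibble::as_tibble(report)
  tbl |>
    dplyr::group_by(.data$trait, .data$method, .data$ranking, .data$scheme) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      sd_accuracy = stats::sd(.data$accuracy, na.rm = TRUE),
      n_missing = sum(is.na(.data$accuracy)),
      .groups = "drop"
    )
}

#' Simulate the default study and run the full comparison
#'
#' End-to-end demonstration: simulate the five-population study, apply
#' quality control, and run every method combination. Wholly deterministic
#' given `seed`.
#'
#' @param seed Integer seed (drives the simulation and the CV folds).
#' @param config Optional [sim_config()] (its own seed is kept if supplied).
#' @param ... Passed to [run_study()].
#' @return List with `study` (the [simulate_study()] output) and `result`
#'   (the [run_study()] report).
#' @export
run_demo <- function(seed = 1, config = NULL, ...) {
  config <- config %||% sim_config(seed = seed)
  study <- simulate_study(config, quiet = TRUE)
  result <- run_study(study, seed = seed, ...)
  list(study = study, result = result)
}
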