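# Prediction accuracy is the Pearson correlation between genotype
# predicted values (GPV) and observed phenotype values (OPV) on held-out
# individuals, evaluated by seeded k-fold cross-validation (default
# five-fold, unstratified random folds).

#' Prediction accuracy (Pearson r between GPV and OPV)
#'
#' Computed over the intersection of the two vectors' names (or the rows of
#' a data frame with columns `gpv` and `opv`). Requires at least three
#' shared individuals and nonzero variance in both vectors.
#'
#' @param gpv Named numeric vector of predicted values, or a data frame
#'   with columns `gpv` and `opv`.
#' @param opv Named numeric vector of observed values (ignored when `gpv`
#'   is a data frame).
#' @return The sample Pearson correlation coefficient.
#' @examples
#' prediction_accuracy(c(a = 1, b = 2, c = 3, d = 4),
#'                     c(a = 2, b = 1, c = 4, d = 3)) # 0.6
#' @export
prediction_accuracy <- function(gpv, opv = NULL) {
  if (is.data.frame(gpv)) {
    stopifnot(all(c("gpv", "opv") %in% names(gpv)))
    x <- gpv$gpv
    y <- gpv$opv
  } else {
    shared <- intersect(names(gpv), names(opv))
    x <- unname(gpv[shared])
    y <- unname(opv[shared])
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    abort("Need at least 3 shared individuals for prediction accuracy.",
          class = "markergap_degenerate_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Undefined correlation: zero variance in GPV or OPV.",
          class = "markergap_zero_variance_error")
  }
  cor(x, y)
}

#' Seeded k-fold cross-validation of a GAP model
#'
#' Individuals with both genotypes and a phenotype are shuffled under the
#' seed and partitioned into `k` folds whose sizes differ by at most one;
#' for each fold the model is trained on the complement and the accuracy
#' (Pearson r between GPV and OPV) computed on the fold. Folds whose
#' correlation is undefined (zero variance) are flagged and excluded from
#' the mean rather than imputed. Fully reproducible under the seed;
#' `repeats > 1` runs additional shuffles with seeds `seed + 1, ...` and
#' pools the folds.
#'
#' @inheritParams train_gap_model
#' @param k Number of folds, `>= 2` (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param repeats Number of repeated k-fold runs (default 1).
#' @return An object of class `gap_cv`: list with `trait`, `mode`, `k`,
#'   `seed`, `repeats`, `folds` (tibble `rep`, `fold`, `n_test`, `r`),
#'   `fold_assignment` (tibble `rep`, `individual_id`, `fold`), `mean_r`
#'   (mean of the defined per-fold correlations) and `n_undefined`.
#' @export
kfold_cv <- function(geno, pheno, trait, sets = list(),
                     mode = c("additive", "nonadditive"), k = 5, seed = 1,
                     min_class_n = 3, fallback = c("additive_sum", "zero"),
                     repeats = 1) {
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  if (k < 2) {
    abort("k must be >= 2.", class = "markergap_config_error")
  }
  ph <- matched_phenotypes(geno, pheno, trait)
  ids <- ph$individual_id
  n <- length(ids)
  if (n < k) {
    abort(paste0("Only ", n, " matched individuals for ", k, " folds."),
          class = "markergap_config_error")
  }
  folds_out <- list()
  assign_out <- list()
  for (r_i in seq_len(repeats)) {
    withr::local_seed(seed + r_i - 1L)
    shuffled <- sample(ids)
    fold_of <- setNames(rep(seq_len(k), length.out = n), shuffled)
    assign_out[[r_i]] <- tibble(rep = r_i, individual_id = shuffled,
                                fold = unname(fold_of))
    fold_r <- purrr::map_dfr(seq_len(k), function(f) {
      test_ids <- shuffled[fold_of == f]
      train_ids <- setdiff(ids, test_ids)
      model <- train_gap_model(
        dplyr::filter(geno, .data$individual_id %in% train_ids),
        ph, trait, sets = sets, mode = mode, min_class_n = min_class_n,
        fallback = fallback
      )
      pred <- predict(model,
                      dplyr::filter(geno, .data$individual_id %in% test_ids))
      obs <- dplyr::inner_join(
        pred, dplyr::select(ph, "individual_id", opv = "value"),
        by = "individual_id"
      )
      r_val <- tryCatch(
        prediction_accuracy(dplyr::rename(obs, gpv = "gpv")),
        markergap_zero_variance_error = function(e) NA_real_,
        markergap_degenerate_error = function(e) NA_real_
      )
      tibble(rep = r_i, fold = f, n_test = length(test_ids), r = r_val)
    })
    folds_out[[r_i]] <- fold_r
  }
  folds <- dplyr::bind_rows(folds_out)
  n_undefined <- sum(is.na(folds$r))
  if (n_undefined > 0) {
    warn(paste0(n_undefined,
                " fold(s) had undefined correlation; excluded from mean."))
  }
  structure(
    list(trait = trait, mode = mode, k = k, seed = seed, repeats = repeats,
         folds = folds, fold_assignment = dplyr::bind_rows(assign_out),
         mean_r = mean(folds$r, na.rm = TRUE), n_undefined = n_undefined),
    class = "gap_cv"
  )
}

#' @export
print.gap_cv <- function(x, ...) {
  cat(x$k, "-fold CV (", x$mode, ") for ", x$trait,
      ", seed ", x$seed, ", repeats ", x$repeats, "\n", sep = "")
  cat("  mean accuracy r =", round(x$mean_r, 4))
  if (x$n_undefined > 0) cat("  (", x$n_undefined, "undefined folds excluded)")
  cat("\n")
  invisible(x)
}

#' Recovery of simulation-truth effects by the estimator
#'
#' Compares estimated genotype effects against the truth's deviations. The
#' truth's per-marker effects are first re-centered to deviations under the
#' cohort's realized genotype frequencies (an estimated effect is a
#' deviation from the grand mean, so the comparable truth value for class g
#' is `effect_g - sum_g' freq_g' * effect_g'`). Interacting-set members are
#' compared at the combination level only (in the truth they act through
#' the joint effect, so no per-marker truth deviation exists for them).
#'
#' @param truth An [effect_config()] used to simulate the cohort.
#' @param geno The cohort's genotype tibble (used for realized
#'   frequencies).
#' @param est A `gap_effects` object estimated on the cohort.
#' @param joint_est Optional list of `gap_joint_effects` estimated on the
#'   cohort, matched to `truth$interacting_sets` by members.
#' @return Tibble `term_type` ("marker" or "set"), `id`, `n_classes`,
#'   `bias`, `rmse` (estimate minus truth, over classes observed in the
#'   estimate).
#' @export
parameter_recovery <- function(truth, geno, est, joint_est = NULL) {
  members <- set_member_ids(truth)
  marker_truth <- dplyr::filter(truth$marker_effects,
                                !.data$marker_id %in% members)
  rows <- list()
  for (m in unique(marker_truth$marker_id)) {
    if (!m %in% names(geno)) {
      abort(paste0("Truth marker ", m, " absent from cohort genotypes."),
            class = "markergap_lookup_error")
    }
    tr <- dplyr::filter(marker_truth, .data$marker_id == m)
    calls <- geno[[m]][!is.na(geno[[m]])]
    freq <- table(calls) / length(calls)
    e_tr <- tr$effect[match(norm_call(names(freq)), norm_call(tr$genotype))]
    expected <- sum(as.numeric(freq) * e_tr)
    true_dev <- tibble(genotype = norm_call(tr$genotype),
                       true_effect = tr$effect - expected)
    cmp <- est$effects |>
      dplyr::filter(.data$marker_id == m) |>
      dplyr::mutate(genotype = norm_call(.data$genotype)) |>
      dplyr::inner_join(true_dev, by = "genotype")
    if (nrow(cmp) == 0L) {
      abort(paste0("No overlapping genotype classes for marker ", m, "."),
            class = "markergap_lookup_error")
    }
    err <- cmp$effect - cmp$true_effect
    rows[[length(rows) + 1L]] <- tibble(
      term_type = "marker", id = m, n_classes = nrow(cmp),
      bias = mean(err), rmse = sqrt(mean(err^2))
    )
  }
  if (!is.null(joint_est)) {
    for (je in joint_est) {
      ts <- purrr::detect(truth$interacting_sets,
                          ~ setequal(.x$members, je$member_ids))
      if (is.null(ts)) {
        abort(paste0("No truth interacting set matching ", je$set_id, "."),
              class = "markergap_lookup_error")
      }
      complete <- stats::complete.cases(geno[ts$members])
      key <- combo_key(geno[complete, , drop = FALSE], ts$members)
      freq <- table(key) / length(key)
      e_tr <- ts$effects$effect[match(names(freq),
                                      norm_combo(ts$effects$combo))]
      expected <- sum(as.numeric(freq) * e_tr)
      true_dev <- tibble(combo = norm_combo(ts$effects$combo),
                         true_effect = ts$effects$effect - expected)
      cmp <- dplyr::inner_join(je$combos, true_dev, by = "combo")
      err <- cmp$effect - cmp$true_effect
      rows[[length(rows) + 1L]] <- tibble(
        term_type = "set", id = je$set_id, n_classes = nrow(cmp),
        bias = mean(err), rmse = sqrt(mean(err^2))
      )
    }
  }
  dplyr::bind_rows(rows)
}
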