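test_that("prediction accuracy is the Pearson correlation on shared ids", {
  ids <- letters[1:4]
  expect_equal(prediction_accuracy(setNames(c(1, 2, 3, 4), ids),
                                   setNames(c(2, 1, 4, 3), ids)), 0.6)
  x <- setNames(rnorm(10), paste0("i", 1:10))
  expect_equal(prediction_accuracy(x, x), 1.0)
  expect_equal(prediction_accuracy(x, -x + 5), -1.0)
  # only the intersection of names counts
  y <- setNames(c(x[1:5], z = 99), c(names(x)[1:5], "z"))
  expect_equal(prediction_accuracy(x, y), 1.0)
  expect_error(prediction_accuracy(x[1:2], x[1:2]),
               class = "markergap_degenerate_error")
  expect_error(
    prediction_accuracy(setNames(rep(1, 5), paste0("i", 1:5)), x[1:5]),
    class = "markergap_zero_variance_error"
  )
})

test_that("accuracy is invariant under positive affine rescaling of GPV", {
  set.seed(81)
  for (i in 1:10) {
    ids <- paste0("i", 1:20)
    gpv <- setNames(rnorm(20), ids)
    opv <- setNames(rnorm(20), ids)
    r0 <- prediction_accuracy(gpv, opv)
    slope <- runif(1, 0.1, 10)
    shift <- rnorm(1, 0, 5)
    expect_equal(prediction_accuracy(gpv * slope + shift, opv), r0)
  }
})

test_that("folds are near-equal, disjoint, cover the cohort and reproduce", {
  arch <- storability_architecture(residual_sd = 1)
  g <- simulate_biparental_genotypes(arch$parent1, arch$parent2, 103,
                                     seed = 20)
  co <- simulate_cohort(arch$config, g, seed = 21)
  cv <- kfold_cv(co$genotypes, co$phenotypes, "FFR", k = 5, seed = 3)
  sizes <- table(cv$fold_assignment$fold)
  expect_equal(length(sizes), 5L)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(cv$fold_assignment$individual_id, co$genotypes$individual_id)
  expect_false(anyDuplicated(cv$fold_assignment$individual_id) > 0)
  expect_equal(cv$mean_r, mean(cv$folds$r))

  # n = 10, k = 5 gives five folds of exactly two
  cv10 <- suppressWarnings(
    kfold_cv(co$genotypes[1:10, ], co$phenotypes, "FFR", k = 5,
             seed = 3, min_class_n = 1)
  )
  expect_true(all(table(cv10$fold_assignment$fold) == 2))

  # determinism under the seed
  cv2 <- kfold_cv(co$genotypes, co$phenotypes, "FFR", k = 5, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  # another seed shuffles differently
  cv3 <- kfold_cv(co$genotypes, co$phenotypes, "FFR", k = 5, seed = 4)
  expect_false(identical(cv$fold_assignment, cv3$fold_assignment))
})

test_that("noiseless single-marker CV recovers accuracy 1 in every fold", {
  cfg <- effect_config(8, ad_effects("m1", c("A", "B"), a = 2, d = 0.3),
                       residual_sd = 0)
  g <- simulate_biparental_genotypes(c(m1 = "A/B"), c(m1 = "A/B"), 60,
                                     seed = 22)
  co <- simulate_cohort(cfg, g, seed = 23)
  cv <- kfold_cv(co$genotypes, co$phenotypes, "FFR", k = 5, seed = 5,
                 min_class_n = 1)
  expect_equal(cv$folds$r, rep(1, 5), tolerance = 1e-12)
  expect_equal(cv$mean_r, 1, tolerance = 1e-12)
})

test_that("zero-variance folds are excluded from the mean with a warning", {
  geno <- as_genotype_table(data.frame(
    individual_id = paste0("i", 1:8),
    m1 = rep(c("A/A", "A/T"), 4)
  ))
  pheno <- data.frame(individual_id = paste0("i", 1:8), trait = "FFR",
                      value = rep(5, 8), unit = "months")
  expect_warning(
    cv <- kfold_cv(geno, pheno, "FFR", k = 2, seed = 1, min_class_n = 1),
    "undefined"
  )
  expect_equal(cv$n_undefined, 2L)
  expect_true(is.nan(cv$mean_r))
})

test_that("repeats pool folds under consecutive seeds", {
  arch <- storability_architecture(residual_sd = 1)
  g <- simulate_biparental_genotypes(arch$parent1, arch$parent2, 80,
                                     seed = 24)
  co <- simulate_cohort(arch$config, g, seed = 25)
  cv <- kfold_cv(co$genotypes, co$phenotypes, "FFR", k = 4, seed = 9,
                 repeats = 3)
  expect_equal(nrow(cv$folds), 12L)
  expect_equal(sort(unique(cv$folds$rep)), 1:3)
  expect_equal(cv$mean_r, mean(cv$folds$r))
})

test_that("parameter recovery is exact on noiseless balanced cohorts", {
  # additive markers on a balanced factorial: deviations are orthogonal
  g <- factorial_cohort(n_markers = 2, reps = 3)
  cfg <- effect_config(
    8,
    dplyr::bind_rows(ad_effects("m1", c("A", "B"), a = 2, d = 0.4),
                     ad_effects("m2", c("A", "B"), a = 1, d = 0.6)),
    residual_sd = 0
  )
  co <- simulate_cohort(cfg, g, seed = 26)
  est <- estimate_genotype_effects(co$genotypes, co$phenotypes, "FFR",
                                   min_class_n = 1)
  rec <- parameter_recovery(cfg, co$genotypes, est)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$rmse < 1e-9))

  # joint-only truth: estimated combination deviations equal the truth's
  g2 <- factorial_cohort(n_markers = 2, reps = 2)
  names(g2) <- c("individual_id", "e1", "e2")
  score <- c("A/A" = 1, "A/B" = 0, "B/B" = -1)
  combos <- expand.grid(g1 = names(score), g2 = names(score),
                        stringsAsFactors = FALSE)
  joint <- tibble::tibble(
    combo = paste(combos$g1, combos$g2, sep = ";"),
    effect = as.numeric(4 * score[combos$g1] * score[combos$g2])
  )
  cfg2 <- effect_config(
    8, interacting_sets = list(list(members = c("e1", "e2"),
                                    effects = joint)),
    residual_sd = 0
  )
  co2 <- simulate_cohort(cfg2, g2, seed = 27)
  est2 <- estimate_genotype_effects(co2$genotypes, co2$phenotypes, "FFR",
                                    min_class_n = 1)
  je2 <- estimate_joint_effects(co2$genotypes, co2$phenotypes, "FFR",
                                c("e1", "e2"), min_class_n = 1)
  rec2 <- parameter_recovery(cfg2, co2$genotypes, est2, list(je2))
  set_row <- rec2[rec2$term_type == "set", ]
  expect_true(all(set_row$rmse < 1e-9))
})

test_that("zero-effect truth makes recovery RMSE the estimates' own RMS", {
  cfg <- effect_config(
    8, tibble::tibble(marker_id = "m1",
                      genotype = c("A/A", "A/B", "B/B"),
                      effect = c(0, 0, 0)),
    residual_sd = 1
  )
  g <- simulate_biparental_genotypes(c(m1 = "A/B"), c(m1 = "A/B"), 100,
                                     seed = 28)
  co <- simulate_cohort(cfg, g, seed = 29)
  est <- estimate_genotype_effects(co$genotypes, co$phenotypes, "FFR",
                                   min_class_n = 1)
  rec <- parameter_recovery(cfg, co$genotypes, est)
  own_rms <- sqrt(mean(tidy(est)$effect^2))
  expect_equal(rec$rmse, own_rms)
})
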