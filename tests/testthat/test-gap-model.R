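toy_model <- function(min_class_n = 1, ...) {
  geno <- as_genotype_table(data.frame(
    individual_id = paste0("i", 1:5),
    m1 = c("A/A", "A/A", "A/T", "T/T", "T/T")
  ))
  pheno <- data.frame(individual_id = paste0("i", 1:5), trait = "FFR",
                      value = c(10, 12, 8, 4, 6), unit = "months")
  train_gap_model(geno, pheno, "FFR", min_class_n = min_class_n, ...)
}

test_that("training bundles the effect estimates", {
  m <- toy_model()
  expect_equal(m$grand_mean, 8)
  eff <- tidy(m)
  expect_equal(eff$effect[eff$level == "A/A"], 3)
  expect_equal(eff$effect[eff$level == "T/T"], -3)
  expect_equal(glance(m)$n_markers, 1L)
})

test_that("additive GPV is grand mean plus summed genotype effects", {
  m <- toy_model()
  expect_equal(compute_gpv(m, c(m1 = "A/A")), 11)
  expect_equal(compute_gpv(m, c(m1 = "A/T")), 8)
  expect_equal(compute_gpv(m, c(m1 = "T/T")), 5)
  # missing call contributes 0 and counts as a fallback
  g_na <- tibble::tibble(individual_id = "x", m1 = NA_character_)
  pred <- predict(m, g_na)
  expect_equal(pred$gpv, 8)
  expect_equal(pred$n_fallback, 1L)
})

test_that("predicting an unknown marker raises a lookup error", {
  m <- toy_model()
  expect_error(predict(m, tibble::tibble(individual_id = "x", zz = "A/A")),
               class = "markergap_lookup_error")
})

test_that("nonadditive mode without sets equals the additive model", {
  set.seed(71)
  co <- random_cohort(n_max = 40)
  m_add <- train_gap_model(co$geno, co$pheno, "FFR", mode = "additive",
                           min_class_n = 1)
  m_non <- train_gap_model(co$geno, co$pheno, "FFR", mode = "nonadditive",
                           min_class_n = 1)
  expect_equal(predict(m_add, co$geno), predict(m_non, co$geno))
  # additive mode with sets supplied: sets stored but inert
  mk <- setdiff(names(co$geno), "individual_id")[1:2]
  m_inert <- train_gap_model(co$geno, co$pheno, "FFR", sets = list(mk),
                             mode = "additive", min_class_n = 1)
  expect_equal(predict(m_add, co$geno), predict(m_inert, co$geno))
})

test_that("joint effects replace member contributions (no double counting)", {
  geno <- as_genotype_table(data.frame(
    individual_id = paste0("i", 1:4),
    mA = c("A/A", "A/A", "A/a", "A/a"),
    mB = c("B/B", "B/b", "B/B", "B/b")
  ))
  pheno <- data.frame(individual_id = paste0("i", 1:4), trait = "FFR",
                      value = c(10, 6, 6, 10), unit = "months")
  m_non <- train_gap_model(geno, pheno, "FFR", sets = list(c("mA", "mB")),
                           mode = "nonadditive", min_class_n = 1)
  m_add <- train_gap_model(geno, pheno, "FFR", mode = "additive",
                           min_class_n = 1)
  # pure epistasis: additive model predicts the grand mean everywhere,
  # the non-additive model recovers the combination means
  expect_equal(compute_gpv(m_add, c(mA = "A/A", mB = "B/B")), 8)
  expect_equal(compute_gpv(m_non, c(mA = "A/A", mB = "B/B")), 10)
  expect_equal(compute_gpv(m_non, c(mA = "A/A", mB = "B/b")), 6)
})

test_that("unseen combinations fall back per policy", {
  geno <- as_genotype_table(data.frame(
    individual_id = paste0("i", 1:4),
    mA = c("A/A", "A/A", "A/a", "A/a"),
    mB = c("B/B", "B/b", "B/B", "B/b")
  ))
  pheno <- data.frame(individual_id = paste0("i", 1:4), trait = "FFR",
                      value = c(12, 8, 8, 8), unit = "months")
  m_sum <- train_gap_model(geno, pheno, "FFR", sets = list(c("mA", "mB")),
                           mode = "nonadditive", min_class_n = 1,
                           fallback = "additive_sum")
  m_zero <- train_gap_model(geno, pheno, "FFR", sets = list(c("mA", "mB")),
                            mode = "nonadditive", min_class_n = 1,
                            fallback = "zero")
  # combination a/a;B/B was never observed in training
  unseen <- tibble::tibble(individual_id = "x", mA = "a/a", mB = "B/B")
  p_sum <- predict(m_sum, unseen)
  p_zero <- predict(m_zero, unseen)
  expect_equal(p_sum$n_fallback, 1L)
  expect_equal(p_zero$gpv, m_zero$grand_mean)
  # additive_sum uses the members' individual effects (a/a unseen -> 0,
  # B/B effect = mean(12, 8) - 9 = 1)
  expect_equal(p_sum$gpv, m_sum$grand_mean + 0 + 1)
  # missing member call also triggers the fallback
  p_na <- predict(m_sum, tibble::tibble(individual_id = "x",
                                        mA = NA_character_, mB = "B/B"))
  expect_equal(p_na$n_fallback, 1L)
})

test_that("an all-missing individual is predicted at the grand mean", {
  m <- toy_model()
  g <- tibble::tibble(individual_id = c("a", "b"),
                      m1 = c(NA_character_, "A/A"))
  pred <- predict(m, g)
  expect_equal(pred$gpv, c(8, 11))
  expect_equal(pred$n_fallback, c(1L, 0L))
})

test_that("predictions match per-individual hand sums on a mixed fixture", {
  geno <- as_genotype_table(data.frame(
    individual_id = paste0("i", 1:5),
    m1 = c("A/A", "A/T", "T/T", "A/A", NA),
    m2 = c("C/C", "C/C", "C/G", "G/G", "C/G")
  ))
  pheno <- data.frame(individual_id = paste0("i", 1:5), trait = "FF",
                      value = c(9, 8, 6, 8, 7), unit = "kg/cm2")
  m <- train_gap_model(geno, pheno, "FF", min_class_n = 1)
  pred <- predict(m, geno)
  eff <- naive_effects(geno, pheno, "FF")
  for (i in 1:5) {
    expected <- eff$grand_mean
    for (mk in c("m1", "m2")) {
      call <- geno[[mk]][i]
      if (!is.na(call)) {
        row <- eff$effects[eff$effects$marker_id == mk &
                             eff$effects$genotype == call, ]
        expected <- expected + row$effect
      }
    }
    expect_equal(pred$gpv[i], expected)
  }
})

test_that("noiseless additive self-prediction reproduces OPV exactly", {
  # single segregating marker: GPV equals the class mean = OPV
  cfg <- effect_config(8, ad_effects("m1", c("A", "B"), a = 2, d = 0.3),
                       residual_sd = 0)
  g <- simulate_biparental_genotypes(c(m1 = "A/B"), c(m1 = "A/B"), 60,
                                     seed = 14)
  co <- simulate_cohort(cfg, g, seed = 15)
  m <- train_gap_model(co$genotypes, co$phenotypes, "FFR", min_class_n = 1)
  pred <- predict(m, co$genotypes)
  expect_equal(pred$gpv, co$phenotypes$value)

  # balanced full-factorial cohort with two markers: deviations are
  # orthogonal, GPV = OPV exactly
  g2 <- factorial_cohort(n_markers = 2, reps = 3)
  cfg2 <- effect_config(
    8,
    dplyr::bind_rows(ad_effects("m1", c("A", "B"), a = 2, d = 0.4),
                     ad_effects("m2", c("A", "B"), a = 1, d = 0.6)),
    residual_sd = 0
  )
  co2 <- simulate_cohort(cfg2, g2, seed = 16)
  m2 <- train_gap_model(co2$genotypes, co2$phenotypes, "FFR", min_class_n = 1)
  expect_equal(predict(m2, co2$genotypes)$gpv, co2$phenotypes$value)
})

test_that("effect lookups are insensitive to allele order conventions", {
  # truth declared in (ref, alt) order must match calls canonicalized
  # alphabetically by the simulator
  cfg <- effect_config(6, ad_effects("SNP388", c("G", "A"), a = 1.2, d = 0.4),
                       residual_sd = 0)
  g <- simulate_biparental_genotypes(c(SNP388 = "G/A"), c(SNP388 = "G/A"),
                                     40, seed = 33)
  expect_true(any(g$SNP388 == "A/G"))  # alphabetical form
  co <- simulate_cohort(cfg, g, seed = 34)
  m <- train_gap_model(co$genotypes, co$phenotypes, "FFR", min_class_n = 1)
  # predicting calls written in declared-order form gives identical GPVs
  markers <- tibble::tibble(marker_id = "SNP388", chrom = "Chr16",
                            pos = 9128903L, alleles = list(c("G", "A")),
                            class = "functional")
  g_decl <- as_genotype_table(co$genotypes, markers = markers)
  expect_equal(predict(m, g_decl)$gpv, predict(m, co$genotypes)$gpv)
})
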