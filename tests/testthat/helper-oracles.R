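# Independent, deliberately naive re-implementations used as oracles, plus
# random-cohort generators for property tests. Written in plain base R
# (loops and tapply) so they share no code path with the package.

naive_effects <- function(geno, pheno, trait) {
  ph <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  ph <- ph[ph$individual_id %in% geno$individual_id, ]
  grand <- mean(ph$value)
  out <- list()
  for (m in setdiff(names(geno), "individual_id")) {
    calls <- geno[[m]][match(ph$individual_id, geno$individual_id)]
    keep <- !is.na(calls)
    means <- tapply(ph$value[keep], calls[keep], mean)
    ns <- tapply(ph$value[keep], calls[keep], length)
    out[[m]] <- data.frame(
      marker_id = m, genotype = names(means),
      n = as.integer(ns), effect = as.numeric(means) - grand,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$marker_id, res$genotype), ]
  rownames(res) <- NULL
  list(grand_mean = grand, effects = res)
}

naive_joint_effects <- function(geno, pheno, trait, members) {
  ph <- pheno[pheno$trait == trait & !is.na(pheno$value), ]
  ph <- ph[ph$individual_id %in% geno$individual_id, ]
  grand <- mean(ph$value)
  sub <- geno[match(ph$individual_id, geno$individual_id), members, drop = FALSE]
  full <- !apply(is.na(sub), 1, any)
  key <- apply(sub[full, , drop = FALSE], 1, paste, collapse = ";")
  means <- tapply(ph$value[full], key, mean)
  ns <- tapply(ph$value[full], key, length)
  res <- data.frame(combo = names(means), n = as.integer(ns),
                    effect = as.numeric(means) - grand,
                    stringsAsFactors = FALSE)
  res <- res[order(res$combo), ]
  rownames(res) <- NULL
  list(grand_mean = grand, combos = res)
}

# Random cohort: 2-5 biallelic markers, random calls with some
# missingness, Gaussian phenotypes. Call after set.seed().
random_cohort <- function(n_max = 50, missing_prob = 0.1) {
  n <- sample(5:n_max, 1)
  n_markers <- sample(2:5, 1)
  geno <- tibble::tibble(individual_id = sprintf("i%03d", seq_len(n)))
  for (j in seq_len(n_markers)) {
    alleles <- sort(sample(LETTERS, 2))
    gts <- c(paste(alleles[1], alleles[1], sep = "/"),
             paste(alleles[1], alleles[2], sep = "/"),
             paste(alleles[2], alleles[2], sep = "/"))
    calls <- sample(gts, n, replace = TRUE)
    calls[runif(n) < missing_prob] <- NA_character_
    geno[[paste0("mk", j)]] <- calls
  }
  pheno <- data.frame(
    individual_id = geno$individual_id, trait = "FFR",
    value = rnorm(n, 8, 2), unit = "months", stringsAsFactors = FALSE
  )
  list(geno = geno, pheno = pheno)
}

# Balanced full-factorial cohort over k markers x 3 genotype classes,
# each combination replicated `reps` times; fully called.
factorial_cohort <- function(n_markers = 2, reps = 2) {
  gts <- c("A/A", "A/B", "B/B")
  grid <- do.call(expand.grid,
                  c(rep(list(gts), n_markers), stringsAsFactors = FALSE))
  names(grid) <- paste0("m", seq_len(n_markers))
  grid <- grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE]
  geno <- dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("i%03d", seq_len(nrow(grid)))),
    tibble::as_tibble(grid)
  )
  geno
}
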