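# Synthetic training populations with known genetic architecture. Markers
# segregate independently (no linkage map): the prediction method treats
# markers as exchangeable predictors, so linkage is out of scope here.
# Every stochastic function takes an explicit seed and is byte-reproducible.

#' Genotype effects from an additive/dominance parameterization
#'
#' Maps `(a, d)` onto per-genotype effects `{ref-hom: +a, het: d*a,
#' alt-hom: -a}`: `d = 0` gives a purely additive marker, `|d| = 1` a
#' dominant one and `0 < |d| < 1` partial dominance — the allelic-action
#' classes observed for storability markers.
#'
#' @param marker_id Marker id.
#' @param alleles Character vector of the two alleles `(ref, alt)`.
#' @param a Additive value (half the homozygote spread), in trait units.
#' @param d Dominance degree (d/a ratio of the heterozygote deviation).
#' @return Tibble `marker_id`, `genotype`, `effect` (canonical calls).
#' @examples
#' ad_effects("SNP388", c("G", "A"), a = 1.2, d = 0.4)
#' @export
ad_effects <- function(marker_id, alleles, a, d = 0) {
  stopifnot(length(alleles) == 2L)
  tibble(
    marker_id = marker_id,
    genotype = canonical_call(
      c(paste(alleles[1], alleles[1], sep = "/"),
        paste(alleles[1], alleles[2], sep = "/"),
        paste(alleles[2], alleles[2], sep = "/")),
      alleles
    ),
    effect = c(a, d * a, -a)
  )
}

#' Declare a simulation truth (effect model)
#'
#' Bundles the population mean, per-marker genotype effect maps, joint
#' effect maps for interacting marker sets, residual noise SD and a
#' missingness rate into the configuration used both as simulation truth
#' and for recovery checks. Markers belonging to an interacting set
#' contribute to the genetic value only through the set's joint effect
#' (no double counting); any per-marker rows for them are ignored with a
#' warning.
#'
#' @param population_mean Population mean phenotype, trait units.
#' @param marker_effects Tibble `marker_id`, `genotype`, `effect` (rows from
#'   [ad_effects()] can be bound together), or NULL for no marker effects.
#' @param interacting_sets List of interacting sets; each is a list with
#'   `members` (character vector of marker ids) and `effects` (tibble with
#'   one `combo` column — member calls pasted with `";"` in member order —
#'   and an `effect` column). The truth map must be total over combinations
#'   that can occur.
#' @param residual_sd Residual (environmental) SD, `>= 0`.
#' @param missing_rate Probability a call is masked, in `[0, 1]`.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(population_mean, marker_effects = NULL,
                          interacting_sets = list(), residual_sd = 0,
                          missing_rate = 0) {
  if (residual_sd < 0) {
    abort("residual_sd must be >= 0.", class = "markergap_config_error")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    abort("missing_rate must be in [0, 1].", class = "markergap_config_error")
  }
  if (is.null(marker_effects)) {
    marker_effects <- tibble(marker_id = character(), genotype = character(),
                             effect = numeric())
  }
  marker_effects <- as_tibble(marker_effects)
  stopifnot(all(c("marker_id", "genotype", "effect") %in% names(marker_effects)))
  for (s in interacting_sets) {
    stopifnot(is.character(s$members), length(s$members) >= 2L,
              all(c("combo", "effect") %in% names(s$effects)))
  }
  set_members <- unique(unlist(lapply(interacting_sets, `[[`, "members")))
  overlap <- intersect(set_members, unique(marker_effects$marker_id))
  if (length(overlap)) {
    warn(paste0("Per-marker effects for interacting-set member(s) ",
                paste(overlap, collapse = ", "),
                " are ignored; these markers act through the joint effect."))
  }
  structure(
    list(population_mean = population_mean, marker_effects = marker_effects,
         interacting_sets = interacting_sets, residual_sd = residual_sd,
         missing_rate = missing_rate),
    class = "effect_config"
  )
}

#' Simulate a biparental F1 genotype matrix
#'
#' Each offspring call draws one allele uniformly from each parent,
#' independently across markers (Mendelian segregation, no linkage).
#'
#' @param parent1,parent2 Named character vectors of parental calls
#'   (`"X/Y"`), names = marker ids; parents must be fully genotyped.
#' @param n_offspring Number of offspring.
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @param prefix Prefix for offspring ids.
#' @return A genotype tibble with `n_offspring` rows.
#' @examples
#' simulate_biparental_genotypes(c(m1 = "A/a"), c(m1 = "A/a"), 6, seed = 1)
#' @export
simulate_biparental_genotypes <- function(parent1, parent2, n_offspring,
                                          seed, prefix = "F1") {
  marker_ids <- names(parent1)
  if (!identical(sort(marker_ids), sort(names(parent2)))) {
    abort("Parents must be genotyped at the same markers.",
          class = "markergap_config_error")
  }
  if (anyNA(parent1) || anyNA(parent2) || any(parent1 == MISSING_CALL) ||
      any(parent2 == MISSING_CALL)) {
    abort("Parents must be fully genotyped (no missing calls).",
          class = "markergap_config_error")
  }
  withr::local_seed(seed)
  geno <- tibble(individual_id = sprintf("%s_%04d", prefix, seq_len(n_offspring)))
  for (m in marker_ids) {
    a1 <- strsplit(parent1[[m]], "/", fixed = TRUE)[[1]]
    a2 <- strsplit(parent2[[m]], "/", fixed = TRUE)[[1]]
    from1 <- a1[sample.int(2L, n_offspring, replace = TRUE)]
    from2 <- a2[sample.int(2L, n_offspring, replace = TRUE)]
    geno[[m]] <- canonical_call(paste(from1, from2, sep = "/"))
  }
  geno
}

#' Simulate accession genotypes under Hardy-Weinberg proportions
#'
#' Calls are drawn independently per marker by sampling two alleles from
#' the supplied allele frequencies (random union of gametes).
#'
#' @param allele_freqs Named list, one element per marker: a named numeric
#'   vector of allele frequencies summing to 1 (tolerance 1e-9).
#' @param n Number of accessions.
#' @param seed Integer seed.
#' @param prefix Prefix for accession ids.
#' @return A genotype tibble with `n` rows.
#' @examples
#' simulate_accession_genotypes(list(m1 = c(A = 0.8, T = 0.2)), 5, seed = 1)
#' @export
simulate_accession_genotypes <- function(allele_freqs, n, seed, prefix = "ACC") {
  for (m in names(allele_freqs)) {
    if (abs(sum(allele_freqs[[m]]) - 1) > 1e-9) {
      abort(paste0("Allele frequencies for marker ", m, " must sum to 1."),
            class = "markergap_config_error")
    }
  }
  withr::local_seed(seed)
  geno <- tibble(individual_id = sprintf("%s_%04d", prefix, seq_len(n)))
  for (m in names(allele_freqs)) {
    f <- allele_freqs[[m]]
    a1 <- sample(names(f), n, replace = TRUE, prob = f)
    a2 <- sample(names(f), n, replace = TRUE, prob = f)
    geno[[m]] <- canonical_call(paste(a1, a2, sep = "/"))
  }
  geno
}

set_member_ids <- function(cfg) {
  unique(unlist(lapply(cfg$interacting_sets, `[[`, "members")))
}

combo_key <- function(geno, members) {
  cols <- lapply(unname(as.list(geno[members])), norm_call)
  do.call(paste, c(cols, sep = ";"))
}

norm_combo <- function(combos) {
  vapply(strsplit(combos, ";", fixed = TRUE), function(p) {
    paste(norm_call(p), collapse = ";")
  }, character(1))
}

#' Noiseless genetic values under a truth configuration
#'
#' `population_mean` plus the per-marker effects of markers outside any
#' interacting set plus, for each interacting set, the joint effect of the
#' observed member combination. Truth must be total: a configured marker
#' call or set combination without an effect entry is an error.
#'
#' @param cfg An [effect_config()].
#' @param geno Genotype tibble, fully called at all configured markers
#'   (truth is computed before missingness is injected).
#' @return Tibble `individual_id`, `genetic_value`.
#' @export
genetic_value <- function(cfg, geno) {
  out <- tibble(individual_id = geno$individual_id,
                genetic_value = cfg$population_mean)
  members <- set_member_ids(cfg)
  eff <- dplyr::filter(cfg$marker_effects, !.data$marker_id %in% members)
  for (m in unique(eff$marker_id)) {
    if (!m %in% names(geno)) {
      abort(paste0("Configured marker ", m, " absent from genotype table."),
            class = "markergap_lookup_error")
    }
    map <- dplyr::filter(eff, .data$marker_id == m)
    e <- map$effect[match(norm_call(geno[[m]]), norm_call(map$genotype))]
    if (anyNA(e)) {
      bad <- geno[[m]][which(is.na(e))[1]]
      abort(paste0("No truth effect for marker ", m, " genotype ",
                   ifelse(is.na(bad), "<missing>", bad),
                   "; the truth map must be total."),
            class = "markergap_config_error")
    }
    out$genetic_value <- out$genetic_value + e
  }
  for (s in cfg$interacting_sets) {
    miss <- setdiff(s$members, names(geno))
    if (length(miss)) {
      abort(paste0("Interacting-set member(s) absent from genotype table: ",
                   paste(miss, collapse = ", ")),
            class = "markergap_lookup_error")
    }
    key <- combo_key(geno, s$members)
    e <- s$effects$effect[match(key, norm_combo(s$effects$combo))]
    if (anyNA(e)) {
      abort(paste0("No truth joint effect for combination ",
                   key[which(is.na(e))[1]], " of set {",
                   paste(s$members, collapse = ", "),
                   "}; the truth map must be total."),
            class = "markergap_config_error")
    }
    out$genetic_value <- out$genetic_value + e
  }
  out
}

#' Simulate phenotypes as genetic value plus Gaussian noise
#'
#' `value_i = genetic_value_i + e_i` with `e ~ N(0, residual_sd^2)` i.i.d.
#' (homoscedastic). With `residual_sd = 0` the phenotype equals the genetic
#' value exactly. The realized signal fraction
#' `var(genetic) / var(phenotype)` — the narrow-plus-non-additive analogue
#' of heritability in this noise model — is attached as attribute
#' `"signal_fraction"`.
#'
#' @param cfg An [effect_config()].
#' @param geno Genotype tibble (fully called at configured markers).
#' @param trait Trait label, default `"FFR"`.
#' @param unit Unit string, default `"months"`.
#' @param seed Integer seed for the noise draw.
#' @return Phenotype tibble `individual_id`, `trait`, `value`, `unit`.
#' @export
simulate_phenotypes <- function(cfg, geno, trait = "FFR", unit = "months",
                                seed = 1) {
  gv <- genetic_value(cfg, geno)
  withr::local_seed(seed)
  eps <- if (cfg$residual_sd > 0) rnorm(nrow(gv), 0, cfg$residual_sd) else
    numeric(nrow(gv))
  ph <- tibble(individual_id = gv$individual_id, trait = trait,
               value = gv$genetic_value + eps, unit = unit)
  attr(ph, "signal_fraction") <-
    if (var(ph$value) > 0) var(gv$genetic_value) / var(ph$value) else NA_real_
  ph
}

#' Mask genotype calls at random
#'
#' Each call is independently set missing with probability `rate`;
#' `rate = 0` is the identity, `rate = 1` masks everything.
#'
#' @param geno Genotype tibble.
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Genotype tibble with the same shape.
#' @export
inject_missing <- function(geno, rate, seed) {
  if (rate < 0 || rate > 1) {
    abort("Missing rate must be in [0, 1].", class = "markergap_config_error")
  }
  if (rate == 0) {
    return(geno)
  }
  withr::local_seed(seed)
  for (m in setdiff(names(geno), "individual_id")) {
    mask <- runif(nrow(geno)) < rate
    geno[[m]][mask] <- NA_character_
  }
  geno
}

#' Simulate a monthly softening series during cold storage
#'
#' Linear decay with optional Gaussian noise, floored at zero:
#' `value(t) = max(0, initial - t * monthly_decay + e_t)`. Month index
#' starts at 1 (the first monthly sampling after harvest; the at-harvest
#' measurement is the FF/FC phenotype, not part of the retention series).
#'
#' @param initial Value at harvest (month 0), e.g. firmness in kg/cm2.
#' @param monthly_decay Decay per month, `>= 0`.
#' @param n_months Number of monthly samplings, `>= 1`.
#' @param noise_sd SD of per-month measurement noise (default 0).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param replicate_id Replicate label.
#' @param trait `"firmness"` or `"crispness"`.
#' @return Tibble `replicate_id`, `trait`, `month`, `value`.
#' @examples
#' simulate_softening_series(9, 0.5, 4)
#' @export
simulate_softening_series <- function(initial, monthly_decay, n_months,
                                      noise_sd = 0, seed = 1,
                                      replicate_id = "rep1",
                                      trait = c("firmness", "crispness")) {
  trait <- match.arg(trait)
  if (n_months < 1) {
    abort("n_months must be >= 1.", class = "markergap_config_error")
  }
  if (monthly_decay < 0) {
    abort("monthly_decay must be >= 0.", class = "markergap_config_error")
  }
  months <- seq_len(n_months)
  eps <- if (noise_sd > 0) {
    withr::local_seed(seed)
    rnorm(n_months, 0, noise_sd)
  } else {
    numeric(n_months)
  }
  tibble(replicate_id = replicate_id, trait = trait, month = months,
         value = pmax(0, initial - months * monthly_decay + eps))
}

#' Simulate a full genotype-phenotype cohort
#'
#' Convenience wrapper: computes noiseless genetic values from the truth,
#' draws phenotypes (seed `seed`), then injects missingness into the
#' genotypes at the truth's `missing_rate` (seed `seed + 1`). Truth is
#' always computed on the pre-missingness calls.
#'
#' @param cfg An [effect_config()].
#' @param geno Fully-called genotype tibble (from
#'   [simulate_biparental_genotypes()] or [simulate_accession_genotypes()]).
#' @param trait,unit Trait label and unit for the phenotype table.
#' @param seed Integer seed.
#' @return A list of class `gap_cohort`: `genotypes` (post-missingness),
#'   `phenotypes`, `genetic_values`, `truth` (the config) and `seed`.
#' @export
simulate_cohort <- function(cfg, geno, trait = "FFR", unit = "months",
                            seed = 1) {
  ph <- simulate_phenotypes(cfg, geno, trait = trait, unit = unit, seed = seed)
  gv <- genetic_value(cfg, geno)
  gm <- inject_missing(geno, cfg$missing_rate, seed = seed + 1L)
  structure(
    list(genotypes = gm, phenotypes = ph, genetic_values = gv,
         truth = cfg, seed = seed),
    class = "gap_cohort"
  )
}

#' @export
print.gap_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes) - 1L, "markers\n")
  cat("  trait:", unique(x$phenotypes$trait),
      " residual_sd:", x$truth$residual_sd,
      " missing_rate:", x$truth$missing_rate, " seed:", x$seed, "\n")
  sf <- attr(x$phenotypes, "signal_fraction")
  if (!is.null(sf)) cat("  realized signal fraction:", round(sf, 3), "\n")
  invisible(x)
}
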