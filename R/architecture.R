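# The package's reference simulation architecture. It emulates the
# structure of a storability training population of F1 hybrid lines: a
# fixed marker panel with additive/partial-dominant QTL markers plus one
# pair of interacting functional markers acting through epistatic joint
# effects, and a heterozygous-by-heterozygous biparental cross so every
# marker segregates 1:2:1.

#' Reference simulation architecture for storability traits
#'
#' Returns the default truth configuration and parental genotypes used by
#' the package's simulation studies. Four independent markers carry
#' additive/partial-dominant effects (`a` = 1.5, 1.0, 0.8, 0.5 trait
#' units; `d` = 0.4, 0.3, 0.5, 0.2 — partial dominance being the
#' allelic action typical of functional storability markers), and one
#' interacting pair (`e1`, `e2`) carries product-structure epistatic joint
#' effects `4 * s1 * s2` with `s in {+1, 0, -1}` for the three genotype
#' classes. Under 1:2:1 segregation this interaction has zero marginal
#' (per-marker) effect and SD 2 — purely non-additive signal, twice the
#' residual SD. Both parents are heterozygous at every marker.
#'
#' @param population_mean Population mean phenotype (default 8, a
#'   months-scale retainability).
#' @param residual_sd Residual SD (default 1).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param epistasis_scale Scale of the product-structure joint effects
#'   (default 4, i.e. joint-effect SD 2 under 1:2:1 segregation).
#' @return List with `config` (an [effect_config()]), `parent1`,
#'   `parent2` (named call vectors) and `sets` (the interacting-set
#'   declaration for [train_gap_model()]/[kfold_cv()]).
#' @examples
#' arch <- storability_architecture()
#' g <- simulate_biparental_genotypes(arch$parent1, arch$parent2, 100, seed = 1)
#' cohort <- simulate_cohort(arch$config, g, seed = 1)
#' @export
storability_architecture <- function(population_mean = 8, residual_sd = 1,
                                     missing_rate = 0, epistasis_scale = 4) {
  additive <- dplyr::bind_rows(
    ad_effects("m1", c("A", "B"), a = 1.5, d = 0.4),
    ad_effects("m2", c("A", "B"), a = 1.0, d = 0.3),
    ad_effects("m3", c("A", "B"), a = 0.8, d = 0.5),
    ad_effects("m4", c("A", "B"), a = 0.5, d = 0.2)
  )
  score <- c("A/A" = 1, "A/B" = 0, "B/B" = -1)
  combos <- expand.grid(g1 = names(score), g2 = names(score),
                        stringsAsFactors = FALSE)
  joint <- tibble(
    combo = paste(combos$g1, combos$g2, sep = ";"),
    effect = as.numeric(epistasis_scale * score[combos$g1] * score[combos$g2])
  )
  cfg <- effect_config(
    population_mean = population_mean,
    marker_effects = additive,
    interacting_sets = list(list(members = c("e1", "e2"), effects = joint)),
    residual_sd = residual_sd,
    missing_rate = missing_rate
  )
  parent <- setNames(rep("A/B", 6), c("m1", "m2", "m3", "m4", "e1", "e2"))
  list(config = cfg, parent1 = parent, parent2 = parent,
       sets = list(c("e1", "e2")))
}
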