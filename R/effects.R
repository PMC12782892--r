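# Deviation-based effect estimation: the genotype effect of a marker class
# is the difference between the mean observed phenotype value (OPV) of the
# individuals carrying that genotype and the grand mean OPV of the whole
# training population. Joint effects of interacting marker sets are the
# same deviation computed on multi-marker genotype combinations, and carry
# allelic dominance plus nonallelic epistasis that per-marker effects
# cannot see.

matched_phenotypes <- function(geno, pheno, trait) {
  ph <- pheno |>
    dplyr::filter(.data$trait == !!trait, !is.na(.data$value)) |>
    dplyr::semi_join(geno, by = "individual_id")
  if (nrow(ph) == 0L) {
    abort(paste0("No genotype-phenotype matched individuals for trait ",
                 trait, "."),
          class = "markergap_join_error")
  }
  ph
}

#' Estimate per-marker genotype effects
#'
#' For each marker and genotype class, `effect = mean(OPV | class) -
#' grand_mean`, computed over individuals with both a non-missing call and
#' a phenotype. The grand mean is the mean OPV over all phenotyped matched
#' individuals (a missing call excludes an individual from that marker's
#' classes, not from the grand mean). Classes supported by fewer than
#' `min_class_n` individuals are flagged and carry effect 0.
#'
#' When every individual is called at a marker, the class-size-weighted
#' effects sum to zero exactly (deviations from a common mean).
#'
#' @param geno Genotype tibble.
#' @param pheno Phenotype tibble (`individual_id`, `trait`, `value`, ...).
#' @param trait Trait to estimate for (e.g. `"FFR"`).
#' @param min_class_n Minimum class support; smaller classes are flagged
#'   `low_support` and contribute 0 to prediction. Default 3.
#' @return An object of class `gap_effects`: list with `trait`,
#'   `grand_mean`, `effects` (tibble `marker_id`, `genotype`, `n`,
#'   `effect`, `low_support`), `min_class_n`, `n_individuals`.
#' @examples
#' g <- as_genotype_table(data.frame(
#'   individual_id = paste0("i", 1:5),
#'   m1 = c("A/A", "A/A", "A/T", "T/T", "T/T")
#' ))
#' p <- data.frame(individual_id = paste0("i", 1:5), trait = "FFR",
#'                 value = c(10, 12, 8, 4, 6), unit = "months")
#' estimate_genotype_effects(g, p, "FFR", min_class_n = 1)
#' @export
estimate_genotype_effects <- function(geno, pheno, trait, min_class_n = 3) {
  stopifnot(min_class_n >= 1)
  ph <- matched_phenotypes(geno, pheno, trait)
  grand_mean <- mean(ph$value)
  effects <- geno |>
    dplyr::semi_join(ph, by = "individual_id") |>
    pivot_calls() |>
    dplyr::filter(!is.na(.data$call)) |>
    dplyr::inner_join(dplyr::select(ph, "individual_id", "value"),
                      by = "individual_id") |>
    dplyr::group_by(.data$marker_id, genotype = .data$call) |>
    dplyr::summarise(n = dplyr::n(), effect = mean(.data$value) - grand_mean,
                     .groups = "drop") |>
    dplyr::mutate(
      low_support = .data$n < min_class_n,
      effect = dplyr::if_else(.data$low_support, 0, .data$effect)
    ) |>
    dplyr::arrange(.data$marker_id, .data$genotype)
  structure(
    list(trait = trait, grand_mean = grand_mean, effects = effects,
         min_class_n = min_class_n, n_individuals = nrow(ph)),
    class = "gap_effects"
  )
}

#' @export
print.gap_effects <- function(x, ...) {
  cat("Genotype effects for", x$trait, "(deviation from grand mean",
      round(x$grand_mean, 3), "over", x$n_individuals, "individuals)\n")
  print(x$effects, ...)
  invisible(x)
}

#' Estimate joint effects of an interacting marker set
#'
#' Individuals fully called at all member markers are grouped by their
#' multi-marker genotype combination (member calls pasted with `";"` in
#' `member_ids` order); `joint_effect(combo) = mean(OPV | combo) -
#' grand_mean`. A single-member set reduces to
#' [estimate_genotype_effects()] for that marker.
#'
#' @param geno,pheno,trait,min_class_n As in [estimate_genotype_effects()].
#' @param member_ids Ordered character vector of the set's marker ids.
#' @param set_id Label for the set; defaults to the members joined by "x".
#' @return An object of class `gap_joint_effects`: list with `set_id`,
#'   `member_ids`, `trait`, `grand_mean`, `combos` (tibble `combo`, `n`,
#'   `effect`, `low_support`), `min_class_n`.
#' @export
estimate_joint_effects <- function(geno, pheno, trait, member_ids,
                                   min_class_n = 3,
                                   set_id = paste(member_ids, collapse = "x")) {
  miss <- setdiff(member_ids, names(geno))
  if (length(miss)) {
    abort(paste0("Interacting-set member(s) absent from genotype table: ",
                 paste(miss, collapse = ", ")),
          class = "markergap_lookup_error")
  }
  ph <- matched_phenotypes(geno, pheno, trait)
  grand_mean <- mean(ph$value)
  df <- geno |>
    dplyr::semi_join(ph, by = "individual_id") |>
    dplyr::select("individual_id", dplyr::all_of(member_ids))
  fully_called <- stats::complete.cases(df)
  df <- df[fully_called, , drop = FALSE]
  combos <- tibble(
    individual_id = df$individual_id,
    combo = combo_key(df, member_ids)
  ) |>
    dplyr::inner_join(dplyr::select(ph, "individual_id", "value"),
                      by = "individual_id") |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(n = dplyr::n(), effect = mean(.data$value) - grand_mean,
                     .groups = "drop") |>
    dplyr::mutate(
      low_support = .data$n < min_class_n,
      effect = dplyr::if_else(.data$low_support, 0, .data$effect)
    ) |>
    dplyr::arrange(.data$combo)
  structure(
    list(set_id = set_id, member_ids = member_ids, trait = trait,
         grand_mean = grand_mean, combos = combos, min_class_n = min_class_n),
    class = "gap_joint_effects"
  )
}

#' @export
print.gap_joint_effects <- function(x, ...) {
  cat("Joint effects of set", x$set_id, "{",
      paste(x$member_ids, collapse = ", "), "} on", x$trait, "\n")
  print(x$combos, ...)
  invisible(x)
}

#' Classify allelic interaction from genotype effects
#'
#' For a biallelic marker with usable effects for both homozygotes and the
#' heterozygote: `a = (e_homA - e_homB) / 2`, `d = e_het - (e_homA +
#' e_homB) / 2`, and the dominance ratio `d/a` classifies the allelic
#' action: `|d/a| <= 0.2` additive, `< 0.8` partial_dominant, `<= 1.2`
#' dominant, otherwise overdominant. The class boundaries are this
#' package's convention. Markers without exactly two usable homozygote
#' classes and one usable heterozygote are `undetermined`; `a = 0` with
#' `d != 0` is overdominant with an infinite ratio.
#'
#' @param effects A `gap_effects` object or its `effects` tibble
#'   (`marker_id`, `genotype`, `n`, `effect`, `low_support`).
#' @return Tibble `marker_id`, `a`, `d`, `dominance_ratio`, `label`.
#' @examples
#' eff <- tibble::tibble(marker_id = "m1",
#'                       genotype = c("A/A", "A/T", "T/T"),
#'                       n = 10, effect = c(3, 1.5, -3), low_support = FALSE)
#' classify_allelic_interaction(eff)
#' @export
classify_allelic_interaction <- function(effects) {
  if (inherits(effects, "gap_effects")) {
    effects <- effects$effects
  }
  effects |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::group_modify(~ classify_one_marker(.x)) |>
    dplyr::ungroup()
}

classify_one_marker <- function(df) {
  und <- tibble(a = NA_real_, d = NA_real_, dominance_ratio = NA_real_,
                label = "undetermined")
  usable <- df[!df$low_support, , drop = FALSE]
  parts <- strsplit(usable$genotype, "/", fixed = TRUE)
  is_hom <- vapply(parts, function(p) length(p) == 2L && p[1] == p[2], logical(1))
  homs <- usable[is_hom, , drop = FALSE]
  hets <- usable[!is_hom, , drop = FALSE]
  if (nrow(homs) != 2L || nrow(hets) != 1L) {
    return(und)
  }
  homs <- homs[order(homs$genotype, method = "radix"), , drop = FALSE]
  a <- (homs$effect[1] - homs$effect[2]) / 2
  midpoint <- (homs$effect[1] + homs$effect[2]) / 2
  d <- hets$effect[1] - midpoint
  if (a == 0) {
    if (d == 0) return(und)
    return(tibble(a = a, d = d, dominance_ratio = Inf, label = "overdominant"))
  }
  ratio <- d / a
  label <- dplyr::case_when(
    abs(ratio) <= 0.2 ~ "additive",
    abs(ratio) < 0.8 ~ "partial_dominant",
    abs(ratio) <= 1.2 ~ "dominant",
    TRUE ~ "overdominant"
  )
  tibble(a = a, d = d, dominance_ratio = ratio, label = label)
}

#' Marker effect magnitude (range over genotype classes)
#'
#' Scalar summary of how much a marker moves the trait: the range
#' (max - min) of its usable genotype effects. This range definition is
#' this package's convention for a scalar "marker effect"; signed
#' per-genotype effects cannot be condensed to a scalar in only one way.
#' Markers with fewer than two usable classes return `NA`.
#'
#' @param effects A `gap_effects` object or its `effects` tibble.
#' @return Tibble `marker_id`, `magnitude`, `n_usable_classes`.
#' @export
marker_effect_magnitude <- function(effects) {
  if (inherits(effects, "gap_effects")) {
    effects <- effects$effects
  }
  effects |>
    dplyr::filter(!.data$low_support) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      magnitude = if (dplyr::n() >= 2) max(.data$effect) - min(.data$effect)
                  else NA_real_,
      n_usable_classes = dplyr::n(),
      .groups = "drop"
    )
}
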