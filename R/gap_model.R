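# GAP model: the genotype-predicted value (GPV) of an individual is the
# population mean plus the sum of its marker genotype effects and, in
# non-additive mode, the joint effects of the declared interacting marker
# sets. Markers belonging to a set contribute only through the joint
# effect — the deviation of a combination's class mean already carries the
# members' allelic effects, so adding them again would double count.

#' Train a genomics-assisted prediction model
#'
#' Bundles [estimate_genotype_effects()] and, in non-additive mode,
#' [estimate_joint_effects()] for each declared interacting set. In
#' additive mode supplied sets are stored but inert.
#'
#' @param geno Genotype tibble (training panel).
#' @param pheno Phenotype tibble.
#' @param trait Trait to train for.
#' @param sets List of interacting sets, each a character vector of member
#'   marker ids (all must be columns of `geno`).
#' @param mode `"additive"` or `"nonadditive"`.
#' @param min_class_n Minimum class support, see
#'   [estimate_genotype_effects()].
#' @param fallback Policy when a set's combination is unusable at
#'   prediction time (a member call missing, or the combination unseen or
#'   low-support in training): `"additive_sum"` (default) substitutes the
#'   sum of the members' individual genotype effects, `"zero"` contributes
#'   nothing.
#' @param double_count If `TRUE`, set members also keep their individual
#'   additive contributions next to the joint effect (the literal
#'   both-terms reading; for sensitivity analysis only). Default `FALSE`.
#' @return An object of class `gap_model`.
#' @seealso [predict.gap_model()], [kfold_cv()]
#' @export
train_gap_model <- function(geno, pheno, trait, sets = list(),
                            mode = c("additive", "nonadditive"),
                            min_class_n = 3,
                            fallback = c("additive_sum", "zero"),
                            double_count = FALSE) {
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  effects <- estimate_genotype_effects(geno, pheno, trait, min_class_n)
  joint <- list()
  if (mode == "nonadditive" && length(sets)) {
    joint <- lapply(sets, function(members) {
      estimate_joint_effects(geno, pheno, trait, members, min_class_n)
    })
  }
  structure(
    list(trait = trait, grand_mean = effects$grand_mean, effects = effects,
         joint = joint, sets = sets, mode = mode, fallback = fallback,
         double_count = double_count, min_class_n = min_class_n,
         panel = setdiff(names(geno), "individual_id")),
    class = "gap_model"
  )
}

#' @export
print.gap_model <- function(x, ...) {
  cat("GAP model (", x$mode, ") for ", x$trait, "\n", sep = "")
  cat("  grand mean:", round(x$grand_mean, 4),
      " markers:", length(x$panel),
      " interacting sets:", length(x$joint),
      " min_class_n:", x$min_class_n, "\n")
  invisible(x)
}

#' Genotype-predicted values for a cohort
#'
#' Additive mode: `GPV = grand_mean + sum over markers of effect(marker,
#' call)`, with missing calls, low-support classes and classes unseen in
#' training contributing 0 (the expectation of a class-mean deviation).
#' Non-additive mode: markers inside an interacting set contribute only
#' through the set's joint effect for the observed member combination; if
#' any member is missing or the combination was unseen/low-support, the
#' model's fallback policy applies. All other markers contribute
#' additively. Individuals may be predicted without phenotypes.
#'
#' @param object A [train_gap_model()] fit.
#' @param geno Genotype tibble for the individuals to predict; its markers
#'   must all belong to the model's training panel.
#' @param ... Unused.
#' @return Tibble `individual_id`, `gpv`, `n_fallback` — the count of
#'   markers and sets that contributed through a fallback (missing call,
#'   unseen or low-support class/combination).
#' @export
predict.gap_model <- function(object, geno, ...) {
  marker_ids <- setdiff(names(geno), "individual_id")
  unknown <- setdiff(marker_ids, object$panel)
  if (length(unknown)) {
    abort(paste0("Marker(s) absent from the trained model: ",
                 paste(unknown, collapse = ", ")),
          class = "markergap_lookup_error")
  }
  if (length(marker_ids) == 0L) {
    abort("No markers shared between model and genotype table.",
          class = "markergap_join_error")
  }
  eff <- dplyr::filter(object$effects$effects, !.data$low_support)
  active_sets <- if (object$mode == "nonadditive") object$joint else list()
  set_markers <- unique(unlist(lapply(active_sets, `[[`, "member_ids")))
  additive_markers <- if (object$double_count) marker_ids else
    setdiff(marker_ids, set_markers)

  n <- nrow(geno)
  gpv <- rep(object$grand_mean, n)
  n_fallback <- integer(n)

  marker_effect <- function(m, calls) {
    map <- eff[eff$marker_id == m, , drop = FALSE]
    e <- map$effect[match(norm_call(calls), norm_call(map$genotype))]
    e[is.na(e)] <- 0  # missing call, unseen or flagged class
    e
  }

  for (m in additive_markers) {
    map <- eff[eff$marker_id == m, , drop = FALSE]
    e <- map$effect[match(norm_call(geno[[m]]), norm_call(map$genotype))]
    usable <- !is.na(e)
    e[!usable] <- 0
    gpv <- gpv + e
    n_fallback <- n_fallback + !usable
  }

  for (js in active_sets) {
    members <- js$member_ids
    if (!all(members %in% marker_ids)) {
      abort(paste0("Set ", js$set_id,
                   " member(s) missing from prediction panel."),
            class = "markergap_lookup_error")
    }
    complete <- stats::complete.cases(geno[members])
    key <- combo_key(geno, members)
    usable_combos <- js$combos[!js$combos$low_support, , drop = FALSE]
    je <- usable_combos$effect[match(key, norm_combo(usable_combos$combo))]
    hit <- complete & !is.na(je)
    contrib <- numeric(n)
    contrib[hit] <- je[hit]
    if (any(!hit)) {
      if (object$fallback == "additive_sum") {
        fb <- numeric(n)
        for (m in members) {
          fb <- fb + marker_effect(m, geno[[m]])
        }
        contrib[!hit] <- fb[!hit]
      } # "zero": contrib stays 0
      n_fallback <- n_fallback + !hit
    }
    gpv <- gpv + contrib
  }

  tibble(individual_id = geno$individual_id, gpv = gpv,
         n_fallback = n_fallback)
}

#' GPV for a single individual
#'
#' Convenience wrapper around [predict.gap_model()] for one set of calls.
#'
#' @param model A [train_gap_model()] fit.
#' @param calls Named character vector of calls (names = marker ids);
#'   `NA` allowed for missing.
#' @return A single numeric GPV.
#' @export
compute_gpv <- function(model, calls) {
  geno <- as_tibble(c(list(individual_id = "x"), as.list(calls)))
  predict(model, geno)$gpv
}
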