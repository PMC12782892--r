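# broom-style tidiers for the fitted objects.

#' Tidy a gap_effects object
#'
#' @param x A `gap_effects` fit.
#' @param ... Unused.
#' @return The per-class effects tibble (`marker_id`, `genotype`, `n`,
#'   `effect`, `low_support`).
#' @method tidy gap_effects
#' @export
tidy.gap_effects <- function(x, ...) {
  x$effects
}

#' @rdname tidy.gap_effects
#' @method glance gap_effects
#' @export
glance.gap_effects <- function(x, ...) {
  tibble(trait = x$trait, grand_mean = x$grand_mean,
         n_individuals = x$n_individuals,
         n_markers = dplyr::n_distinct(x$effects$marker_id),
         min_class_n = x$min_class_n)
}

#' Tidy a gap_joint_effects object
#'
#' @param x A `gap_joint_effects` fit.
#' @param ... Unused.
#' @return Tibble `set_id`, `combo`, `n`, `effect`, `low_support`.
#' @method tidy gap_joint_effects
#' @export
tidy.gap_joint_effects <- function(x, ...) {
  dplyr::bind_cols(tibble(set_id = x$set_id), x$combos)
}

#' Tidy a gap_model
#'
#' One row per estimated term: per-marker genotype effects
#' (`term_type = "marker"`) and, for non-additive models, interacting-set
#' combination effects (`term_type = "set"`).
#'
#' @param x A `gap_model` fit.
#' @param ... Unused.
#' @return Tibble `term_type`, `id`, `level`, `n`, `effect`,
#'   `low_support`.
#' @method tidy gap_model
#' @export
tidy.gap_model <- function(x, ...) {
  marker_rows <- x$effects$effects |>
    dplyr::transmute(term_type = "marker", id = .data$marker_id,
                     level = .data$genotype, n = .data$n,
                     effect = .data$effect, low_support = .data$low_support)
  set_rows <- purrr::map_dfr(x$joint, function(js) {
    js$combos |>
      dplyr::transmute(term_type = "set", id = js$set_id,
                       level = .data$combo, n = .data$n,
                       effect = .data$effect, low_support = .data$low_support)
  })
  dplyr::bind_rows(marker_rows, set_rows)
}

#' @rdname tidy.gap_model
#' @method glance gap_model
#' @export
glance.gap_model <- function(x, ...) {
  tibble(trait = x$trait, mode = x$mode, grand_mean = x$grand_mean,
         n_individuals = x$effects$n_individuals,
         n_markers = length(x$panel), n_sets = length(x$joint),
         min_class_n = x$min_class_n, fallback = x$fallback)
}

#' Tidy a cross-validation result
#'
#' @param x A `gap_cv` object.
#' @param ... Unused.
#' @return Per-fold tibble `rep`, `fold`, `n_test`, `r`.
#' @method tidy gap_cv
#' @export
tidy.gap_cv <- function(x, ...) {
  x$folds
}

#' @rdname tidy.gap_cv
#' @method glance gap_cv
#' @export
glance.gap_cv <- function(x, ...) {
  tibble(trait = x$trait, mode = x$mode, k = x$k, seed = x$seed,
         repeats = x$repeats, mean_r = x$mean_r,
         n_undefined = x$n_undefined)
}
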