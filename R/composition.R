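#' Genotype frequencies of one marker, by group
#'
#' Per-group genotype frequencies over non-missing calls (they sum to 1
#' within each group); missing calls are counted separately, as rows with
#' `genotype = NA` and `freq = NA`. Used to compare genetic composition of
#' storability markers between *Malus* species or populations.
#'
#' @param geno Genotype tibble.
#' @param marker_id Marker column to tabulate.
#' @param groups Optional data frame `individual_id`, `group` assigning each
#'   individual to a population/species label; individuals absent from it
#'   are dropped. Default: one group `"all"`.
#' @return Tibble `group`, `genotype`, `n`, `freq`.
#' @examples
#' g <- as_genotype_table(data.frame(
#'   individual_id = c("i1", "i2", "i3", "i4"),
#'   m1 = c("A/A", "A/A", "A/T", ".")
#' ))
#' genotype_frequencies(g, "m1")
#' @export
genotype_frequencies <- function(geno, marker_id, groups = NULL) {
  if (!marker_id %in% names(geno)) {
    abort(paste0("Marker ", marker_id, " not present in genotype table."),
          class = "markergap_lookup_error")
  }
  df <- tibble(individual_id = geno$individual_id, genotype = geno[[marker_id]])
  if (is.null(groups)) {
    df$group <- "all"
  } else {
    groups <- as_tibble(groups)
    if (!all(c("individual_id", "group") %in% names(groups))) {
      abort("`groups` needs columns individual_id and group.",
            class = "markergap_validation_error")
    }
    df <- dplyr::inner_join(df, groups, by = "individual_id")
    if (nrow(df) == 0L) {
      abort("No individuals left after applying `groups`.",
            class = "markergap_validation_error")
    }
  }
  df |>
    dplyr::count(.data$group, .data$genotype, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      freq = dplyr::if_else(
        is.na(.data$genotype), NA_real_,
        .data$n / sum(.data$n[!is.na(.data$genotype)])
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, is.na(.data$genotype), .data$genotype)
}

#' Reduce genotype counts to a segregation ratio
#'
#' Divides the counts by their greatest common divisor and renders them in
#' the supplied genotype order, e.g. `"2:5:5"` for
#' Del216/Del216 : Del216/del216 : del216/del216.
#'
#' @param counts Named non-negative integer vector of genotype counts, at
#'   least one positive.
#' @param order Genotype order for rendering; defaults to `names(counts)`.
#' @return A ratio string `"a:b:c"`.
#' @examples
#' segregation_ratio(c(`Del/Del` = 2, `Del/del` = 5, `del/del` = 5))
#' @export
segregation_ratio <- function(counts, order = names(counts)) {
  if (any(counts < 0)) {
    abort("Genotype counts must be non-negative.",
          class = "markergap_validation_error")
  }
  if (sum(counts) == 0) {
    abort("All genotype counts are zero.",
          class = "markergap_degenerate_error")
  }
  if (!is.null(order)) {
    miss <- setdiff(order, names(counts))
    if (length(miss)) {
      abort(paste0("Genotype(s) not in counts: ", paste(miss, collapse = ", ")),
            class = "markergap_lookup_error")
    }
    counts <- counts[order]
  }
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  g <- Reduce(gcd2, counts[counts > 0])
  paste(as.integer(counts / g), collapse = ":")
}
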