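# Genotype tables are plain tibbles: first column `individual_id`, one
# character column per marker holding diploid calls "X/Y" (canonical allele
# order) or NA for missing. Marker metadata travels in a separate tibble
# (marker_id, chrom, pos, alleles <list>, class), as produced by
# read_marker_table(); most operations work without it.

MISSING_CALL <- "."

#' Canonicalize diploid calls
#'
#' Stores the unordered allele pair in a canonical order so that `"A/T"` and
#' `"T/A"` compare equal. When `alleles` is supplied the pair is ordered by
#' allele index in that vector (the marker's declared allele order);
#' otherwise alphabetically. `"."` and `NA` map to `NA` (missing is a
#' distinct state, never an allele).
#'
#' @param calls Character vector of calls `"X/Y"`, `"."`, or `NA`.
#' @param alleles Optional character vector of the marker's alleles, in
#'   declared order.
#' @return Character vector of canonical calls (`NA` for missing).
#' @examples
#' canonical_call(c("T/A", "A/T", "."))
#' @export
canonical_call <- function(calls, alleles = NULL) {
  out <- rep(NA_character_, length(calls))
  ok <- !is.na(calls) & calls != MISSING_CALL & calls != "./."
  if (!any(ok)) {
    return(out)
  }
  parts <- strsplit(calls[ok], "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(
      paste0("Malformed genotype call(s): ", paste(unique(calls[ok][bad]), collapse = ", "),
             " (expected \"X/Y\" or \".\")"),
      class = "markergap_parse_error"
    )
  }
  out[ok] <- vapply(parts, function(p) {
    if (is.null(alleles)) {
      p <- sort(p, method = "radix")  # byte order: locale-independent
    } else {
      idx <- match(p, alleles)
      if (anyNA(idx)) {
        # leave validation (with marker/individual context) to the caller;
        # fall back to byte order so the value is still canonical
        p <- sort(p, method = "radix")
      } else {
        p <- p[order(idx)]
      }
    }
    paste(p, collapse = "/")
  }, character(1))
  out
}

#' Assemble and validate a genotype table
#'
#' Checks shape (unique `individual_id` first column, character marker
#' columns), canonicalizes every call, and — when marker metadata is given —
#' rejects calls using alleles outside the marker's declared allele set,
#' naming the offending marker and individual.
#'
#' @param geno A data frame with column `individual_id` and one column per
#'   marker.
#' @param markers Optional marker metadata tibble with columns `marker_id`
#'   and `alleles` (list column of character vectors), e.g. from
#'   [read_marker_table()].
#' @return A validated genotype tibble with canonical calls.
#' @examples
#' as_genotype_table(data.frame(individual_id = c("i1", "i2"),
#'                              m1 = c("T/A", "A/T")))
#' @export
as_genotype_table <- function(geno, markers = NULL) {
  geno <- as_tibble(geno)
  if (!"individual_id" %in% names(geno)) {
    abort("Genotype table must have an `individual_id` column.",
          class = "markergap_validation_error")
  }
  geno <- dplyr::relocate(geno, "individual_id")
  geno$individual_id <- as.character(geno$individual_id)
  if (anyDuplicated(geno$individual_id)) {
    abort("Duplicated individual ids in genotype table.",
          class = "markergap_validation_error")
  }
  marker_ids <- setdiff(names(geno), "individual_id")
  if (!is.null(markers)) {
    missing_meta <- setdiff(marker_ids, markers$marker_id)
    if (length(missing_meta)) {
      abort(paste0("Markers absent from metadata: ",
                   paste(missing_meta, collapse = ", ")),
            class = "markergap_lookup_error")
    }
  }
  for (m in marker_ids) {
    alleles <- if (is.null(markers)) NULL else
      markers$alleles[[match(m, markers$marker_id)]]
    calls <- canonical_call(as.character(geno[[m]]), alleles)
    if (!is.null(alleles)) {
      obs <- unique(unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE)))
      bad_alleles <- setdiff(obs, alleles)
      if (length(bad_alleles)) {
        bad_row <- which(vapply(
          strsplit(ifelse(is.na(calls), "", calls), "/", fixed = TRUE),
          function(p) any(p %in% bad_alleles), logical(1)
        ))[1]
        abort(
          paste0("Allele(s) ", paste(bad_alleles, collapse = ", "),
                 " not defined for marker ", m,
                 " (individual ", geno$individual_id[bad_row], ")"),
          class = "markergap_validation_error"
        )
      }
    }
    geno[[m]] <- calls
  }
  geno
}

#' Read a genotype table
#'
#' TSV dialect: individuals as rows, markers as columns; header row of
#' marker ids with a leading `individual_id` column; calls written `"X/Y"`
#' with `"."` for missing. VCF dialect (requires the vcfR package) maps GT
#' fields onto REF/ALT allele strings; `"./."` becomes missing.
#'
#' @param path Path to the genotype file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param markers Optional marker metadata tibble used to validate alleles
#'   and fix canonical allele order (TSV dialect only; the VCF dialect
#'   derives metadata from the VCF itself).
#' @return For `"tsv"`, a genotype tibble. For `"vcf"`, a genotype tibble
#'   with the derived marker metadata attached as attribute `"markers"`.
#' @seealso [write_genotype_table()], [read_marker_table()]
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "vcf"), markers = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "markergap_io_error")
  }
  if (dialect == "vcf") {
    return(read_genotype_vcf(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    abort("Genotype TSV needs a header row and at least one individual.",
          class = "markergap_parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  bad <- which(lengths(fields) != n_col)
  if (length(bad)) {
    abort(paste0("Line ", bad[1], " of ", path, " has ",
                 length(fields[[bad[1]]]), " fields, expected ", n_col),
          class = "markergap_parse_error")
  }
  header <- fields[[1]]
  body <- do.call(rbind, fields[-1])
  geno <- as_tibble(as.data.frame(body, stringsAsFactors = FALSE),
                    .name_repair = "minimal")
  names(geno) <- header
  names(geno)[1] <- "individual_id"
  as_genotype_table(geno, markers = markers)
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the vcfR package.",
          class = "markergap_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  allele_list <- lapply(seq_len(nrow(fix)), function(i) {
    c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
  })
  markers <- tibble(
    marker_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    alleles = allele_list, class = "linkage"
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), ids))
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    idx <- strsplit(g, "[/|]")
    calls[, i] <- vapply(idx, function(p) {
      if (length(p) != 2L || anyNA(p) || any(p == ".")) return(NA_character_)
      paste(allele_list[[i]][as.integer(p) + 1L], collapse = "/")
    }, character(1))
  }
  geno <- as_tibble(as.data.frame(calls, stringsAsFactors = FALSE))
  geno <- dplyr::bind_cols(tibble(individual_id = rownames(calls)), geno)
  out <- as_genotype_table(geno, markers = markers)
  attr(out, "markers") <- markers
  out
}

#' Write a genotype table as TSV
#'
#' Inverse of [read_genotype_table()] under the TSV dialect: missing calls
#' become `"."`. Round-tripping a genotype table through write-then-read is
#' the identity (including the missingness pattern).
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(geno, path) {
  out <- geno
  for (m in setdiff(names(out), "individual_id")) {
    out[[m]] <- ifelse(is.na(out[[m]]), MISSING_CALL, out[[m]])
  }
  lines <- c(
    paste(names(out), collapse = "\t"),
    do.call(paste, c(unname(as.list(out)), sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read marker metadata
#'
#' Marker metadata TSV columns: `marker_id`, `chrom`, `pos` (1-based),
#' `alleles` (comma-separated allele strings; an allele may be a multi-base
#' string or a deletion symbol), `class` (`functional` or `linkage`).
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with `alleles` as a list column.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("marker_id", "chrom", "pos", "alleles", "class")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0("Marker metadata missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "markergap_parse_error")
  }
  df$alleles <- strsplit(df$alleles, ",", fixed = TRUE)
  bad <- which(lengths(df$alleles) < 2L |
                 vapply(df$alleles, anyDuplicated, integer(1)) > 0L)
  if (length(bad)) {
    abort(paste0("Marker ", df$marker_id[bad[1]],
                 " must declare >= 2 distinct alleles."),
          class = "markergap_validation_error")
  }
  if (any(df$pos < 1L)) {
    abort("Marker positions are 1-based and must be >= 1.",
          class = "markergap_validation_error")
  }
  if (anyDuplicated(df$marker_id)) {
    abort("Duplicated marker ids in metadata.",
          class = "markergap_validation_error")
  }
  if (!all(df$class %in% c("functional", "linkage"))) {
    abort("Marker class must be 'functional' or 'linkage'.",
          class = "markergap_validation_error")
  }
  as_tibble(df)
}

#' Read a phenotype table
#'
#' Long-format phenotype TSV with columns `individual_id`, `trait`
#' (e.g. FF, FC, FFR, FCR), `value`, `unit` (kg/cm2 or months).
#'
#' @param path Path to the phenotype TSV.
#' @return A tibble `individual_id`, `trait`, `value`, `unit`.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("individual_id", "trait", "value", "unit")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0("Phenotype table missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "markergap_parse_error")
  }
  df$individual_id <- as.character(df$individual_id)
  df$value <- as.numeric(df$value)
  retain <- df$trait %in% c("FFR", "FCR") & !is.na(df$value)
  if (any(df$value[retain] < 0)) {
    abort("Retainability traits (FFR/FCR) must be >= 0 months.",
          class = "markergap_validation_error")
  }
  as_tibble(df)
}

#' Summarise genotype missingness
#'
#' @param geno Genotype tibble.
#' @return Tibble `marker_id`, `n_missing`, `n_called`, `missing_rate`.
#' @export
missingness_summary <- function(geno) {
  geno |>
    tidyr::pivot_longer(-"individual_id", names_to = "marker_id",
                        values_to = "call") |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$call)),
      n_called = sum(!is.na(.data$call)),
      missing_rate = .data$n_missing / dplyr::n(),
      .groups = "drop"
    )
}

# byte-order normal form used for all effect-map lookups, so that a call
# canonicalized by declared allele order ("G/A") still matches one
# canonicalized alphabetically ("A/G")
norm_call <- function(calls) {
  out <- calls
  ok <- !is.na(calls)
  out[ok] <- vapply(strsplit(calls[ok], "/", fixed = TRUE), function(p) {
    paste(sort(p, method = "radix"), collapse = "/")
  }, character(1))
  out
}

# long view used throughout estimation/prediction
pivot_calls <- function(geno) {
  tidyr::pivot_longer(geno, -"individual_id", names_to = "marker_id",
                      values_to = "call")
}
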