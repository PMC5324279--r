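# Three-level alteration identity: gene ("KRAS"), type ("KRAS|missense_snv"),
# variant ("KRAS|G12C"; non-protein-change classes fall back to the type key).

KEY_LEVELS <- c("gene", "type", "variant")

#' Canonical variant-level key for alterations
#'
#' Upper-case gene symbol joined with `"|"` to the short HGVS-p protein
#' change (any `"p."` prefix stripped); alterations without a protein
#' change (copy number, rearrangement, truncation, frameshift, other) key
#' on their class instead, so all such events in one gene collapse to one
#' variant-level key.
#'
#' @param gene,alt_class,protein_change Character vectors (recycled).
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' variant_key("KRAS", "missense_snv", "G12C")     # "KRAS|G12C"
#' variant_key("KRAS", "copy_number", "")          # "KRAS|copy_number"
variant_key <- function(gene, alt_class, protein_change) {
  pc <- stringr::str_remove(
    dplyr::coalesce(as.character(protein_change), ""), "^p\\."
  )
  ifelse(
    alt_class %in% CODING_CLASSES & pc != "",
    paste0(toupper(gene), "|", pc),
    paste0(toupper(gene), "|", alt_class)
  )
}

# Accept either a `synthetic_cohort` or a bare alteration table; always
# return list(samples, alterations) so empty mutanomes are representable.
as_cohort_tbls <- function(x) {
  if (inherits(x, "synthetic_cohort")) {
    return(list(samples = x$samples, alterations = x$alterations))
  }
  x <- tibble::as_tibble(x)
  needed <- c("sample_id", "gene", "alt_class")
  if (!all(needed %in% names(x))) {
    abort(sprintf("alteration table must have columns: %s", toString(needed)))
  }
  if (!"protein_change" %in% names(x)) x$protein_change <- ""
  list(
    samples = dplyr::distinct(x, .data$sample_id),
    alterations = x
  )
}

#' Per-tumor alteration keys at a chosen identity level
#'
#' @param x A `synthetic_cohort` or an alteration table with columns
#'   `sample_id`, `gene`, `alt_class` and (for variant level)
#'   `protein_change`.
#' @param level One of `"gene"`, `"type"`, `"variant"`.
#'
#' @return Tibble with columns `sample_id`, `key`; one row per distinct
#'   (tumor, key) pair.
#' @export
#' @examples
#' alts <- tibble::tibble(
#'   sample_id = "T1", gene = "KRAS",
#'   alt_class = c("missense_snv", "copy_number"),
#'   protein_change = c("G12C", "")
#' )
#' keys_at_level(alts, "variant")
keys_at_level <- function(x, level = c("variant", "type", "gene")) {
  level <- rlang::arg_match(level, KEY_LEVELS[c(3, 2, 1)])
  tb <- as_cohort_tbls(x)
  alt <- tb$alterations
  key <- switch(
    level,
    gene = toupper(alt$gene),
    type = paste0(toupper(alt$gene), "|", alt$alt_class),
    variant = variant_key(alt$gene, alt$alt_class, alt$protein_change)
  )
  dplyr::distinct(tibble::tibble(sample_id = alt$sample_id, key = key))
}

# One canonical string per tumor: sorted keys joined by ";". Tumors without
# alterations get "" so two empty mutanomes compare equal.
mutanome_signatures <- function(x, level) {
  tb <- as_cohort_tbls(x)
  keys <- keys_at_level(x, level)
  sig <- keys |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      signature = paste(sort(.data$key), collapse = ";"),
      .groups = "drop"
    )
  tb$samples |>
    dplyr::select("sample_id") |>
    dplyr::left_join(sig, by = "sample_id") |>
    dplyr::mutate(signature = dplyr::coalesce(.data$signature, ""))
}

#' Fraction of tumors with a unique mutanome
#'
#' A tumor is unique at a level if no other tumor in the cohort has exactly
#' the same key set at that level. Uniqueness is monotone non-decreasing
#' from gene to type to variant level.
#'
#' @inheritParams keys_at_level
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' alts <- tibble::tibble(
#'   sample_id = c("T1", "T2"), gene = "KRAS",
#'   alt_class = "missense_snv", protein_change = "G12C"
#' )
#' uniqueness_fraction(alts, "variant")  # identical mutanomes -> 0
uniqueness_fraction <- function(x, level = c("variant", "type", "gene")) {
  sig <- mutanome_signatures(x, level)
  if (nrow(sig) == 0) abort("cohort is empty")
  mean(!(duplicated(sig$signature) | duplicated(sig$signature, fromLast = TRUE)))
}

#' Mutanome uniqueness at all three identity levels
#'
#' @inheritParams keys_at_level
#' @return Tibble with columns `level`, `unique_fraction`.
#' @export
uniqueness_summary <- function(x) {
  tibble::tibble(
    level = KEY_LEVELS,
    unique_fraction = vapply(KEY_LEVELS, function(l) uniqueness_fraction(x, l),
                             numeric(1), USE.NAMES = FALSE)
  )
}

#' Recurrent alterations at the variant level
#'
#' Tallies, per canonical variant key, the number of distinct tumors
#' carrying the alteration, and keeps keys seen in at least `min_tumors`
#' tumors. By default only missense SNVs and non-frameshift indels are
#' eligible; frameshift, truncation, copy-number and rearrangement events
#' are excluded from neoantigen-facing recurrence.
#'
#' @inheritParams keys_at_level
#' @param min_tumors Minimum number of distinct tumors (default 10).
#' @param classes Alteration classes eligible for recurrence.
#'
#' @return Tibble with columns `key`, `gene`, `protein_change`, `alt_class`,
#'   `n_tumors`, sorted by decreasing `n_tumors` then key.
#' @export
recurrent_alterations <- function(x, min_tumors = 10,
                                  classes = CODING_CLASSES) {
  if (!is.numeric(min_tumors) || min_tumors < 1) {
    abort("`min_tumors` must be >= 1")
  }
  alt <- as_cohort_tbls(x)$alterations |>
    dplyr::filter(.data$alt_class %in% classes)
  if (nrow(alt) == 0) {
    return(tibble::tibble(
      key = character(), gene = character(), protein_change = character(),
      alt_class = character(), n_tumors = integer()
    ))
  }
  alt |>
    dplyr::mutate(
      key = variant_key(.data$gene, .data$alt_class, .data$protein_change)
    ) |>
    dplyr::distinct(.data$sample_id, .data$key, .keep_all = TRUE) |>
    dplyr::count(.data$key, .data$gene, .data$protein_change,
                 .data$alt_class, name = "n_tumors") |>
    dplyr::filter(.data$n_tumors >= min_tumors) |>
    dplyr::arrange(dplyr::desc(.data$n_tumors), .data$key)
}

#' Recurrence cutoff as a percentage of the cohort
#'
#' @param min_tumors Recurrence cutoff in tumors.
#' @param n_tumors Cohort size.
#' @return `100 * min_tumors / n_tumors` (a percentage).
#' @export
#' @examples
#' cutoff_fraction(10, 63220)  # 0.0158..., i.e. 0.016% at 2 significant figures
cutoff_fraction <- function(min_tumors, n_tumors) {
  if (n_tumors == 0) abort("`n_tumors` must be positive")
  if (min_tumors < 0 || min_tumors > n_tumors) {
    abort("need 0 <= min_tumors <= n_tumors")
  }
  100 * min_tumors / n_tumors
}
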