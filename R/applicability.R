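# Cohort coverage within an HLA subtype and its translation to the general
# population, plus the HLA-typing enrichment test.

#' Coverage of a selected key set among tumors of one HLA subtype
#'
#' Among tumors assigned the given HLA-A/B subtype pair, the fraction
#' carrying at least one of the selected keys (e.g. the ten greedy-selected
#' neoantigen producers for that pair).
#'
#' @param x A `synthetic_cohort`, or an alteration table; if a bare table,
#'   it must carry the subtype via `hla` below.
#' @param selected_keys Character vector of keys (variant level by default).
#' @param pair HLA subtype pair label (e.g. `"A*01:01|B*08:01"`).
#' @param hla Optional tibble `sample_id`, `hla_subtype`; unneeded for a
#'   `synthetic_cohort`, which carries assignments.
#' @param level Key level of `selected_keys`.
#' @return Fraction in `[0, 1]`.
#' @export
subtype_cohort_coverage <- function(x, selected_keys, pair, hla = NULL,
                                    level = "variant") {
  tb <- as_cohort_tbls(x)
  samples <- tb$samples
  if (!"hla_subtype" %in% names(samples)) {
    if (is.null(hla)) abort("supply `hla` assignments (sample_id, hla_subtype)")
    samples <- dplyr::left_join(samples, hla, by = "sample_id")
  }
  carriers <- samples$sample_id[!is.na(samples$hla_subtype) &
                                  samples$hla_subtype == pair]
  if (length(carriers) == 0) {
    abort(sprintf("no tumor carries HLA subtype '%s'", pair))
  }
  keys <- keys_at_level(x, level)
  hit <- unique(keys$sample_id[keys$key %in% selected_keys])
  length(intersect(carriers, hit)) / length(carriers)
}

#' General-population applicability of a subtype-specific alteration set
#'
#' The fraction of the general population a subtype-restricted vaccine set
#' would apply to: the coverage among subtype-bearing tumors times the
#' subtype's population frequency.
#'
#' @param cohort_fraction Coverage fraction in `[0, 1]` among tumors of the
#'   subtype.
#' @param population_frequency The subtype pair's population frequency in
#'   `[0, 1]`.
#' @return Percentage (`100 * cohort_fraction * population_frequency`).
#' @export
#' @examples
#' population_applicability(0.007, 0.126)  # 0.0882% ~ "0.09%"
population_applicability <- function(cohort_fraction, population_frequency) {
  if (any(cohort_fraction < 0 | cohort_fraction > 1) ||
      any(population_frequency < 0 | population_frequency > 1)) {
    abort("both arguments must be fractions in [0, 1]")
  }
  100 * cohort_fraction * population_frequency
}

#' Display rounding for small percentages
#'
#' Mixed precision as conventional in cohort reports: two decimals below
#' 0.1%, one decimal below 10%, integers above. Raw values should always be
#' kept alongside.
#'
#' @param pct Numeric percentages.
#' @return Character vector.
#' @export
#' @examples
#' format_pct(c(0.0882, 0.1638, 1.0044, 24.9))
format_pct <- function(pct) {
  dplyr::case_when(
    pct < 0.1 ~ sprintf("%.2f%%", round(pct, 2)),
    pct < 10 ~ sprintf("%.1f%%", round(pct, 1)),
    TRUE ~ sprintf("%.0f%%", round(pct))
  )
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Standard two-sided convention: the p-value sums hypergeometric
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one. Thin wrapper over [stats::fisher.test()] with
#' input validation for the count-table contract.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_two_sided(8, 32, 4, 36)  # 0.348
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("all four cells must be non-negative integers")
  }
  if (sum(cells) == 0) abort("table is all zero")
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Expected carrier count under a population frequency
#'
#' @param n Number of subjects.
#' @param freq Population frequency in `[0, 1]`.
#' @return `round(n * freq)` (nearest integer, ties to even).
#' @export
#' @examples
#' expected_count(40, 0.104)  # 4
expected_count <- function(n, freq) {
  if (n < 0) abort("`n` must be >= 0")
  round(n * freq)
}

#' Applicability table for a set of HLA subtype pairs
#'
#' For each subtype pair: the cohort coverage of its selected key set and
#' the implied general-population applicability.
#'
#' @param x A `synthetic_cohort` (or alteration table plus `hla`).
#' @param selections Named list of key vectors, one per subtype pair.
#' @param subtype_frequencies Tibble `subtype`, `frequency`.
#' @inheritParams subtype_cohort_coverage
#' @return Tibble `subtype`, `k`, `cohort_fraction`, `population_frequency`,
#'   `population_pct`, `population_pct_display`.
#' @export
applicability_table <- function(x, selections, subtype_frequencies,
                                hla = NULL, level = "variant") {
  purrr::imap_dfr(selections, function(keys, pair) {
    freq <- subtype_frequencies$frequency[
      subtype_frequencies$subtype == pair
    ]
    if (length(freq) != 1) {
      abort(sprintf("no population frequency for subtype '%s'", pair))
    }
    cf <- subtype_cohort_coverage(x, keys, pair, hla = hla, level = level)
    pp <- population_applicability(cf, freq)
    tibble::tibble(
      subtype = pair, k = length(keys), cohort_fraction = cf,
      population_frequency = freq, population_pct = pp,
      population_pct_display = format_pct(pp)
    )
  })
}
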