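#' Simulation parameters for a synthetic tumor cohort
#'
#' Bundles and validates everything [simulate_cohort()] needs: cohort size,
#' gene universe, the gene-recurrence power law, the per-tumor
#' alteration-count distribution, hotspot drivers with target frequencies,
#' the alteration class mix, the HLA subtype-pair frequency table, and the
#' protein length range.
#'
#' Defaults emulate a large clinical hybrid-capture cohort: 63,220 tumors
#' over a 300-gene panel, Zipf-weighted gene recurrence (exponent 1.2), a
#' negative binomial alteration count per tumor (mean 4, size 2), and a
#' hotspot tail headed by KRAS G12C (1799/63220), PIK3CA E545K (1713/63220)
#' and EGFR L858R (478/63220) plus common literature drivers, sized so that
#' the ten most recurrent missense variants jointly cover roughly a quarter
#' of tumors.
#'
#' @param n_tumors Number of tumors to simulate.
#' @param n_genes Number of genes in the panel (hotspot genes are added if
#'   not already present).
#' @param gene_weight_exponent Power-law exponent for gene recurrence
#'   weights: gene ranked r gets weight proportional to `r^-exponent`.
#' @param alterations_per_tumor Length-2 numeric `c(mean, dispersion)` of the
#'   negative binomial per-tumor alteration count (dispersion is the
#'   `size` parameter; smaller means more overdispersed).
#' @param hotspot_spec Tibble/data frame with columns `gene`,
#'   `protein_change`, `class`, `frequency` (per-tumor probability, each
#'   strictly below 1).
#' @param class_mix Named numeric vector of probabilities over alteration
#'   classes; must sum to 1 within 1e-9. Names must be a subset of
#'   `r toString(ALT_CLASSES)`.
#' @param hla_frequency_table Tibble/data frame with columns `subtype`
#'   (e.g. `"A*01:01|B*08:01"`) and `frequency`; the residual mass is
#'   assigned to an `"other"` bucket.
#' @param protein_length_range Length-2 integer range of protein lengths in
#'   amino acids.
#' @param seed Integer seed; the single pseudo-random stream of the run.
#'
#' @return A validated list of class `cohort_sim_params`.
#' @seealso [simulate_cohort()], [default_hotspots()], [default_hla_frequencies()]
#' @export
#' @examples
#' p <- cohort_sim_params(n_tumors = 100, seed = 1)
#' p$n_tumors
cohort_sim_params <- function(n_tumors = 63220,
                              n_genes = 300,
                              gene_weight_exponent = 1.2,
                              alterations_per_tumor = c(mean = 4, dispersion = 2),
                              hotspot_spec = default_hotspots(),
                              class_mix = default_class_mix(),
                              hla_frequency_table = default_hla_frequencies(),
                              protein_length_range = c(200L, 1200L),
                              seed = 1L) {
  check_count <- function(x, name, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
      abort(sprintf("`%s` must be a single integer >= %d", name, min))
    }
  }
  check_count(n_tumors, "n_tumors")
  check_count(n_genes, "n_genes")
  check_count(seed, "seed", min = 0)
  if (!is.numeric(gene_weight_exponent) || gene_weight_exponent < 0) {
    abort("`gene_weight_exponent` must be a non-negative number")
  }
  if (length(alterations_per_tumor) != 2 || any(alterations_per_tumor < 0) ||
      alterations_per_tumor[2] <= 0) {
    abort("`alterations_per_tumor` must be c(mean >= 0, dispersion > 0)")
  }

  hotspot_spec <- tibble::as_tibble(hotspot_spec)
  needed <- c("gene", "protein_change", "class", "frequency")
  if (!all(needed %in% names(hotspot_spec))) {
    abort("`hotspot_spec` needs columns gene, protein_change, class, frequency")
  }
  if (any(hotspot_spec$frequency < 0) || any(hotspot_spec$frequency >= 1)) {
    abort("`hotspot_spec` frequencies must be in [0, 1)")
  }
  if (!all(hotspot_spec$class %in% CODING_CLASSES)) {
    abort("`hotspot_spec` classes must be missense_snv or nonframeshift_indel")
  }

  if (is.null(names(class_mix)) || !all(names(class_mix) %in% ALT_CLASSES)) {
    abort(sprintf("`class_mix` must be named with classes among: %s",
                  toString(ALT_CLASSES)))
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    abort("`class_mix` probabilities must be >= 0 and sum to 1 (tol 1e-9)")
  }

  hla_frequency_table <- tibble::as_tibble(hla_frequency_table)
  if (!all(c("subtype", "frequency") %in% names(hla_frequency_table))) {
    abort("`hla_frequency_table` needs columns subtype, frequency")
  }
  if (any(hla_frequency_table$frequency < 0) ||
      any(hla_frequency_table$frequency > 1) ||
      sum(hla_frequency_table$frequency) > 1 + 1e-9) {
    abort("`hla_frequency_table` frequencies must lie in [0,1] and sum to <= 1")
  }

  if (length(protein_length_range) != 2 ||
      protein_length_range[1] < 30 ||
      protein_length_range[2] < protein_length_range[1]) {
    abort("`protein_length_range` must be c(min >= 30, max >= min)")
  }

  structure(
    list(
      n_tumors = as.integer(n_tumors),
      n_genes = as.integer(n_genes),
      gene_weight_exponent = gene_weight_exponent,
      alterations_per_tumor = c(
        mean = unname(alterations_per_tumor[1]),
        dispersion = unname(alterations_per_tumor[2])
      ),
      hotspot_spec = hotspot_spec,
      class_mix = class_mix,
      hla_frequency_table = hla_frequency_table,
      protein_length_range = as.integer(protein_length_range),
      seed = as.integer(seed)
    ),
    class = "cohort_sim_params"
  )
}

#' Default hotspot driver specification
#'
#' Three drivers at the frequencies observed in large pan-cancer
#' hybrid-capture cohorts (KRAS G12C 1799/63220, PIK3CA E545K 1713/63220,
#' EGFR L858R 478/63220) plus eight further common hotspots at plausible
#' pan-cancer frequencies. Jointly the ten most frequent cover ~25% of
#' tumors under independent occurrence.
#'
#' @return Tibble with columns `gene`, `protein_change`, `class`, `frequency`.
#' @export
default_hotspots <- function() {
  tibble::tribble(
    ~gene,     ~protein_change, ~class,         ~frequency,
    "BRAF",    "V600E",         "missense_snv", 0.050,
    "KRAS",    "G12D",          "missense_snv", 0.040,
    "KRAS",    "G12V",          "missense_snv", 0.035,
    "PIK3CA",  "H1047R",        "missense_snv", 0.030,
    "KRAS",    "G12C",          "missense_snv", 1799 / 63220,
    "PIK3CA",  "E545K",         "missense_snv", 1713 / 63220,
    "TP53",    "R175H",         "missense_snv", 0.028,
    "IDH1",    "R132H",         "missense_snv", 0.025,
    "TP53",    "R273H",         "missense_snv", 0.022,
    "TP53",    "R248Q",         "missense_snv", 0.018,
    "EGFR",    "L858R",         "missense_snv", 478 / 63220
  )
}

#' Default alteration class mix
#'
#' Probabilities over alteration classes for background (non-hotspot)
#' events, reflecting a cancer-gene panel where missense SNVs dominate.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_mix <- function() {
  c(
    missense_snv = 0.55,
    truncation = 0.12,
    copy_number = 0.12,
    frameshift = 0.08,
    nonframeshift_indel = 0.05,
    rearrangement = 0.05,
    other = 0.03
  )
}

#' Default HLA-A/B subtype-pair population frequencies
#'
#' The two most common North American/European pairs
#' (A*01:01|B*08:01 at 12.6%, A*02:01|B*44:02 at 10.8%) plus four further
#' plausible pairs; the residual population mass falls into an "other"
#' bucket at simulation time.
#'
#' @return Tibble with columns `subtype`, `frequency`.
#' @export
default_hla_frequencies <- function() {
  tibble::tribble(
    ~subtype,            ~frequency,
    "A*01:01|B*08:01",   0.126,
    "A*02:01|B*44:02",   0.108,
    "A*02:01|B*07:02",   0.085,
    "A*03:01|B*07:02",   0.065,
    "A*02:01|B*40:01",   0.050,
    "A*24:02|B*35:01",   0.040
  )
}

#' @export
print.cohort_sim_params <- function(x, ...) {
  cat("<cohort_sim_params>\n")
  cat(sprintf("  tumors: %d, genes: %d, seed: %d\n",
              x$n_tumors, x$n_genes, x$seed))
  cat(sprintf("  alterations/tumor: NB(mean = %g, size = %g)\n",
              x$alterations_per_tumor[["mean"]],
              x$alterations_per_tumor[["dispersion"]]))
  cat(sprintf("  hotspots: %d, HLA pairs: %d\n",
              nrow(x$hotspot_spec), nrow(x$hla_frequency_table)))
  invisible(x)
}
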