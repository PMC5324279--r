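#' Run configuration for the end-to-end analysis
#'
#' Defaults follow the analysis conventions used throughout the package: a
#' recurrence cutoff of 10 tumors, ±25-aa windows, MHC-I peptide lengths
#' 8-11, selection sets of size 10.
#'
#' @param alterations,proteins,hla,subtype_frequencies Input file paths
#'   (may be `NULL` when the corresponding object is passed directly to
#'   [run_analysis()]).
#' @param level Key level for uniqueness/selection reporting.
#' @param min_tumors Recurrence cutoff in tumors.
#' @param flank Window flank in amino acids.
#' @param lengths MHC-I peptide lengths.
#' @param k Selection set size.
#' @param binder_quantile Surrogate predictor binder quantile.
#' @param seed Integer seed for the predictor.
#' @param out_dir Optional output directory for reports.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alterations = NULL, proteins = NULL, hla = NULL,
                       subtype_frequencies = NULL, level = "variant",
                       min_tumors = 10, flank = 25, lengths = 8:11,
                       k = 10, binder_quantile = 0.02, seed = 1L,
                       out_dir = NULL) {
  if (min_tumors < 1 || flank < 0 || k < 1) {
    abort("need min_tumors >= 1, flank >= 0, k >= 1")
  }
  structure(
    list(alterations = alterations, proteins = proteins, hla = hla,
         subtype_frequencies = subtype_frequencies, level = level,
         min_tumors = min_tumors, flank = flank, lengths = lengths, k = k,
         binder_quantile = binder_quantile, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

#' End-to-end cohort analysis
#'
#' Orchestrates the full pipeline on one cohort: mutanome uniqueness at all
#' three key levels, the cumulative AND-chain and additive OR-cover at the
#' gene level, recurrence filtering, the OR-cover over recurrent
#' missense/in-frame-indel variants, surrogate MHC-I neoantigen calling
#' over the alleles of the supplied subtype pairs, per-pair
#' neoantigen-producer fractions, greedy producer sets, and their cohort
#' and general-population applicability.
#'
#' @param x A `synthetic_cohort`, or an alteration tibble (then supply
#'   `proteins` and `hla`).
#' @param subtype_frequencies Tibble `subtype`, `frequency`; pairs named
#'   `"A|B"` define the MHC-I allele panel.
#' @param proteins,hla Reference proteins and HLA assignments (unneeded for
#'   a `synthetic_cohort`).
#' @param config A [run_config()].
#' @param predictor Optional [mhc_predictor()]; defaults to
#'   [surrogate_predictor()] over the panel with the config seed.
#' @return A list of class `neovax_report`: tibbles `uniqueness`,
#'   `and_chain`, `gene_or_cover`, `variant_or_cover`, `recurrent`,
#'   `producer_fractions`, `applicability`, plus `calls`, `n_skipped`, and
#'   the `config`.
#' @export
run_analysis <- function(x, subtype_frequencies,
                         proteins = NULL, hla = NULL,
                         config = run_config(), predictor = NULL) {
  if (inherits(x, "synthetic_cohort")) {
    proteins <- proteins %||% x$proteins
  }
  if (is.null(proteins)) abort("reference proteins are required")

  pairs <- subtype_frequencies$subtype
  pair_alleles <- strsplit(pairs, "|", fixed = TRUE)
  panel <- unique(unlist(pair_alleles))
  predictor <- predictor %||% surrogate_predictor(
    panel, seed = config$seed, binder_quantile = config$binder_quantile,
    lengths = config$lengths
  )

  uniq <- uniqueness_summary(x)
  chain <- and_chain(x, level = "gene", k = config$k)
  gene_keys <- unique(keys_at_level(x, "gene")$key)
  gene_cover <- or_cover(x, gene_keys, level = "gene", k = config$k)

  recurrent <- recurrent_alterations(x, min_tumors = config$min_tumors)
  variant_cover <- NULL
  calls <- tibble::tibble(variant_key = character(), allele = character(),
                          peptide = character(), total_score = numeric())
  n_skipped <- 0L
  if (nrow(recurrent) > 0) {
    variant_cover <- or_cover(x, recurrent$key, level = "variant",
                              k = config$k)
    calls <- withCallingHandlers(
      call_cohort_neoantigens(recurrent, proteins, panel, predictor,
                              flank = config$flank, lengths = config$lengths),
      warning = function(w) {
        n_skipped <<- as.integer(gsub("\\D", "", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  producer_fractions <- purrr::map2_dfr(pairs, pair_alleles, function(p, al) {
    tibble::tibble(
      subtype = p,
      n_recurrent = nrow(recurrent),
      n_producers = length(intersect(
        unique(calls$variant_key[calls$allele %in% al]), recurrent$key
      )),
      producer_pct = if (nrow(recurrent) > 0) {
        neoantigen_producer_fraction(calls, recurrent$key, alleles = al)
      } else NA_real_
    )
  })

  selections <- setNames(purrr::map2(pairs, pair_alleles, function(p, al) {
    producers <- intersect(
      unique(calls$variant_key[calls$allele %in% al]), recurrent$key
    )
    if (length(producers) == 0) return(character(0))
    or_cover(x, producers, level = "variant", k = config$k)$key
  }), pairs)

  has_carriers <- vapply(pairs, function(p) {
    tb <- as_cohort_tbls(x)
    s <- tb$samples
    if (!"hla_subtype" %in% names(s)) {
      s <- dplyr::left_join(s, hla, by = "sample_id")
    }
    any(!is.na(s$hla_subtype) & s$hla_subtype == p)
  }, logical(1))
  usable <- pairs[has_carriers & lengths(selections[pairs]) > 0]
  applicability <- if (length(usable) > 0) {
    applicability_table(x, selections[usable], subtype_frequencies,
                        hla = hla, level = "variant")
  } else {
    tibble::tibble(subtype = character(), k = integer(),
                   cohort_fraction = numeric(),
                   population_frequency = numeric(),
                   population_pct = numeric(),
                   population_pct_display = character())
  }

  structure(
    list(
      uniqueness = uniq, and_chain = chain, gene_or_cover = gene_cover,
      variant_or_cover = variant_cover, recurrent = recurrent,
      producer_fractions = producer_fractions,
      producer_selections = selections, applicability = applicability,
      calls = calls, n_skipped = n_skipped, config = config
    ),
    class = "neovax_report"
  )
}

#' @export
print.neovax_report <- function(x, ...) {
  cat("<neovax_report>\n")
  cat("  uniqueness:\n")
  for (i in seq_len(nrow(x$uniqueness))) {
    cat(sprintf("    %-8s %5.1f%%\n", x$uniqueness$level[i],
                100 * x$uniqueness$unique_fraction[i]))
  }
  cat(sprintf("  recurrent variants (>= %d tumors): %d\n",
              x$config$min_tumors, nrow(x$recurrent)))
  if (nrow(x$producer_fractions) > 0) {
    for (i in seq_len(nrow(x$producer_fractions))) {
      cat(sprintf("  producers %s: %d/%d (%s)\n",
                  x$producer_fractions$subtype[i],
                  x$producer_fractions$n_producers[i],
                  x$producer_fractions$n_recurrent[i],
                  format_pct(x$producer_fractions$producer_pct[i])))
    }
  }
  if (nrow(x$applicability) > 0) {
    for (i in seq_len(nrow(x$applicability))) {
      cat(sprintf("  applicability %s: cohort %s -> population %s\n",
                  x$applicability$subtype[i],
                  format_pct(100 * x$applicability$cohort_fraction[i]),
                  x$applicability$population_pct_display[i]))
    }
  }
  invisible(x)
}

#' One-row summary of a cohort analysis report
#'
#' @param x A `neovax_report`.
#' @param ... Unused.
#' @return One-row tibble with headline quantities.
#' @method glance neovax_report
#' @export
glance.neovax_report <- function(x, ...) {
  tibble::tibble(
    uniqueness_gene = x$uniqueness$unique_fraction[x$uniqueness$level == "gene"],
    uniqueness_variant =
      x$uniqueness$unique_fraction[x$uniqueness$level == "variant"],
    n_recurrent = nrow(x$recurrent),
    top_gene_cover = glance(x$gene_or_cover)$final_fraction,
    top_variant_cover = if (is.null(x$variant_or_cover)) NA_real_ else {
      glance(x$variant_or_cover)$final_fraction
    },
    n_calls = nrow(x$calls),
    n_skipped = x$n_skipped
  )
}

#' Write a report to disk (JSON summary plus TSV selections)
#'
#' @param report A `neovax_report`.
#' @param dir Output directory.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_coverage_selection(report$and_chain, file.path(dir, "and_chain.tsv"))
  write_coverage_selection(report$gene_or_cover,
                           file.path(dir, "gene_or_cover.tsv"))
  if (!is.null(report$variant_or_cover)) {
    write_coverage_selection(report$variant_or_cover,
                             file.path(dir, "variant_or_cover.tsv"))
  }
  readr::write_tsv(report$calls, file.path(dir, "neoantigen_calls.tsv"))
  summary <- list(
    uniqueness = report$uniqueness,
    and_chain = tibble::as_tibble(report$and_chain),
    gene_or_cover = tibble::as_tibble(report$gene_or_cover),
    variant_or_cover = if (is.null(report$variant_or_cover)) NULL else {
      tibble::as_tibble(report$variant_or_cover)
    },
    producer_fractions = report$producer_fractions,
    applicability = report$applicability,
    n_recurrent = nrow(report$recurrent),
    n_calls = nrow(report$calls),
    n_skipped = report$n_skipped
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(summary, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
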