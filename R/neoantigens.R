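# Neoantigen calling: binder prediction on mutant windows with wild-type
# binder subtraction, the step that turns predicted binders into
# mutant-specific (neo)antigens.

#' Call MHC-I neoantigens for one peptide window
#'
#' For each allele, scores every wild-type and mutant k-mer, keeps mutant
#' binders, and subtracts — by exact peptide-string match — *all* wild-type
#' binders of that allele (not only positionally overlapping ones). What
#' remains is mutant-specific: either a peptide covering the altered
#' residue(s) or a novel fragment created by the alteration (e.g. through a
#' changed cleavage context).
#'
#' @param window A `peptide_window` from [extract_windows()].
#' @param alleles Character vector of MHC-I alleles to call.
#' @param predictor An [mhc_predictor()] covering `alleles`.
#' @param lengths MHC-I peptide lengths (default 8-11).
#'
#' @return Tibble of class `neoantigen_calls` with columns `variant_key`,
#'   `allele`, `peptide`, `total_score`; zero rows when nothing is
#'   mutant-specific.
#' @export
call_mhc1_neoantigens <- function(window, alleles, predictor, lengths = 8:11) {
  missing <- setdiff(alleles, predictor$alleles)
  if (length(missing) > 0) {
    abort(sprintf("predictor does not cover allele(s): %s", toString(missing)))
  }
  cand <- enumerate_candidates(window, lengths)
  out <- purrr::map(alleles, function(a) {
    wt_binders <- dplyr::filter(predict_binding(predictor, cand$wt, a),
                                .data$is_binder)$peptide
    mut <- dplyr::filter(predict_binding(predictor, cand$mut, a),
                         .data$is_binder)
    mut <- dplyr::filter(mut, !.data$peptide %in% wt_binders)
    if (nrow(mut) == 0) return(NULL)
    tibble::tibble(
      variant_key = window$variant_key, allele = a,
      peptide = mut$peptide, total_score = mut$total_score
    )
  })
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      variant_key = character(), allele = character(),
      peptide = character(), total_score = numeric()
    )
  }
  structure(calls, class = c("neoantigen_calls", class(tibble::tibble())))
}

#' Call MHC-II neoantigens with the dual-method consensus rule
#'
#' A 15-mer is an MHC-II binder only if its predicted IC50 is below the
#' threshold under *both* component methods (emulating SMM and NN inside a
#' consensus predictor); thresholds follow the high/low affinity convention
#' of 50 and 500 nM. Wild-type binders are then subtracted exactly as for
#' MHC-I.
#'
#' @param window A `peptide_window`.
#' @param allele MHC-II allele name.
#' @param predictor_a,predictor_b Two [surrogate_mhc2_predictor()]-style
#'   component predictors.
#' @param ic50_threshold_nm Either 50 ("high affinity") or 500
#'   ("low affinity").
#' @param length MHC-II peptide length (default 15).
#'
#' @return Tibble of class `neoantigen_calls` with columns `variant_key`,
#'   `allele`, `peptide`, `ic50_a_nm`, `ic50_b_nm`.
#' @export
call_mhc2_neoantigens <- function(window, allele, predictor_a, predictor_b,
                                  ic50_threshold_nm = 500, length = 15) {
  if (!ic50_threshold_nm %in% c(50, 500)) {
    abort("`ic50_threshold_nm` must be 50 or 500")
  }
  cand <- enumerate_candidates(window, length)
  dual_binders <- function(peps) {
    if (length(peps) == 0) return(tibble::tibble(
      peptide = character(), ic50_a_nm = numeric(), ic50_b_nm = numeric()
    ))
    a <- predict_ic50(predictor_a, peps)
    b <- predict_ic50(predictor_b, peps)
    keep <- a < ic50_threshold_nm & b < ic50_threshold_nm
    tibble::tibble(peptide = peps[keep], ic50_a_nm = a[keep], ic50_b_nm = b[keep])
  }
  wt <- dual_binders(cand$wt)
  mut <- dual_binders(cand$mut) |>
    dplyr::filter(!.data$peptide %in% wt$peptide)
  structure(
    tibble::tibble(
      variant_key = rep(window$variant_key, nrow(mut)),
      allele = rep(allele, nrow(mut)),
      peptide = mut$peptide, ic50_a_nm = mut$ic50_a_nm, ic50_b_nm = mut$ic50_b_nm
    ),
    class = c("neoantigen_calls", class(tibble::tibble()))
  )
}

#' Call MHC-I neoantigens for every recurrent variant in a cohort
#'
#' Convenience driver: extracts windows for each (parseable) recurrent
#' missense/in-frame-indel variant against the reference proteins and runs
#' [call_mhc1_neoantigens()] across the allele panel. Variants whose gene
#' has no reference protein are skipped with a warning count.
#'
#' @param recurrent Tibble from [recurrent_alterations()].
#' @param proteins Tibble `gene`, `sequence` (e.g. from a
#'   `synthetic_cohort` or [read_proteins()]).
#' @param alleles MHC-I allele panel.
#' @param predictor An [mhc_predictor()].
#' @param flank,lengths Window flank and peptide lengths.
#' @return `neoantigen_calls` tibble over all variants and alleles.
#' @export
call_cohort_neoantigens <- function(recurrent, proteins, alleles, predictor,
                                    flank = 25, lengths = 8:11) {
  seq_by_gene <- setNames(proteins$sequence, proteins$gene)
  skipped <- 0L
  out <- purrr::pmap(
    recurrent[c("gene", "protein_change", "alt_class")],
    function(gene, protein_change, alt_class) {
      prot <- unname(seq_by_gene[gene])
      if (is.na(prot)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      w <- extract_windows(prot, protein_change, alt_class,
                           gene = gene, flank = flank)
      call_mhc1_neoantigens(w, alleles, predictor, lengths)
    }
  )
  if (skipped > 0) {
    warning(sprintf("%d variant(s) skipped: no reference protein", skipped))
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      variant_key = character(), allele = character(),
      peptide = character(), total_score = numeric()
    )
  }
  structure(calls, class = c("neoantigen_calls", class(tibble::tibble())))
}

#' Fraction of recurrent alterations predicted to produce a neoantigen
#'
#' @param calls A `neoantigen_calls` tibble.
#' @param recurrent_keys Character vector of recurrent variant keys (the
#'   denominator universe).
#' @param alleles Optional allele restriction (e.g. the two alleles of one
#'   HLA-A/B subtype pair; a key counts if it produces a mutant-specific
#'   binder for *either* allele). Default: all alleles present in `calls`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' # 62 producers among 2833 recurrent variants -> 2.2%
#' calls <- tibble::tibble(
#'   variant_key = paste0("G|V", 1:62), allele = "A*01:01", peptide = "X"
#' )
#' neoantigen_producer_fraction(calls, paste0("G|V", 1:2833))
neoantigen_producer_fraction <- function(calls, recurrent_keys,
                                         alleles = NULL) {
  if (length(recurrent_keys) == 0) abort("`recurrent_keys` must be non-empty")
  if (!is.null(alleles)) {
    calls <- dplyr::filter(calls, .data$allele %in% alleles)
  }
  producers <- intersect(unique(calls$variant_key), recurrent_keys)
  100 * length(producers) / length(unique(recurrent_keys))
}

#' Allele-restriction histogram of mutant-specific binders
#'
#' For each mutant-specific binder peptide, counts the number of distinct
#' alleles in the panel that present it; most MHC-I binders are expected to
#' be restricted to a single HLA type.
#'
#' @param calls A `neoantigen_calls` tibble over an allele panel.
#' @param panel Character vector of panel alleles (at least 2); bins run
#'   1..`length(panel)`.
#' @return Tibble with columns `n_alleles`, `peptide_count` (all bins
#'   present, zero-filled).
#' @export
allele_restriction_profile <- function(calls, panel) {
  panel <- unique(panel)
  if (length(panel) < 2) abort("`panel` must contain at least 2 alleles")
  bins <- tibble::tibble(n_alleles = seq_along(panel))
  if (nrow(calls) == 0) {
    return(dplyr::mutate(bins, peptide_count = 0L))
  }
  per_pep <- calls |>
    dplyr::filter(.data$allele %in% panel) |>
    dplyr::distinct(.data$peptide, .data$allele) |>
    dplyr::count(.data$peptide, name = "n_alleles") |>
    dplyr::count(.data$n_alleles, name = "peptide_count")
  bins |>
    dplyr::left_join(per_pep, by = "n_alleles") |>
    dplyr::mutate(peptide_count = dplyr::coalesce(.data$peptide_count, 0L))
}

#' Plot an allele-restriction profile
#'
#' @param profile Tibble from [allele_restriction_profile()].
#' @return A ggplot object.
#' @export
plot_allele_restriction <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = factor(.data$n_alleles), y = .data$peptide_count
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "alleles presenting the peptide",
                  y = "mutant-specific binder peptides") +
    ggplot2::theme_minimal()
}
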