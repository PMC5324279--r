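#' Extract wild-type and mutant peptide windows around an alteration
#'
#' Cuts the window of `flank` amino acids on each side of the altered
#' residue(s) out of the reference protein (truncated at the termini) and
#' applies the alteration to produce the mutant window. Only missense SNVs
#' and non-frameshift indels are accepted; frameshift events are rejected.
#' The reference residues named in the protein change must match the
#' protein, otherwise an error reports the position and residues.
#'
#' @param protein Reference protein sequence (single amino-acid string).
#' @param protein_change Short HGVS-p string (see [parse_protein_change()]).
#' @param alt_class Alteration class; must be `"missense_snv"` or
#'   `"nonframeshift_indel"`.
#' @param gene Gene symbol, used to form the variant key.
#' @param flank Number of flanking residues on each side (default 25).
#'
#' @return One-row tibble of class `peptide_window`: `variant_key`,
#'   `wt_seq`, `mut_seq`, `window_start` (1-based position in the protein
#'   of the first window residue).
#' @export
#' @examples
#' prot <- strrep("A", 49)
#' prot <- paste0(substr(prot, 1, 24), "G", substr(prot, 25, 49))  # G at 25
#' extract_windows(prot, "G25C", "missense_snv", gene = "KRAS", flank = 10)
extract_windows <- function(protein, protein_change,
                            alt_class = "missense_snv",
                            gene = "GENE", flank = 25) {
  if (alt_class == "frameshift") {
    abort("frameshift events are excluded from window extraction")
  }
  if (!alt_class %in% CODING_CLASSES) {
    abort(sprintf("no peptide window for alteration class '%s'", alt_class))
  }
  p <- parse_protein_change(protein_change)
  if (is.na(p$kind)) {
    abort(sprintf("cannot parse protein change '%s'", protein_change))
  }
  L <- nchar(protein)
  if (p$end > L) {
    abort(sprintf("position %d outside protein of length %d", p$end, L))
  }

  check_ref <- function(pos, expected) {
    got <- substr(protein, pos, pos)
    if (got != expected) {
      abort(sprintf(
        "reference mismatch at position %d: protein has '%s', change expects '%s'",
        pos, got, expected
      ))
    }
  }

  win_start <- max(1L, p$pos - flank)
  win_end <- min(L, p$end + flank)
  wt <- substr(protein, win_start, win_end)
  off <- p$pos - win_start + 1L   # alteration start within the window

  if (p$kind == "missense") {
    check_ref(p$pos, p$ref_aa)
    mut <- wt
    substr(mut, off, off) <- p$alt_aa
  } else if (p$kind == "deletion") {
    first_ref <- p$ref_aa
    check_ref(p$pos, first_ref)
    if (p$end > p$pos) {
      last_ref <- stringr::str_match(protein_change, "_([A-Y])\\d+del$")[, 2]
      check_ref(p$end, last_ref)
    }
    del_len <- p$end - p$pos + 1L
    mut <- paste0(substr(wt, 1, off - 1L),
                  substr(wt, off + del_len, nchar(wt)))
  } else {  # insertion between pos and pos + 1
    flanks <- stringr::str_match(protein_change, "^([A-Y])\\d+_([A-Y])\\d+ins")
    check_ref(p$pos, flanks[, 2])
    check_ref(p$end, flanks[, 3])
    mut <- paste0(substr(wt, 1, off), p$ins_seq,
                  substr(wt, off + 1L, nchar(wt)))
  }

  structure(
    tibble::tibble(
      variant_key = variant_key(gene, alt_class, protein_change),
      wt_seq = wt, mut_seq = mut, window_start = win_start
    ),
    class = c("peptide_window", class(tibble::tibble()))
  )
}

# all contiguous k-mers of the given lengths, de-duplicated
kmers <- function(seq, lengths) {
  L <- nchar(seq)
  out <- character(0)
  for (k in lengths) {
    if (L >= k) {
      out <- c(out, substring(seq, 1:(L - k + 1), k:L))
    }
  }
  unique(out)
}

#' Enumerate candidate peptides from a peptide window
#'
#' All contiguous k-mers of each requested length from the wild-type and
#' mutant windows, de-duplicated within each set.
#'
#' @param window A `peptide_window` from [extract_windows()].
#' @param lengths Integer peptide lengths, each in 8..15 (8-11 for MHC-I,
#'   15 for MHC-II).
#'
#' @return List with character vectors `wt` and `mut`.
#' @export
enumerate_candidates <- function(window, lengths = 8:11) {
  if (any(lengths < 8 | lengths > 15)) {
    abort("peptide lengths must lie in 8..15")
  }
  list(
    wt = kmers(window$wt_seq, lengths),
    mut = kmers(window$mut_seq, lengths)
  )
}
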