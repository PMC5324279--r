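# Short-form HGVS-p parsing (no "p." prefix), covering the protein changes
# this package generates and analyses: missense substitutions ("G12C"),
# in-frame deletions ("E545del", "E545_K547del") and in-frame insertions
# ("K545_E546insGA"). All coordinates are 1-based amino-acid positions.

#' Parse short HGVS-p protein change strings
#'
#' @param protein_change Character vector of short HGVS-p strings
#'   (e.g. `"G12C"`, `"E545_K547del"`, `"K545_E546insGA"`).
#'
#' @return Tibble with one row per input: `protein_change`, `kind`
#'   (`"missense"`, `"deletion"`, `"insertion"` or `NA` for unparseable),
#'   `pos` (first affected / left-flank residue), `end` (last affected
#'   residue; equals `pos` for missense and single-residue deletions),
#'   `ref_aa`, `alt_aa` (missense only) and `ins_seq` (insertions only).
#' @export
#' @examples
#' parse_protein_change(c("G12C", "E545_K547del", "K45_E46insGA"))
parse_protein_change <- function(protein_change) {
  pc <- as.character(protein_change)
  out <- tibble::tibble(
    protein_change = pc,
    kind = NA_character_,
    pos = NA_integer_,
    end = NA_integer_,
    ref_aa = NA_character_,
    alt_aa = NA_character_,
    ins_seq = NA_character_
  )

  m <- stringr::str_match(pc, "^([A-Y])(\\d+)([A-Y])$")
  hit <- !is.na(m[, 1])
  out$kind[hit] <- "missense"
  out$pos[hit] <- as.integer(m[hit, 3])
  out$end[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- m[hit, 2]
  out$alt_aa[hit] <- m[hit, 4]

  m <- stringr::str_match(pc, "^([A-Y])(\\d+)del$")
  hit <- !is.na(m[, 1]) & is.na(out$kind)
  out$kind[hit] <- "deletion"
  out$pos[hit] <- as.integer(m[hit, 3])
  out$end[hit] <- as.integer(m[hit, 3])
  out$ref_aa[hit] <- m[hit, 2]

  m <- stringr::str_match(pc, "^([A-Y])(\\d+)_([A-Y])(\\d+)del$")
  hit <- !is.na(m[, 1]) & is.na(out$kind)
  out$kind[hit] <- "deletion"
  out$pos[hit] <- as.integer(m[hit, 3])
  out$end[hit] <- as.integer(m[hit, 5])
  out$ref_aa[hit] <- m[hit, 2]

  m <- stringr::str_match(pc, "^([A-Y])(\\d+)_([A-Y])(\\d+)ins([A-Y]+)$")
  hit <- !is.na(m[, 1]) & is.na(out$kind)
  out$kind[hit] <- "insertion"
  out$pos[hit] <- as.integer(m[hit, 3])
  out$end[hit] <- as.integer(m[hit, 5])
  out$ins_seq[hit] <- m[hit, 6]

  bad <- !is.na(out$kind) & !is.na(out$end) & out$kind == "insertion" &
    out$end != out$pos + 1L
  out$kind[bad] <- NA_character_

  out
}
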