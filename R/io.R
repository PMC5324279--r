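# Bit-stable readers/writers for the artifact formats: MAF-like alteration
# TSV, protein FASTA, HLA assignment CSV, subtype frequency CSV, JSON
# reports. TSV dialect: UTF-8, header row, "." for missing values, 1-based
# protein coordinates.

na_dot <- function(x) dplyr::if_else(is.na(x) | x == "", ".", x)

#' Write a cohort's alteration table as MAF-like TSV
#'
#' Columns: `sample_id`, `disease`, `gene`, `class`, `protein_change`
#' (`"."` when absent).
#'
#' @param alterations Tibble with columns `sample_id`, `disease`, `gene`,
#'   `alt_class`, `protein_change`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alterations <- function(alterations, path) {
  out <- alterations |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      disease = .data$disease,
      gene = .data$gene,
      class = .data$alt_class,
      protein_change = na_dot(.data$protein_change)
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a MAF-like alteration TSV
#'
#' Requires columns `sample_id`, `gene`, `class`, `protein_change`
#' (`disease` optional; extra columns are ignored). `"."` protein changes
#' become empty strings; `protein_position` is derived by parsing the
#' protein change.
#'
#' @param path TSV path.
#' @return Alteration tibble as used throughout the package.
#' @export
read_alterations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("sample_id", "gene", "class", "protein_change")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("alteration TSV is missing column(s): %s", toString(missing)))
  }
  if (!all(raw$class %in% ALT_CLASSES)) {
    bad <- setdiff(unique(raw$class), ALT_CLASSES)
    abort(sprintf("unknown alteration class(es): %s", toString(bad)))
  }
  pc <- dplyr::if_else(raw$protein_change == "." | is.na(raw$protein_change),
                       "", raw$protein_change)
  tibble::tibble(
    sample_id = raw$sample_id,
    disease = raw$disease %||% NA_character_,
    gene = raw$gene,
    alt_class = raw$class,
    protein_change = pc,
    protein_position = parse_protein_change(pc)$pos
  )
}

#' Write protein sequences as FASTA
#'
#' Uses Biostrings when installed; otherwise a plain 60-column writer.
#'
#' @param proteins Tibble with columns `gene`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$gene))
    Biostrings::writeXStringSet(aa, path, width = 60)
  } else {
    lines <- unlist(purrr::map2(proteins$gene, proteins$sequence, function(g, s) {
      c(paste0(">", g),
        substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))))
    }))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return Tibble with columns `gene`, `sequence`, `length`.
#' @export
read_proteins <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- unname(as.character(aa))
    tibble::tibble(
      gene = sub("\\s.*$", "", names(aa)),
      sequence = seqs,
      length = nchar(seqs)
    )
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    gene <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   paste, character(1), collapse = "")
    tibble::tibble(gene = gene, sequence = unname(seqs),
                   length = nchar(unname(seqs)))
  }
}

#' Write / read HLA subtype assignments (CSV: sample_id, subtype)
#' @param hla Tibble with columns `sample_id`, `hla_subtype`.
#' @param path CSV path.
#' @return `path` invisibly (write); tibble `sample_id`, `hla_subtype` (read).
#' @export
write_hla_assignments <- function(hla, path) {
  readr::write_csv(
    dplyr::transmute(hla, sample_id = .data$sample_id,
                     subtype = .data$hla_subtype),
    path
  )
  invisible(path)
}

#' @rdname write_hla_assignments
#' @export
read_hla_assignments <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample_id", "subtype") %in% names(raw))) {
    abort("HLA CSV needs columns sample_id, subtype")
  }
  tibble::tibble(sample_id = raw$sample_id, hla_subtype = raw$subtype)
}

#' Read an HLA subtype population-frequency table (CSV: subtype, frequency)
#' @param path CSV path.
#' @return Tibble `subtype`, `frequency`.
#' @export
read_subtype_frequencies <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(subtype = "c",
                                                       frequency = "d"),
                         progress = FALSE)
  if (!all(c("subtype", "frequency") %in% names(raw))) {
    abort("frequency CSV needs columns subtype, frequency")
  }
  if (any(raw$frequency <= 0 | raw$frequency > 1)) {
    abort("subtype frequencies must lie in (0, 1]")
  }
  tibble::tibble(subtype = raw$subtype, frequency = raw$frequency)
}

#' Write a coverage selection as TSV
#'
#' Columns: rank, key, marginal_count, cumulative_count, cumulative_fraction.
#'
#' @param selection A `coverage_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_selection <- function(selection, path) {
  readr::write_tsv(tibble::as_tibble(selection), path)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Writes the four cohort artifacts: `alterations.tsv` (MAF-like),
#' `proteins.fasta`, `hla_assignments.csv` and `ground_truth.json`.
#' Identical seeds produce byte-identical files.
#'
#' @param sim A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
simulate_to_files <- function(sim, dir) {
  if (!inherits(sim, "synthetic_cohort")) {
    abort("`sim` must be a synthetic_cohort")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alterations = file.path(dir, "alterations.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    hla = file.path(dir, "hla_assignments.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_alterations(sim$alterations, paths[["alterations"]])
  write_proteins(sim$proteins, paths[["proteins"]])
  write_hla_assignments(
    dplyr::select(sim$samples, "sample_id", "hla_subtype"),
    paths[["hla"]]
  )
  jsonlite::write_json(sim$ground_truth, paths[["ground_truth"]],
                       dataframe = "columns", digits = NA)
  invisible(paths)
}
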