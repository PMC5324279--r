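# Independent oracles and small fixture builders shared across tests.

# Quadratic all-pairs uniqueness: a tumor is unique iff no other tumor has
# exactly the same key set. Deliberately naive (setequal over per-tumor
# character vectors).
brute_force_uniqueness <- function(x, level) {
  keys <- keys_at_level(x, level)
  samples <- if (inherits(x, "synthetic_cohort")) {
    x$samples$sample_id
  } else {
    unique(x$sample_id)
  }
  sets <- lapply(samples, function(s) keys$key[keys$sample_id == s])
  n <- length(sets)
  unique_flag <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && setequal(sets[[i]], sets[[j]])) {
        unique_flag[i] <- FALSE
        break
      }
    }
  }
  mean(unique_flag)
}

# Two-sided Fisher p by direct hypergeometric pmf summation: sum the
# probabilities of all tables with the observed margins that are no more
# likely than the observed table (with the standard relative tolerance for
# "no more likely").
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All distinct substrings of the given lengths, by explicit loops.
substring_oracle <- function(seq, lengths) {
  out <- character(0)
  for (k in lengths) {
    if (nchar(seq) >= k) {
      for (i in seq_len(nchar(seq) - k + 1)) {
        out <- c(out, substr(seq, i, i + k - 1))
      }
    }
  }
  unique(out)
}

# Minimal alteration-table builder: one row per (sample, gene, class, change).
make_alterations <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      sample_id = r[[1]], gene = r[[2]], alt_class = r[[3]],
      protein_change = if (length(r) >= 4) r[[4]] else ""
    )
  }))
}

# A cohort where tumor i carries exactly the listed keys, expressed as
# gene-level memberships (for selection tests): `members` is a named list
# key -> integer tumor ids over 1..n_tumors.
membership_cohort <- function(members, n_tumors) {
  alt <- dplyr::bind_rows(purrr::imap(members, function(tumors, key) {
    tibble::tibble(
      sample_id = sprintf("T%03d", tumors), gene = key,
      alt_class = "other", protein_change = ""
    )
  }))
  # tumors carrying no candidate still need to exist in the universe; give
  # each its own private filler key so they join no candidate set
  uncovered <- setdiff(seq_len(n_tumors), unlist(members))
  dplyr::bind_rows(
    alt,
    tibble::tibble(
      sample_id = sprintf("T%03d", uncovered),
      gene = sprintf("PAD%03d", uncovered),
      alt_class = "other", protein_change = ""
    )
  )
}

# A random peptide window around a missense substitution, plus its protein.
random_missense_window <- function(seed, protein_length = 120, flank = 25) {
  withr::with_seed(seed, {
    prot <- paste(
      sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y"),
             protein_length, replace = TRUE),
      collapse = ""
    )
    pos <- sample(seq_len(protein_length), 1)
    ref <- substr(prot, pos, pos)
    alt <- sample(setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                          ref), 1)
    extract_windows(prot, paste0(ref, pos, alt), "missense_snv",
                    gene = "GENEX", flank = flank)
  })
}
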