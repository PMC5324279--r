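#' Generate reference protein sequences for a gene panel
#'
#' Draws one random amino-acid sequence per gene, with lengths uniform in
#' `length_range`, and then forces the reference residues named by
#' `hotspot_spec` (e.g. a G at KRAS position 12 for a `G12C` hotspot) so
#' that hotspot alterations validate against the reference. A gene carrying
#' hotspots is assigned a length at least as large as its right-most
#' hotspot residue.
#'
#' @param genes Character vector of gene symbols.
#' @param hotspot_spec Tibble with columns `gene`, `protein_change`,
#'   `class` (see [cohort_sim_params()]); may have zero rows.
#' @param length_range Length-2 integer range of protein lengths (aa).
#' @param seed Integer seed; same seed gives byte-identical sequences.
#'
#' @return Tibble with columns `gene`, `sequence`, `length`.
#' @export
#' @examples
#' generate_proteins("KRAS", default_hotspots()[5, ], c(150, 200), seed = 1)
generate_proteins <- function(genes, hotspot_spec = NULL,
                              length_range = c(200L, 1200L), seed = 1L) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), sequence = character(),
                          length = integer()))
  }
  hs <- if (is.null(hotspot_spec) || nrow(hotspot_spec) == 0) {
    tibble::tibble(gene = character(), protein_change = character())
  } else {
    tibble::as_tibble(hotspot_spec)
  }
  parsed <- dplyr::bind_cols(hs["gene"], parse_protein_change(hs$protein_change))
  if (any(is.na(parsed$kind))) {
    abort(sprintf("unparseable hotspot protein_change: %s",
                  toString(parsed$protein_change[is.na(parsed$kind)])))
  }
  min_len <- setNames(rep(0L, length(genes)), genes)
  if (nrow(parsed) > 0) {
    need <- parsed |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(need = max(.data$end), .groups = "drop")
    too_long <- need$need > length_range[2]
    if (any(too_long)) {
      abort(sprintf(
        "hotspot position exceeds the maximum protein length (%d): %s",
        length_range[2], toString(need$gene[too_long])
      ))
    }
    min_len[need$gene] <- as.integer(need$need)
  }

  with_seed(seed, {
    lens <- pmax(
      sample(seq(length_range[1], length_range[2]), length(genes),
             replace = TRUE),
      min_len[genes]
    )
    seqs <- random_aa(lens)
    # force hotspot reference residues (and insertion flank letters) so the
    # generated reference matches every hotspot's stated residues
    if (nrow(parsed) > 0) {
      for (i in seq_len(nrow(parsed))) {
        g <- parsed$gene[i]
        j <- match(g, genes)
        if (!is.na(parsed$ref_aa[i])) {
          substr(seqs[j], parsed$pos[i], parsed$pos[i]) <- parsed$ref_aa[i]
        }
        if (parsed$kind[i] == "deletion" && parsed$end[i] > parsed$pos[i]) {
          last_ref <- stringr::str_match(
            parsed$protein_change[i], "_([A-Y])\\d+del$"
          )[, 2]
          substr(seqs[j], parsed$end[i], parsed$end[i]) <- last_ref
        }
        if (parsed$kind[i] == "insertion") {
          flanks <- stringr::str_match(
            parsed$protein_change[i], "^([A-Y])\\d+_([A-Y])\\d+ins"
          )
          substr(seqs[j], parsed$pos[i], parsed$pos[i]) <- flanks[, 2]
          substr(seqs[j], parsed$end[i], parsed$end[i]) <- flanks[, 3]
        }
      }
    }
    tibble::tibble(gene = genes, sequence = seqs, length = as.integer(lens))
  })
}

#' Simulate a synthetic tumor cohort
#'
#' Generates a seeded cohort with the statistical structure the downstream
#' analysis assumes: Zipf-weighted long-tailed gene recurrence, hotspot
#' drivers injected at their target per-tumor frequencies, a negative
#' binomial per-tumor alteration count, background alterations drawn at
#' uniformly random protein positions with uniformly random alternate
#' residues, and one HLA-A/B subtype pair per tumor drawn from the supplied
#' population frequency table (residual mass goes to `"other"`).
#'
#' Hotspots are injected first; background alterations then fill the
#' remaining per-tumor count. Within a tumor, alterations are a set at the
#' variant-key level (duplicates are dropped). Every background missense or
#' in-frame indel is consistent with the generated reference proteins.
#'
#' @param params A [cohort_sim_params()] object.
#'
#' @return A list of class `synthetic_cohort` with elements:
#'   * `samples`: tibble `sample_id`, `disease`, `hla_subtype` (one row per
#'     tumor, including tumors with no alterations);
#'   * `alterations`: tibble `sample_id`, `disease`, `gene`, `alt_class`,
#'     `protein_change`, `protein_position`;
#'   * `proteins`: tibble `gene`, `sequence`, `length`;
#'   * `ground_truth`: list of the true gene probabilities, hotspot
#'     frequencies, and HLA subtype fractions the cohort was drawn from;
#'   * `params`: the input parameters.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_params(n_tumors = 200, seed = 7))
#' nrow(sim$samples)
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_sim_params")) {
    abort("`params` must be created by cohort_sim_params()")
  }
  n <- params$n_tumors
  hs <- params$hotspot_spec

  gene_universe <- unique(c(hs$gene, sprintf("GENE%03d", seq_len(params$n_genes))))
  gene_universe <- gene_universe[seq_len(min(length(gene_universe), params$n_genes))]
  if (!all(hs$gene %in% gene_universe)) {
    abort("`n_genes` too small to hold all hotspot genes")
  }
  weights <- seq_along(gene_universe)^(-params$gene_weight_exponent)
  weights <- weights / sum(weights)

  proteins <- generate_proteins(
    gene_universe, hs, params$protein_length_range,
    seed = hash_seed(params$seed, "proteins")
  )
  len_by_gene <- setNames(proteins$length, proteins$gene)
  seq_by_gene <- setNames(proteins$sequence, proteins$gene)

  diseases <- c("LUAD", "CRC", "BRCA", "MEL", "PRAD", "OTHER")
  disease_p <- c(0.12, 0.12, 0.12, 0.08, 0.08, 0.48)

  with_seed(hash_seed(params$seed, "cohort"), {
    sample_id <- sprintf("T%06d", seq_len(n))
    disease <- sample(diseases, n, replace = TRUE, prob = disease_p)

    hla_tab <- params$hla_frequency_table
    hla_levels <- c(hla_tab$subtype, "other")
    hla_p <- c(hla_tab$frequency, max(0, 1 - sum(hla_tab$frequency)))
    hla_subtype <- sample(hla_levels, n, replace = TRUE, prob = hla_p)

    counts <- rnbinom(
      n,
      size = params$alterations_per_tumor[["dispersion"]],
      mu = params$alterations_per_tumor[["mean"]]
    )

    # hotspots first: independent Bernoulli per (tumor, hotspot)
    hot_list <- vector("list", nrow(hs))
    if (nrow(hs) > 0) {
      for (j in seq_len(nrow(hs))) {
        carriers <- which(runif(n) < hs$frequency[j])
        if (length(carriers) > 0) {
          hot_list[[j]] <- tibble::tibble(
            tumor = carriers,
            gene = hs$gene[j],
            alt_class = hs$class[j],
            protein_change = hs$protein_change[j]
          )
        }
      }
    }
    hot <- dplyr::bind_rows(hot_list)
    if (nrow(hot) == 0) {
      hot <- tibble::tibble(tumor = integer(), gene = character(),
                            alt_class = character(), protein_change = character())
    }
    n_hot <- tabulate(hot$tumor, nbins = n)

    # background fills the remaining per-tumor count
    n_bg <- pmax(0L, counts - n_hot)
    total_bg <- sum(n_bg)
    bg <- NULL
    if (total_bg > 0) {
      tumor <- rep.int(seq_len(n), n_bg)
      gene <- sample(gene_universe, total_bg, replace = TRUE, prob = weights)
      alt_class <- sample(names(params$class_mix), total_bg, replace = TRUE,
                          prob = params$class_mix)
      L <- unname(len_by_gene[gene])
      protein_change <- character(total_bg)
      protein_position <- rep(NA_integer_, total_bg)

      is_mis <- alt_class == "missense_snv"
      if (any(is_mis)) {
        pos <- 1L + as.integer(floor(runif(sum(is_mis)) * L[is_mis]))
        ref <- substring(seq_by_gene[gene[is_mis]], pos, pos)
        # uniform alternate residue, excluding the reference residue
        shift <- 1L + as.integer(floor(runif(sum(is_mis)) * 19))
        alt <- AA_ALPHABET[(match(ref, AA_ALPHABET) + shift - 1L) %% 20L + 1L]
        protein_change[is_mis] <- paste0(ref, pos, alt)
        protein_position[is_mis] <- pos
      }

      is_ind <- alt_class == "nonframeshift_indel"
      if (any(is_ind)) {
        k <- sum(is_ind)
        Li <- L[is_ind]
        si <- seq_by_gene[gene[is_ind]]
        w <- 1L + as.integer(floor(runif(k) * 3))   # 1-3 aa
        is_del <- runif(k) < 0.5
        pos <- integer(k)
        pc <- character(k)
        # deletions: remove residues pos..pos+w-1
        pos[is_del] <- 1L + as.integer(
          floor(runif(sum(is_del)) * pmax(1L, Li[is_del] - w[is_del]))
        )
        if (any(is_del)) {
          d_end <- pos[is_del] + w[is_del] - 1L
          a1 <- substring(si[is_del], pos[is_del], pos[is_del])
          a2 <- substring(si[is_del], d_end, d_end)
          pc[is_del] <- ifelse(
            w[is_del] == 1L,
            paste0(a1, pos[is_del], "del"),
            paste0(a1, pos[is_del], "_", a2, d_end, "del")
          )
        }
        # insertions: insert w residues between pos and pos+1
        ins <- !is_del
        if (any(ins)) {
          pos[ins] <- 1L + as.integer(floor(runif(sum(ins)) * (Li[ins] - 1L)))
          a1 <- substring(si[ins], pos[ins], pos[ins])
          a2 <- substring(si[ins], pos[ins] + 1L, pos[ins] + 1L)
          pc[ins] <- paste0(a1, pos[ins], "_", a2, pos[ins] + 1L,
                            "ins", random_aa(w[ins]))
        }
        protein_change[is_ind] <- pc
        protein_position[is_ind] <- pos
      }

      bg <- tibble::tibble(tumor, gene, alt_class, protein_change)
    }

    alt <- dplyr::bind_rows(hot, bg)
    samples <- tibble::tibble(sample_id, disease, hla_subtype)
    if (nrow(alt) > 0) {
      hot_pos <- parse_protein_change(alt$protein_change)$pos
      alt <- alt |>
        dplyr::mutate(
          sample_id = .env$sample_id[.data$tumor],
          disease = .env$disease[.data$tumor],
          protein_position = hot_pos
        ) |>
        # set semantics at the variant-key level within a tumor
        dplyr::distinct(
          .data$sample_id,
          key = variant_key(.data$gene, .data$alt_class, .data$protein_change),
          .keep_all = TRUE
        ) |>
        dplyr::arrange(.data$sample_id, .data$gene, .data$protein_change) |>
        dplyr::select("sample_id", "disease", "gene", "alt_class",
                      "protein_change", "protein_position")
    } else {
      alt <- tibble::tibble(
        sample_id = character(), disease = character(), gene = character(),
        alt_class = character(), protein_change = character(),
        protein_position = integer()
      )
    }

    ground_truth <- list(
      gene_prob = tibble::tibble(gene = gene_universe, prob = weights),
      hotspot = hs |> dplyr::select("gene", "protein_change", "frequency"),
      hla = tibble::tibble(subtype = hla_levels, frequency = hla_p)
    )

    structure(
      list(samples = samples, alterations = alt, proteins = proteins,
           ground_truth = ground_truth, params = params),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d tumors, %d alterations, %d genes (seed %d)\n",
              nrow(x$samples), nrow(x$alterations), nrow(x$proteins),
              x$params$seed))
  invisible(x)
}
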