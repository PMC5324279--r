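toy_hotspots <- tibble::tibble(
  gene = c("KRAS", "TP53", "BRAF"),
  protein_change = c("G12C", "R175H", "V600E"),
  class = "missense_snv",
  frequency = 0.01
)
toy_proteins <- generate_proteins(c("KRAS", "TP53", "BRAF", "EGFR"),
                                  toy_hotspots, c(650, 700), seed = 2)
toy_alts <- make_alterations(
  list("T1", "KRAS", "missense_snv", "G12C"),
  list("T1", "TP53", "missense_snv", "R175H"),
  list("T2", "KRAS", "missense_snv", "G12C"),
  list("T2", "TP53", "missense_snv", "R175H"),
  list("T3", "KRAS", "missense_snv", "G12C"),
  list("T4", "BRAF", "missense_snv", "V600E"),
  list("T5", "EGFR", "copy_number", "")
)
toy_hla <- tibble::tibble(
  sample_id = paste0("T", 1:5),
  hla_subtype = c("A*01:01|B*08:01", "A*01:01|B*08:01", "A*02:01|B*44:02",
                  "other", "other")
)
toy_freqs <- tibble::tibble(
  subtype = c("A*01:01|B*08:01", "A*02:01|B*44:02"),
  frequency = c(0.126, 0.108)
)
toy_config <- run_config(min_tumors = 2, seed = 1)

test_that("the five-tumor fixture reproduces hand-computed values", {
  rep <- run_analysis(toy_alts, toy_freqs, proteins = toy_proteins,
                      hla = toy_hla, config = toy_config)
  # two identical mutanomes (T1, T2) out of five -> 3/5 unique at all levels
  expect_equal(rep$uniqueness$unique_fraction, rep(0.6, 3))
  # AND-chain: KRAS in 3 tumors, KRAS & TP53 in 2, nothing deeper
  expect_equal(rep$and_chain$key, c("KRAS", "TP53"))
  expect_equal(rep$and_chain$cumulative_count, c(3L, 2L))
  # gene OR-cover: KRAS (3), then BRAF and EGFR (ties resolved
  # lexicographically), TP53 adds nothing
  expect_equal(rep$gene_or_cover$key, c("KRAS", "BRAF", "EGFR"))
  expect_equal(rep$gene_or_cover$cumulative_count, c(3L, 4L, 5L))
  # recurrence at >= 2 tumors
  expect_equal(rep$recurrent$key, c("KRAS|G12C", "TP53|R175H"))
  expect_equal(rep$recurrent$n_tumors, c(3L, 2L))
  # variant OR-cover saturates after KRAS|G12C
  expect_equal(rep$variant_or_cover$key, "KRAS|G12C")
  expect_equal(rep$variant_or_cover$cumulative_fraction, 0.6)
  # producer bookkeeping is consistent with the calls table
  expect_equal(rep$producer_fractions$n_recurrent, c(2L, 2L))
  for (i in 1:2) {
    al <- strsplit(toy_freqs$subtype[i], "|", fixed = TRUE)[[1]]
    expect_equal(
      rep$producer_fractions$n_producers[i],
      length(unique(rep$calls$variant_key[rep$calls$allele %in% al]))
    )
  }
  # applicability rows multiply coverage by population frequency
  if (nrow(rep$applicability) > 0) {
    expect_equal(
      rep$applicability$population_pct,
      100 * rep$applicability$cohort_fraction *
        rep$applicability$population_frequency
    )
  }
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("repeated runs on identical inputs give identical reports", {
  r1 <- run_analysis(toy_alts, toy_freqs, proteins = toy_proteins,
                     hla = toy_hla, config = toy_config)
  r2 <- run_analysis(toy_alts, toy_freqs, proteins = toy_proteins,
                     hla = toy_hla, config = toy_config)
  for (part in c("uniqueness", "recurrent", "producer_fractions",
                 "applicability", "calls")) {
    expect_identical(r1[[part]], r2[[part]], info = part)
  }
  expect_identical(tibble::as_tibble(r1$and_chain),
                   tibble::as_tibble(r2$and_chain))
})

test_that("a cohort without coding changes yields a valid empty call section", {
  alts <- make_alterations(
    list("T1", "EGFR", "copy_number", ""),
    list("T2", "MYC", "copy_number", "")
  )
  hla <- tibble::tibble(sample_id = c("T1", "T2"),
                        hla_subtype = c("other", "other"))
  rep <- run_analysis(alts, toy_freqs, proteins = toy_proteins, hla = hla,
                      config = toy_config)
  expect_equal(nrow(rep$recurrent), 0)
  expect_equal(nrow(rep$calls), 0)
  expect_equal(nrow(rep$applicability), 0)
  expect_equal(rep$uniqueness$unique_fraction, rep(1, 3))
})

test_that("variants without a reference protein are skipped and counted", {
  no_kras <- toy_proteins[toy_proteins$gene != "KRAS", ]
  rep <- run_analysis(toy_alts, toy_freqs, proteins = no_kras,
                      hla = toy_hla, config = toy_config)
  expect_equal(rep$n_skipped, 1L)
  expect_false("KRAS|G12C" %in% rep$calls$variant_key)
})

test_that("reports serialize to JSON and TSV deterministically", {
  rep <- run_analysis(toy_alts, toy_freqs, proteins = toy_proteins,
                      hla = toy_hla, config = toy_config)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  j1 <- write_report(rep, d1)
  j2 <- write_report(rep, d2)
  expect_true(file.exists(file.path(d1, "and_chain.tsv")))
  expect_identical(readLines(j1), readLines(j2))
  parsed <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_equal(parsed$n_recurrent, 2)
})

test_that("run configurations validate and round-trip through YAML", {
  expect_error(run_config(min_tumors = 0), "min_tumors")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(min_tumors = 5, k = 3, seed = 11), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$min_tumors, 5)
  expect_equal(cfg$k, 3)
  expect_equal(cfg$seed, 11L)
  expect_equal(cfg$flank, 25)
})
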