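test_that("subtype coverage counts carriers with at least one selected key", {
  alts <- make_alterations(
    list("T1", "KRAS", "missense_snv", "G12C"),
    list("T2", "TP53", "missense_snv", "R175H"),
    list("T3", "KRAS", "missense_snv", "G12C")
  )
  hla <- tibble::tibble(sample_id = c("T1", "T2", "T3"),
                        hla_subtype = c("A|B", "A|B", "C|D"))
  expect_equal(
    subtype_cohort_coverage(alts, "KRAS|G12C", "A|B", hla = hla), 0.5
  )
  expect_equal(
    subtype_cohort_coverage(alts, c("KRAS|G12C", "TP53|R175H"), "A|B",
                            hla = hla), 1
  )
  expect_equal(
    subtype_cohort_coverage(alts, "BRAF|V600E", "A|B", hla = hla), 0
  )
  expect_error(
    subtype_cohort_coverage(alts, "KRAS|G12C", "E|F", hla = hla), "E\\|F"
  )
})

test_that("subtype coverage matches a brute-force recount on a cohort", {
  sim <- simulate_cohort(cohort_sim_params(n_tumors = 3000, seed = 33))
  keys <- c("KRAS|G12C", "BRAF|V600E", "TP53|R175H")
  pair <- "A*01:01|B*08:01"
  got <- subtype_cohort_coverage(sim, keys, pair)
  carriers <- sim$samples$sample_id[sim$samples$hla_subtype == pair]
  vk <- variant_key(sim$alterations$gene, sim$alterations$alt_class,
                    sim$alterations$protein_change)
  hit <- unique(sim$alterations$sample_id[vk %in% keys])
  expect_equal(got, mean(carriers %in% hit))
})

test_that("subtype coverage stays near overall coverage when HLA is independent", {
  sim <- simulate_cohort(cohort_sim_params(n_tumors = 20000, seed = 44))
  keys <- head(recurrent_alterations(sim, 10)$key, 10)
  vk_hits <- unique(keys_at_level(sim, "variant")$sample_id[
    keys_at_level(sim, "variant")$key %in% keys
  ])
  p_overall <- length(vk_hits) / nrow(sim$samples)
  for (pair in c("A*01:01|B*08:01", "A*02:01|B*44:02")) {
    n_sub <- sum(sim$samples$hla_subtype == pair)
    cov <- subtype_cohort_coverage(sim, keys, pair)
    expect_lte(cov, p_overall + 3 * sqrt(p_overall * (1 - p_overall) / n_sub))
  }
})

test_that("population applicability reproduces the printed products", {
  expect_equal(round(population_applicability(0.007, 0.126), 2), 0.09)
  expect_equal(round(population_applicability(0.013, 0.126), 1), 0.2)
  expect_equal(round(population_applicability(0.093, 0.108), 1), 1.0)
  expect_equal(population_applicability(0, 0.5), 0)
  expect_error(population_applicability(1.2, 0.5), "fractions")
  # monotone in both arguments
  expect_lt(population_applicability(0.007, 0.126),
            population_applicability(0.008, 0.126))
  expect_lt(population_applicability(0.007, 0.126),
            population_applicability(0.007, 0.2))
})

test_that("display rounding uses mixed precision", {
  expect_equal(format_pct(c(0.0882, 1.638, 24.9)),
               c("0.09%", "1.6%", "25%"))
})

test_that("Fisher's exact test matches the enumeration oracle exactly", {
  # reconstructed HLA-typing enrichment table: 8/40 observed carriers vs
  # round(40 * 0.104) = 4 expected
  expect_equal(round(fisher_exact_two_sided(8, 32, 4, 36), 2), 0.35)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  withr::with_seed(55, {
    for (i in 1:50) {
      cells <- as.integer(stats::rmultinom(1, sample(10:60, 1), rep(0.25, 4)))
      if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
      p <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
      expect_equal(p, fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                   tolerance = 1e-12)
      # invariant to simultaneous row and column swaps
      expect_equal(p, fisher_exact_two_sided(cells[4], cells[3],
                                             cells[2], cells[1]),
                   tolerance = 1e-12)
      expect_true(p > 0 && p <= 1)
    }
  })
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "zero")
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("expected carrier counts round to the nearest integer", {
  expect_equal(expected_count(40, 0.104), 4)
  expect_equal(expected_count(0, 0.9), 0)
  expect_equal(expected_count(100, 0.5), 50)
})

test_that("applicability tables combine coverage and population frequency", {
  alts <- make_alterations(
    list("T1", "KRAS", "missense_snv", "G12C"),
    list("T2", "TP53", "missense_snv", "R175H")
  )
  hla <- tibble::tibble(sample_id = c("T1", "T2"),
                        hla_subtype = c("A|B", "A|B"))
  freqs <- tibble::tibble(subtype = "A|B", frequency = 0.126)
  tab <- applicability_table(alts, list("A|B" = "KRAS|G12C"), freqs, hla = hla)
  expect_equal(tab$cohort_fraction, 0.5)
  expect_equal(tab$population_pct, 100 * 0.5 * 0.126)
  expect_error(
    applicability_table(alts, list("Z|Z" = "KRAS|G12C"), freqs, hla = hla),
    "Z\\|Z"
  )
})
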