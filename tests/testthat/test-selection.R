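test_that("forced AND-chain: a universal key then a half-shared key", {
  n <- 20
  alts <- membership_cohort(
    list(A = 1:20, B = 1:10),
    n_tumors = n
  )
  ch <- and_chain(alts, "gene", k = 2)
  expect_equal(ch$key, c("A", "B"))
  expect_equal(ch$cumulative_count, c(20L, 10L))
  expect_true(all(diff(ch$cumulative_count) <= 0))
})

test_that("AND-chain step 1 is the most frequent key and k=1 stops there", {
  alts <- make_alterations(
    list("T1", "KRAS", "missense_snv", "G12C"),
    list("T2", "KRAS", "missense_snv", "G12C"),
    list("T2", "TP53", "missense_snv", "R175H")
  )
  ch <- and_chain(alts, "variant", k = 1)
  expect_equal(ch$key, "KRAS|G12C")
  expect_equal(ch$cumulative_count, 2L)
})

test_that("AND-chain matches an independent stepwise brute force", {
  sim <- simulate_cohort(cohort_sim_params(n_tumors = 300, seed = 31))
  ch <- and_chain(sim, "gene", k = 3)
  # oracle: explicit per-tumor set scans with the documented tie-break
  keys <- keys_at_level(sim, "gene")
  sets <- split(keys$sample_id, keys$key)
  overall <- lengths(sets)
  alive <- sim$samples$sample_id
  expected <- character(0)
  for (step in 1:3) {
    cand <- setdiff(names(sets), expected)
    counts <- vapply(cand, function(k) length(intersect(alive, sets[[k]])),
                     integer(1))
    best <- cand[order(-counts, -overall[cand], cand)][1]
    if (counts[[best]] == 0) break
    expected <- c(expected, best)
    alive <- intersect(alive, sets[[best]])
    expect_equal(ch$cumulative_count[step], length(alive))
  }
  expect_equal(ch$key[seq_along(expected)], expected)
})

test_that("forced OR-cover: disjoint candidates picked largest-first", {
  alts <- membership_cohort(
    list(A = 1:5, B = 6:8, C = 9:10, U = 1:12),
    n_tumors = 12
  )
  oc <- or_cover(alts, c("A", "B", "C"), level = "gene", k = 2)
  expect_equal(oc$key, c("A", "B"))
  expect_equal(oc$cumulative_count, c(5L, 8L))
  # a single candidate covering everything saturates at step 1
  oc2 <- or_cover(alts, "U", level = "gene", k = 3)
  expect_equal(oc2$cumulative_count, 12L)
  expect_equal(nrow(oc2), 1)
})

test_that("OR-cover ties break by overall frequency then key order", {
  # D and E both add 2 new tumors at step 2, but E is overall more frequent
  alts <- membership_cohort(
    list(A = 1:6, D = c(1, 7, 8), E = c(1, 2, 7, 8)),
    n_tumors = 10
  )
  oc <- or_cover(alts, c("A", "D", "E"), level = "gene", k = 2)
  expect_equal(oc$key, c("A", "E"))
})

test_that("greedy OR-cover is submodular-consistent and near-optimal", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n <- 25
      cands <- setNames(
        lapply(1:8, function(i) sample(n, sample(2:10, 1))),
        paste0("K", 1:8)
      )
      alts <- membership_cohort(cands, n_tumors = n)
      oc <- or_cover(alts, names(cands), level = "gene", k = 4)
      expect_true(all(diff(oc$marginal_count) <= 0))
      expect_true(all(diff(oc$cumulative_count) >= 0))
      opt <- brute_force_or_cover(alts, names(cands), level = "gene", k = 4)
      expect_gte(max(oc$cumulative_count), (1 - exp(-1)) * opt)
      expect_lte(max(oc$cumulative_count), opt)
    }
  })
})

test_that("the brute-force oracle is exact on disjoint sets and guarded", {
  alts <- membership_cohort(list(A = 1:5, B = 6:8, C = 9:10), n_tumors = 10)
  expect_equal(brute_force_or_cover(alts, c("A", "B", "C"), "gene", k = 2), 8L)
  expect_equal(brute_force_or_cover(alts, "A", "gene", k = 5), 5L)
  expect_error(
    brute_force_or_cover(alts, sprintf("X%02d", 1:21), "gene", k = 2),
    "20"
  )
})

test_that("coverage selections expose tidy/glance and plot cleanly", {
  alts <- membership_cohort(list(A = 1:5, B = 3:8), n_tumors = 10)
  oc <- or_cover(alts, c("A", "B"), level = "gene", k = 2)
  td <- tidy(oc)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("rank", "key", "marginal_count", "cumulative_count",
                     "cumulative_fraction"))
  gl <- glance(oc)
  expect_equal(gl$final_count, 8L)
  expect_equal(gl$universe_size, 10L)
  expect_s3_class(autoplot(oc), "ggplot")
})
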