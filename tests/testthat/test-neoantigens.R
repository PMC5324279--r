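panel <- c("A*01:01", "B*08:01")
pred <- surrogate_predictor(panel, seed = 1, binder_quantile = 0.05)

as_window <- function(wt, mut, key = "G|X1Y") {
  structure(
    tibble::tibble(variant_key = key, wt_seq = wt, mut_seq = mut,
                   window_start = 1L),
    class = c("peptide_window", class(tibble::tibble()))
  )
}

test_that("an identical mutant window yields no neoantigen call", {
  w <- random_missense_window(3)
  same <- as_window(w$wt_seq, w$wt_seq)
  calls <- call_mhc1_neoantigens(same, panel, pred)
  expect_equal(nrow(calls), 0)
})

test_that("wild-type binders are never returned (subtraction soundness)", {
  for (seed in 1:25) {
    w <- random_missense_window(seed)
    calls <- call_mhc1_neoantigens(w, panel, pred)
    cand <- enumerate_candidates(w, 8:11)
    for (a in panel) {
      wt_binders <- predict_binding(pred, cand$wt, a)
      wt_binders <- wt_binders$peptide[wt_binders$is_binder]
      expect_length(intersect(calls$peptide[calls$allele == a], wt_binders), 0)
      # for pure missense windows every mutant-specific binder differs from
      # every WT k-mer, i.e. it spans the substituted residue
      expect_length(intersect(calls$peptide[calls$allele == a], cand$wt), 0)
    }
  }
})

test_that("MHC-I calls equal a brute-force filter over all scored k-mers", {
  w <- random_missense_window(99)
  calls <- call_mhc1_neoantigens(w, panel, pred)
  for (a in panel) {
    wt <- predict_binding(pred, substring_oracle(w$wt_seq, 8:11), a)
    mut <- predict_binding(pred, substring_oracle(w$mut_seq, 8:11), a)
    expected <- setdiff(mut$peptide[mut$is_binder], wt$peptide[wt$is_binder])
    expect_setequal(calls$peptide[calls$allele == a], expected)
  }
  expect_error(call_mhc1_neoantigens(w, "C*01:02", pred), "C\\*01:02")
})

test_that("MHC-II consensus requires both methods below threshold", {
  w <- random_missense_window(7, protein_length = 200)
  smm <- surrogate_mhc2_predictor("DRB1*01:01", seed = 2, method = "smm")
  nn <- surrogate_mhc2_predictor("DRB1*01:01", seed = 2, method = "nn")
  calls <- call_mhc2_neoantigens(w, "DRB1*01:01", smm, nn, 500)
  expect_true(all(calls$ic50_a_nm < 500 & calls$ic50_b_nm < 500))
  # brute-force dual-filter oracle
  cand <- enumerate_candidates(w, 15)
  dual <- function(peps) {
    peps[predict_ic50(smm, peps) < 500 & predict_ic50(nn, peps) < 500]
  }
  expect_setequal(calls$peptide, setdiff(dual(cand$mut), dual(cand$wt)))
  # a peptide passing one method only is not a binder
  one_sided <- cand$mut[predict_ic50(smm, cand$mut) < 500 &
                          predict_ic50(nn, cand$mut) >= 500]
  expect_length(intersect(calls$peptide, one_sided), 0)
  expect_error(call_mhc2_neoantigens(w, "DRB1*01:01", smm, nn, 100), "50 or 500")
})

test_that("high-affinity MHC-II binders are a subset of low-affinity ones", {
  smm <- surrogate_mhc2_predictor("DQB1*03:01", seed = 5, method = "smm")
  nn <- surrogate_mhc2_predictor("DQB1*03:01", seed = 5, method = "nn")
  for (seed in 1:20) {
    w <- random_missense_window(seed, protein_length = 150)
    lo <- call_mhc2_neoantigens(w, "DQB1*03:01", smm, nn, 500)
    hi <- call_mhc2_neoantigens(w, "DQB1*03:01", smm, nn, 50)
    expect_true(all(hi$peptide %in% lo$peptide))
  }
})

test_that("producer fractions reproduce the printed arithmetic", {
  keys <- paste0("G|V", 1:2833)
  calls62 <- tibble::tibble(variant_key = keys[1:62], allele = "A*01:01",
                            peptide = "X")
  calls348 <- tibble::tibble(variant_key = keys[1:348], allele = "A*02:01",
                             peptide = "X")
  expect_equal(round(neoantigen_producer_fraction(calls62, keys)), 2)
  expect_equal(round(neoantigen_producer_fraction(calls348, keys)), 12)
  none <- calls62[0, ]
  expect_equal(neoantigen_producer_fraction(none, keys), 0)
  expect_error(neoantigen_producer_fraction(calls62, character(0)),
               "non-empty")
  # allele restriction: only calls for the pair's alleles count
  expect_equal(
    neoantigen_producer_fraction(calls62, keys, alleles = "B*08:01"), 0
  )
})

test_that("allele-restriction histograms match a direct recount", {
  four <- c("A*01:01", "A*02:01", "B*08:01", "B*44:02")
  p4 <- surrogate_predictor(four, seed = 2, binder_quantile = 0.05)
  calls <- dplyr::bind_rows(lapply(1:10, function(s) {
    call_mhc1_neoantigens(random_missense_window(s + 100), four, p4)
  }))
  prof <- allele_restriction_profile(calls, four)
  expect_equal(prof$n_alleles, 1:4)
  counts <- table(tapply(calls$allele, calls$peptide,
                         function(a) length(unique(a))))
  for (b in 1:4) {
    expected <- if (as.character(b) %in% names(counts)) {
      unname(counts[[as.character(b)]])
    } else 0L
    expect_equal(prof$peptide_count[b], expected)
  }
  expect_equal(sum(prof$peptide_count), length(unique(calls$peptide)))
  # degenerate inputs
  empty <- allele_restriction_profile(calls[0, ], four)
  expect_equal(empty$peptide_count, rep(0L, 4))
  expect_error(allele_restriction_profile(calls, "A*01:01"), "at least 2")
  expect_s3_class(plot_allele_restriction(prof), "ggplot")
})
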