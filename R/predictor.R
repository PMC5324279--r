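# Pluggable MHC predictor contract. Real tools (IEDB processing+TAP+binding,
# NetMHCpan) plug in through the same interface; the package ships a
# deterministic position-weight-matrix surrogate so the pipeline is fully
# testable offline.

# score = mean over positions of M[residue, position]; vectorised per length
score_peptides_pwm <- function(peptides, M) {
  out <- numeric(length(peptides))
  lens <- nchar(peptides)
  for (L in unique(lens)) {
    sel <- lens == L
    idx <- matrix(
      match(unlist(strsplit(peptides[sel], "", fixed = TRUE)), AA_ALPHABET),
      ncol = L, byrow = TRUE
    )
    val <- matrix(M[cbind(as.vector(idx), rep(seq_len(L), each = sum(sel)))],
                  ncol = L)
    out[sel] <- rowMeans(val)
  }
  out
}

# deterministic 20 x 15 N(0,1) position-weight matrix from a string key
pwm_from_key <- function(...) {
  with_seed(hash_seed(...), {
    matrix(stats::rnorm(20 * 15), nrow = 20, ncol = 15,
           dimnames = list(AA_ALPHABET, NULL))
  })
}

#' Construct an MHC-I predictor from scoring and threshold functions
#'
#' The predictor contract: `score_fn(peptides, allele)` returns a tibble
#' with columns `processing_score`, `tap_score`, `binding_score`,
#' `total_score` (one row per peptide, deterministic for fixed inputs);
#' `threshold_fn(allele)` returns the allele-specific binder cutoff applied
#' to `total_score`. Adapters for external tools implement this same
#' contract.
#'
#' @param score_fn,threshold_fn Functions as described above.
#' @param alleles Character vector of alleles the predictor covers.
#' @param label Free-text description.
#' @return An object of class `mhc_predictor`.
#' @seealso [surrogate_predictor()], [predict_binding()]
#' @export
mhc_predictor <- function(score_fn, threshold_fn, alleles, label = "custom") {
  structure(
    list(score_fn = score_fn, threshold_fn = threshold_fn,
         alleles = alleles, label = label),
    class = "mhc_predictor"
  )
}

#' @export
print.mhc_predictor <- function(x, ...) {
  cat(sprintf("<mhc_predictor '%s': %d alleles>\n", x$label, length(x$alleles)))
  invisible(x)
}

#' Deterministic surrogate MHC-I predictor
#'
#' Stands in for an end-to-end processing + TAP + MHC-I binding tool. Each
#' allele gets three position-weight log-odds matrices (proteasomal
#' processing, TAP transport, MHC binding) derived deterministically from a
#' hash of the allele name and the seed; the combined score is a weighted
#' sum of the three stage scores. The allele-specific binder threshold is
#' set to a fixed quantile of combined scores on a shared random-peptide
#' calibration background, so binder rates are sparse (default 2%) and
#' plausibly allele-specific. Identical (allele, seed) always yields
#' identical scores and thresholds.
#'
#' @param alleles Character vector of HLA allele names (e.g. `"A*01:01"`).
#' @param seed Integer seed.
#' @param binder_quantile Upper-tail mass of the calibration background
#'   scored as binders (default 0.02).
#' @param lengths Peptide lengths used for the calibration background.
#' @param n_background Calibration peptides per length (default 1000).
#' @return An [mhc_predictor()].
#' @export
#' @examples
#' p <- surrogate_predictor(c("A*01:01", "B*08:01"), seed = 1)
#' predict_binding(p, c("SIINFEKLM", "GILGFVFTL"), "A*01:01")
surrogate_predictor <- function(alleles, seed = 1L, binder_quantile = 0.02,
                                lengths = 8:11, n_background = 1000) {
  if (length(alleles) == 0 || any(!nzchar(alleles))) {
    abort("`alleles` must be non-empty allele names")
  }
  stage_w <- c(processing = 0.25, tap = 0.15, binding = 0.60)
  pwms <- lapply(setNames(alleles, alleles), function(a) {
    list(
      processing = pwm_from_key("proc", a, seed),
      tap = pwm_from_key("tap", a, seed),
      binding = pwm_from_key("bind", a, seed)
    )
  })
  score_fn <- function(peptides, allele) {
    w <- pwms[[allele]]
    if (is.null(w)) abort(sprintf("unknown allele '%s'", allele))
    pr <- score_peptides_pwm(peptides, w$processing)
    ta <- score_peptides_pwm(peptides, w$tap)
    bi <- score_peptides_pwm(peptides, w$binding)
    tibble::tibble(
      processing_score = pr, tap_score = ta, binding_score = bi,
      total_score = stage_w[["processing"]] * pr + stage_w[["tap"]] * ta +
        stage_w[["binding"]] * bi
    )
  }
  background <- with_seed(hash_seed("calibration-background", seed), {
    unlist(lapply(lengths, function(L) random_aa(rep(L, n_background))))
  })
  thresholds <- vapply(alleles, function(a) {
    unname(quantile(score_fn(background, a)$total_score,
                    1 - binder_quantile, names = FALSE))
  }, numeric(1))
  mhc_predictor(
    score_fn = score_fn,
    threshold_fn = function(allele) {
      th <- thresholds[[allele]]
      if (is.null(th)) abort(sprintf("unknown allele '%s'", allele))
      th
    },
    alleles = alleles,
    label = sprintf("surrogate PWM (seed %d, q = %g)", seed, binder_quantile)
  )
}

#' Score peptides against one allele
#'
#' @param predictor An [mhc_predictor()].
#' @param peptides Character vector of peptides.
#' @param allele Allele name covered by the predictor.
#' @return Tibble with `peptide`, `allele`, the stage scores, `total_score`
#'   and `is_binder` (total score at or above the allele threshold).
#' @export
predict_binding <- function(predictor, peptides, allele) {
  if (!inherits(predictor, "mhc_predictor")) {
    abort("`predictor` must be an mhc_predictor")
  }
  if (!allele %in% predictor$alleles) {
    abort(sprintf("unknown allele '%s'", allele))
  }
  if (length(peptides) == 0) {
    return(tibble::tibble(
      peptide = character(), allele = character(),
      processing_score = numeric(), tap_score = numeric(),
      binding_score = numeric(), total_score = numeric(), is_binder = logical()
    ))
  }
  sc <- predictor$score_fn(peptides, allele)
  dplyr::bind_cols(
    tibble::tibble(peptide = peptides, allele = allele),
    sc,
    tibble::tibble(is_binder = sc$total_score >= predictor$threshold_fn(allele))
  )
}

#' Deterministic surrogate MHC-II IC50 predictor
#'
#' One component method of an MHC-II consensus predictor. A
#' position-weight score is mapped monotonically to an IC50 (nM): stronger
#' position-weight scores give lower IC50. Two instances with different
#' `method` labels emulate the SMM and NN components whose agreement the
#' consensus rule requires.
#'
#' @param allele MHC-II allele name (e.g. `"DRB1*01:01"`).
#' @param seed Integer seed.
#' @param method Method label, conventionally `"smm"` or `"nn"`.
#' @return Object of class `mhc2_predictor` with an `ic50_fn`.
#' @export
surrogate_mhc2_predictor <- function(allele, seed = 1L, method = "smm") {
  if (!nzchar(allele)) abort("`allele` must be non-empty")
  M <- pwm_from_key("mhc2", method, allele, seed)
  structure(
    list(
      allele = allele, method = method,
      ic50_fn = function(peptides) {
        z <- score_peptides_pwm(peptides, M) * sqrt(nchar(peptides))
        exp(8.5 - 2.5 * z)
      }
    ),
    class = "mhc2_predictor"
  )
}

#' Predict MHC-II IC50 values (nM)
#'
#' @param predictor An `mhc2_predictor`.
#' @param peptides Character vector of peptides (15-mers by convention).
#' @return Numeric vector of IC50 values in nM (lower = stronger binding).
#' @export
predict_ic50 <- function(predictor, peptides) {
  if (!inherits(predictor, "mhc2_predictor")) {
    abort("`predictor` must be an mhc2_predictor")
  }
  if (length(peptides) == 0) return(numeric(0))
  predictor$ic50_fn(peptides)
}
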