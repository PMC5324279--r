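# Greedy alteration-set selection over per-tumor key sets: cumulative "and"
# co-occurrence chains and additive "and/or" maximum coverage.

# key -> integer tumor indices, plus the tie-break ordering (higher overall
# frequency first, then lexicographic key order)
key_tumor_sets <- function(x, level, candidate_keys = NULL) {
  tb <- as_cohort_tbls(x)
  keys <- keys_at_level(x, level)
  keys$tumor <- match(keys$sample_id, tb$samples$sample_id)
  sets <- split(keys$tumor, keys$key)
  if (!is.null(candidate_keys)) {
    missing <- setdiff(candidate_keys, names(sets))
    sets <- c(sets[intersect(candidate_keys, names(sets))],
              setNames(rep(list(integer(0)), length(missing)), missing))
  }
  ord <- order(-lengths(sets), names(sets))
  list(sets = sets[ord], n_tumors = nrow(tb$samples))
}

new_coverage_selection <- function(df, mode, level, universe_size) {
  structure(
    df,
    mode = mode, level = level, universe_size = universe_size,
    class = c("coverage_selection", class(tibble::tibble()))
  )
}

#' Cumulative "and" co-occurrence chain
#'
#' Greedily orders alteration keys so that each prefix maximises the number
#' of tumors containing *all* selected keys: step 1 picks the most frequent
#' key, step i the key maximising the count of tumors that carry every
#' previously selected key and the new one. The chain stops early when no
#' remaining key co-occurs with the current prefix. Ties break to the key
#' with higher overall frequency, then lexicographically.
#'
#' @inheritParams keys_at_level
#' @param k Maximum chain length (default 10).
#'
#' @return A `coverage_selection` tibble with columns `rank`, `key`,
#'   `marginal_count`, `cumulative_count`, `cumulative_fraction`;
#'   `cumulative_count` (tumors containing the whole prefix) is
#'   non-increasing. For AND-chains `marginal_count` equals
#'   `cumulative_count` at each step.
#' @seealso [or_cover()]
#' @export
and_chain <- function(x, level = "gene", k = 10) {
  if (k < 1) abort("`k` must be >= 1")
  kt <- key_tumor_sets(x, level)
  if (kt$n_tumors == 0) abort("cohort is empty")
  sets <- kt$sets
  alive <- rep(TRUE, kt$n_tumors)
  chosen <- character(0)
  cum <- integer(0)
  for (step in seq_len(min(k, length(sets)))) {
    counts <- vapply(sets, function(s) sum(alive[s]), integer(1))
    best <- which.max(counts)   # sets are pre-ordered by the tie-break
    if (length(best) == 0 || counts[best] == 0) break
    chosen <- c(chosen, names(sets)[best])
    cum <- c(cum, counts[[best]])
    keep <- rep(FALSE, kt$n_tumors)
    keep[sets[[best]]] <- TRUE
    alive <- alive & keep
    sets <- sets[-best]
  }
  new_coverage_selection(
    tibble::tibble(
      rank = seq_along(chosen), key = chosen,
      marginal_count = cum, cumulative_count = cum,
      cumulative_fraction = cum / kt$n_tumors
    ),
    mode = "and_chain", level = level, universe_size = kt$n_tumors
  )
}

#' Additive "and/or" maximum-coverage selection
#'
#' Standard greedy maximum coverage: each step adds the candidate key that
#' covers the most not-yet-covered tumors, so the cumulative count of
#' tumors with *at least one* selected key is non-decreasing. Stops early
#' when no candidate adds coverage. Ties break to the key with higher
#' overall frequency, then lexicographically.
#'
#' @inheritParams keys_at_level
#' @param candidate_keys Character vector of candidate keys (e.g. the keys
#'   of [recurrent_alterations()], or all gene-level keys).
#' @param k Maximum set size (default 10).
#'
#' @return A `coverage_selection` tibble (see [and_chain()]);
#'   `marginal_count` is the number of newly covered tumors at each step.
#' @export
or_cover <- function(x, candidate_keys, level = "variant", k = 10) {
  if (k < 1) abort("`k` must be >= 1")
  if (length(candidate_keys) == 0) abort("`candidate_keys` must be non-empty")
  kt <- key_tumor_sets(x, level, candidate_keys = unique(candidate_keys))
  sets <- kt$sets
  covered <- rep(FALSE, kt$n_tumors)
  chosen <- character(0)
  marg <- integer(0)
  for (step in seq_len(min(k, length(sets)))) {
    gains <- vapply(sets, function(s) sum(!covered[s]), integer(1))
    best <- which.max(gains)
    if (length(best) == 0 || gains[best] == 0) break
    chosen <- c(chosen, names(sets)[best])
    marg <- c(marg, gains[[best]])
    covered[sets[[best]]] <- TRUE
    sets <- sets[-best]
  }
  cum <- cumsum(marg)
  new_coverage_selection(
    tibble::tibble(
      rank = seq_along(chosen), key = chosen,
      marginal_count = marg, cumulative_count = cum,
      cumulative_fraction = cum / kt$n_tumors
    ),
    mode = "or_cover", level = level, universe_size = kt$n_tumors
  )
}

#' Exact maximum coverage by exhaustive subset search
#'
#' Test oracle for [or_cover()]: enumerates every candidate subset of size
#' at most `k` and returns the largest number of tumors covered. Guarded to
#' at most 20 candidates.
#'
#' @inheritParams or_cover
#' @return The optimal coverage count (a single integer).
#' @export
brute_force_or_cover <- function(x, candidate_keys, level = "variant", k = 10) {
  candidate_keys <- unique(candidate_keys)
  if (length(candidate_keys) > 20) {
    abort("brute force is guarded to <= 20 candidates")
  }
  kt <- key_tumor_sets(x, level, candidate_keys = candidate_keys)
  sets <- kt$sets
  best <- 0L
  idx <- seq_along(sets)
  for (size in seq_len(min(k, length(sets)))) {
    combos <- utils::combn(idx, size, simplify = FALSE)
    for (cc in combos) {
      cov <- length(unique(unlist(sets[cc], use.names = FALSE)))
      if (cov > best) best <- cov
    }
  }
  best
}

#' @export
print.coverage_selection <- function(x, ...) {
  cat(sprintf("<coverage_selection: %s, %s level, universe %d>\n",
              attr(x, "mode"), attr(x, "level"), attr(x, "universe_size")))
  NextMethod()
}

#' @importFrom generics tidy
#' @method tidy coverage_selection
#' @export
tidy.coverage_selection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom generics glance
#' @method glance coverage_selection
#' @export
glance.coverage_selection <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    level = attr(x, "level"),
    n_selected = nrow(x),
    universe_size = attr(x, "universe_size"),
    final_count = if (nrow(x)) x$cumulative_count[nrow(x)] else 0L,
    final_fraction = if (nrow(x)) x$cumulative_fraction[nrow(x)] else 0
  )
}

#' Plot a coverage selection
#'
#' Bar chart of cumulative tumor coverage (or co-occurrence, for AND
#' chains) along the greedy selection order.
#'
#' @param object A `coverage_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_selection
#' @export
autoplot.coverage_selection <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ylab <- if (attr(object, "mode") == "and_chain") {
    "tumors with all selected alterations"
  } else {
    "tumors with ≥ 1 selected alteration"
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$key, .data$rank),
    y = .data$cumulative_fraction
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
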