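# Random equidistant slice sampling.
#
# A stack is m slices j + k*(x-1), x = 1..m (1-based slice indices), with the
# spacing k drawn uniformly from the admissible part of k_range and the start
# j drawn uniformly from {1, ..., t - m*k}. The start range deliberately
# leaves the top k slices of a volume unreachable (max index t - k); the
# coverage analysis below quantifies the resulting under-sampling of
# superior slices.

admissible_k <- function(t, m, k_range) {
  k_range <- sort(unique(as.integer(k_range)))
  assert_that(all(k_range >= 1), "spacings must be >= 1")
  k_range[t - m * k_range >= 1]
}

#' Sample one random equidistant slice stack
#'
#' Draws a spacing `k` uniformly from the admissible subset of `k_range`
#' (`k` admissible iff `t - m*k >= 1`), then a start slice `j` uniformly
#' from `1..(t - m*k)`, and returns the `m` slice indices
#' `j + k*(x - 1)`, `x = 1..m`. Consumes the global RNG stream.
#'
#' @param t total slice count of the volume.
#' @param m slices per stack (default 8).
#' @param k_range candidate spacings in slices (default `1:4`).
#' @return list with `m`, `k`, `j` and `indices` (strictly increasing,
#'   1-based, all within `1..t`).
#' @examples
#' set.seed(1)
#' sample_stack(t = 40)$indices
#' @export
sample_stack <- function(t, m = 8L, k_range = 1:4) {
  assert_that(is_count(t) && is_count(m, 2), "t and m must be positive counts")
  ks <- admissible_k(t, m, k_range)
  if (length(ks) == 0L)
    stop_bpr("volume with t = %d slices admits no spacing in {%s} for m = %d (need t >= %d)",
             t, paste(k_range, collapse = ","), m, m * min(k_range) + 1,
             class = "bpr_sampling_error")
  k <- if (length(ks) == 1L) ks else ks[sample.int(length(ks), 1L)]
  j <- sample.int(t - m * k, 1L)
  list(m = as.integer(m), k = as.integer(k), j = as.integer(j),
       indices = as.integer(j + k * (seq_len(m) - 1L)))
}

#' Per-slice selection probability of the equidistant sampler
#'
#' Computes, for every slice position `1..t`, the expected number of times
#' the slice is selected by one stack draw (the array sums to `m`). The
#' `exact` mode enumerates all `(k, j)` pairs with `k` uniform over the
#' admissible spacings and `j` uniform given `k`; the `monte_carlo` mode
#' estimates the same distribution from repeated [sample_stack()] draws.
#'
#' The summary reports the superior-coverage deficit
#' `100 * (1 - mean count over the top ceiling(0.1 t) slices / mean count
#' over all slices)`, i.e. by how many percent the most superior decile of
#' slice positions is under-sampled relative to the average slice.
#'
#' @param t slice count.
#' @param m slices per stack (default 8).
#' @param k_range candidate spacings (default `1:4`).
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param n_draws Monte-Carlo draws (default `1e5`).
#' @param seed optional seed for the Monte-Carlo mode.
#' @return list with `counts` (length `t`, expected selections per draw)
#'   and `top_decile_deficit_pct`.
#' @details `counts[s]` is the expected number of selections of slice `s`
#'   in one draw; because a slice can appear at most once per stack it also
#'   equals the probability that slice `s` is part of a random stack.
#' @examples
#' d <- selection_distribution(40)
#' sum(d$counts)  # = m
#' @export
selection_distribution <- function(t, m = 8L, k_range = 1:4,
                                   mode = c("exact", "monte_carlo"),
                                   n_draws = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  assert_that(is_count(t) && is_count(m, 2), "t and m must be positive counts")
  ks <- admissible_k(t, m, k_range)
  if (length(ks) == 0L)
    stop_bpr("no admissible spacing for t = %d", t, class = "bpr_sampling_error")
  counts <- numeric(t)
  if (mode == "exact") {
    for (k in ks) {
      nj <- t - m * k
      w <- 1 / (length(ks) * nj)
      for (x in seq_len(m)) {
        idx <- seq_len(nj) + k * (x - 1L)
        counts[idx] <- counts[idx] + w
      }
    }
  } else {
    assert_that(is_count(n_draws), "n_draws must be >= 1")
    counts <- with_seed(seed, {
      acc <- numeric(t)
      for (i in seq_len(n_draws)) {
        s <- sample_stack(t, m, k_range)
        acc[s$indices] <- acc[s$indices] + 1
      }
      acc / n_draws
    })
  }
  top <- ceiling(0.1 * t)
  deficit <- 100 * (1 - mean(counts[(t - top + 1L):t]) / mean(counts))
  structure(list(t = as.integer(t), m = as.integer(m), k_range = ks, mode = mode,
                 counts = counts, top_decile_deficit_pct = deficit),
            class = "bpr_selection_distribution")
}

#' @export
print.bpr_selection_distribution <- function(x, ...) {
  cat(sprintf("Slice-selection distribution (%s): t = %d, m = %d, k in {%s}\n",
              x$mode, x$t, x$m, paste(x$k_range, collapse = ",")))
  cat(sprintf("  expected selections/draw: min %.4f, max %.4f (sum %.3f)\n",
              min(x$counts), max(x$counts), sum(x$counts)))
  cat(sprintf("  top-decile coverage deficit: %.1f%%\n", x$top_decile_deficit_pct))
  invisible(x)
}
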