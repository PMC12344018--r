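# Score post-processing and landmark calibration. The pipeline for a raw
# per-slice score curve is: Gaussian smoothing along the slice axis, then
# an affine normalization that anchors the cohort-mean score at the lowest
# landmark (femoral head start) to 0 and at the highest landmark
# (esophagus end) to 100. Both steps are linear, so their order does not
# matter beyond floating point; the implemented order is fixed to
# smooth-then-normalize.

#' Post-processing configuration
#'
#' @param gaussian_sd standard deviation of the Gaussian smoothing kernel,
#'   in slices (default 10).
#' @param boundary_mode boundary handling for the convolution; only
#'   `"reflect"` is provided.
#' @return an object of class `bpr_postprocess_config`.
#' @export
postprocess_config <- function(gaussian_sd = 10, boundary_mode = "reflect") {
  assert_that(gaussian_sd > 0, "gaussian_sd must be > 0")
  assert_that(identical(boundary_mode, "reflect"), "only reflect boundaries supported")
  structure(list(gaussian_sd = gaussian_sd, boundary_mode = boundary_mode),
            class = "bpr_postprocess_config")
}

# reflect an out-of-range 1-based index back into 1..n ("reflect" padding:
# ... 3 2 1 | 1 2 3 ... n | n n-1 ...)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Gaussian-smooth a score curve
#'
#' 1-D Gaussian convolution along the slice axis with reflecting
#' boundaries; the kernel is truncated at 4 standard deviations and
#' renormalized, so constants are preserved exactly.
#'
#' @param curve numeric vector of per-slice scores.
#' @param config a [postprocess_config()].
#' @return smoothed numeric vector of the same length.
#' @export
smooth_curve <- function(curve, config = postprocess_config()) {
  assert_that(is.numeric(curve) && length(curve) >= 1, "curve must be numeric")
  sd <- config$gaussian_sd
  radius <- max(1L, as.integer(ceiling(4 * sd)))
  kern <- stats::dnorm(-radius:radius, sd = sd)
  kern <- kern / sum(kern)
  n <- length(curve)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- reflect_index((i - radius):(i + radius), n)
    out[i] <- sum(curve[idx] * kern)
  }
  out
}

#' Fit the landmark-anchored normalization
#'
#' `MinValue` is the mean, over the training volumes, of the smoothed
#' score at the lowest landmark (femoral head start by default);
#' `MaxValue` likewise at the highest landmark (esophagus end). Volumes
#' missing an anchor landmark are skipped for that anchor.
#'
#' @param curves list of smoothed score curves (one per training volume).
#' @param landmark_sets list of named landmark vectors aligned with
#'   `curves`.
#' @param low_landmark,high_landmark anchor landmark names.
#' @return an object of class `bpr_normalization` with fields `MinValue`
#'   and `MaxValue` (`MaxValue > MinValue` enforced).
#' @export
fit_normalization <- function(curves, landmark_sets,
                              low_landmark = "femoral_head_start",
                              high_landmark = "esophagus_end") {
  assert_that(length(curves) == length(landmark_sets) && length(curves) >= 1,
              "need matched, non-empty curves and landmark sets")
  at_landmark <- function(name) {
    vals <- mapply(function(cv, lm) {
      if (!name %in% names(lm)) return(NA_real_)
      cv[lm[[name]]]
    }, curves, landmark_sets)
    vals[!is.na(vals)]
  }
  lo <- at_landmark(low_landmark)
  hi <- at_landmark(high_landmark)
  assert_that(length(lo) >= 1, "landmark %s present in no training volume", low_landmark,
              class = "bpr_calibration_error")
  assert_that(length(hi) >= 1, "landmark %s present in no training volume", high_landmark,
              class = "bpr_calibration_error")
  mn <- mean(lo); mx <- mean(hi)
  if (mx <= mn)
    stop_bpr("calibration failed: mean score at %s (%.4g) not above %s (%.4g); model not ordered",
             high_landmark, mx, low_landmark, mn, class = "bpr_calibration_error")
  structure(list(MinValue = mn, MaxValue = mx,
                 low_landmark = low_landmark, high_landmark = high_landmark),
            class = "bpr_normalization")
}

#' Normalize a score curve to the 0--100 landmark scale
#'
#' Applies `score_new = (score_old - MinValue) * 100 / (MaxValue -
#' MinValue)`: the mean lowest-landmark score maps to 0, the mean
#' highest-landmark score to 100. Values outside the anchors are not
#' clipped.
#'
#' @param curve numeric vector (typically smoothed).
#' @param params a `bpr_normalization` from [fit_normalization()].
#' @return normalized numeric vector.
#' @export
normalize_curve <- function(curve, params) {
  assert_that(inherits(params, "bpr_normalization"), "params must be a bpr_normalization")
  (curve - params$MinValue) * 100 / (params$MaxValue - params$MinValue)
}

#' Fit the organ-landmark calibration table
#'
#' Smooths each training curve, fits the 0--100 normalization on the
#' anchor landmarks, and records for every landmark the mean and SD
#' (across training volumes) of the normalized smoothed score at the true
#' landmark slice. These reference scores are what predicts landmark
#' slices on unseen volumes.
#'
#' @param curves list of raw score curves (one per training volume).
#' @param landmark_sets list of named landmark slice vectors.
#' @param config a [postprocess_config()].
#' @param low_landmark,high_landmark normalization anchors.
#' @return an object of class `bpr_landmark_table`: a data.frame with
#'   columns `landmark`, `mean`, `sd`, `n`, and attributes
#'   `normalization` and `config`. Landmarks absent from every volume are
#'   omitted with a warning.
#' @export
fit_landmark_table <- function(curves, landmark_sets,
                               config = postprocess_config(),
                               low_landmark = "femoral_head_start",
                               high_landmark = "esophagus_end") {
  assert_that(length(curves) == length(landmark_sets) && length(curves) >= 1,
              "need matched, non-empty curves and landmark sets")
  smoothed <- lapply(curves, smooth_curve, config = config)
  params <- fit_normalization(smoothed, landmark_sets, low_landmark, high_landmark)
  normalized <- lapply(smoothed, normalize_curve, params = params)
  all_landmarks <- unique(unlist(lapply(landmark_sets, names)))
  rows <- lapply(all_landmarks, function(name) {
    vals <- unlist(mapply(function(cv, lm) {
      if (!name %in% names(lm) || is.na(lm[[name]])) return(NULL)
      cv[lm[[name]]]
    }, normalized, landmark_sets, SIMPLIFY = FALSE))
    if (length(vals) == 0) return(NULL)
    data.frame(landmark = name, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals), stringsAsFactors = FALSE)
  })
  dropped <- all_landmarks[vapply(rows, is.null, TRUE)]
  if (length(dropped) > 0)
    warning("landmark(s) absent from all volumes, omitted: ",
            paste(dropped, collapse = ", "))
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(tab, normalization = params, config = config,
            class = c("bpr_landmark_table", "data.frame"))
}

#' @export
print.bpr_landmark_table <- function(x, ...) {
  p <- attr(x, "normalization")
  cat(sprintf("Landmark calibration table: %d landmarks (anchors %s -> 0, %s -> 100)\n",
              nrow(x), p$low_landmark, p$high_landmark))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Post-process a raw score curve with a fitted table's parameters
#'
#' Convenience wrapper: smooth with the table's config, then normalize
#' with its embedded normalization.
#'
#' @param curve raw score curve.
#' @param table a `bpr_landmark_table`.
#' @return normalized smoothed curve.
#' @export
postprocess_curve <- function(curve, table) {
  assert_that(inherits(table, "bpr_landmark_table"), "table must be a bpr_landmark_table")
  normalize_curve(smooth_curve(curve, attr(table, "config")),
                  attr(table, "normalization"))
}

#' Predict the slice of a landmark from its reference score
#'
#' Returns the slice whose normalized smoothed score is nearest to the
#' reference score; ties break toward the lower (more inferior) slice
#' index. A reference above the curve's range returns the first maximal
#' slice, below the range the first minimal slice.
#'
#' @param curve normalized smoothed score curve.
#' @param reference reference score (e.g. a calibration-table mean).
#' @return 1-based slice index.
#' @export
predict_landmark_slice <- function(curve, reference) {
  assert_that(length(curve) >= 1, "curve must be non-empty")
  which.min(abs(curve - reference))
}

#' Predict all landmarks of a calibration table on one curve
#'
#' @param curve raw score curve of the target volume.
#' @param table a `bpr_landmark_table`.
#' @return named integer vector of predicted landmark slices.
#' @export
predict_landmarks <- function(curve, table) {
  post <- postprocess_curve(curve, table)
  stats::setNames(vapply(table$mean, function(r) predict_landmark_slice(post, r), 0L),
                  table$landmark)
}

#' Rescaled mean absolute landmark error
#'
#' Each volume's slice indices are rescaled so the largest (1-based) index
#' maps to 100; the per-landmark error is `|predicted - true| * 100 / t`,
#' interpretable as percent of the scan length. Errors are aggregated into
#' a per-landmark MAE and two overall summaries: `overall_mae` pools every
#' prediction, `overall_mae_by_landmark` averages the per-landmark MAEs.
#'
#' @param predictions list (one per volume) of named predicted-slice
#'   vectors.
#' @param truths list of named true-slice vectors; only landmarks present
#'   in both are scored.
#' @param t integer vector of per-volume slice counts.
#' @return an object of class `bpr_eval_result`: list with `errors` (long
#'   data.frame), `per_landmark` (data.frame of MAEs), `overall_mae`,
#'   `overall_mae_by_landmark`.
#' @export
evaluate_mae <- function(predictions, truths, t) {
  assert_that(length(predictions) == length(truths) &&
                length(predictions) == length(t),
              "predictions, truths and t must be aligned")
  assert_that(all(t >= 1), "every volume needs t >= 1")
  rows <- list()
  for (i in seq_along(predictions)) {
    shared <- intersect(names(predictions[[i]]), names(truths[[i]]))
    if (length(shared) == 0) next
    rows[[i]] <- data.frame(
      volume = i, landmark = shared,
      predicted = as.integer(predictions[[i]][shared]),
      true = as.integer(truths[[i]][shared]),
      error = abs(predictions[[i]][shared] - truths[[i]][shared]) * 100 / t[i],
      stringsAsFactors = FALSE)
  }
  errors <- do.call(rbind, rows)
  assert_that(!is.null(errors) && nrow(errors) > 0, "no matched prediction/truth pairs")
  per_landmark <- stats::aggregate(error ~ landmark, errors, mean)
  names(per_landmark)[2] <- "mae"
  structure(list(errors = errors, per_landmark = per_landmark,
                 overall_mae = mean(errors$error),
                 overall_mae_by_landmark = mean(per_landmark$mae)),
            class = "bpr_eval_result")
}

#' @export
print.bpr_eval_result <- function(x, ...) {
  cat(sprintf("Landmark evaluation: %d predictions over %d landmarks\n",
              nrow(x$errors), nrow(x$per_landmark)))
  cat(sprintf("  overall MAE (pooled): %.2f   (per-landmark average: %.2f)\n",
              x$overall_mae, x$overall_mae_by_landmark))
  invisible(x)
}

#' Pairwise Wilcoxon comparison of model errors with Bonferroni correction
#'
#' Performs a two-sided paired Wilcoxon signed-rank test for every pair of
#' models and flags significance at `alpha / n_comparisons`. Zero paired
#' differences are dropped (signed-rank convention); the exact null
#' distribution is used for up to 25 non-zero pairs, the normal
#' approximation with continuity correction above. If all paired
#' differences of a comparison are zero, its p-value is reported as 1 with
#' a degenerate-data warning.
#'
#' @param errors named list of numeric error vectors, one per model, all
#'   the same length and paired (same cases in the same order).
#' @param alpha family-wise error rate (default 0.05).
#' @param n_comparisons size of the test family; defaults to
#'   `choose(n_models, 2)` but may be set for other families (e.g. 20
#'   per-organ tests).
#' @return list with `comparisons` (data.frame of `model_a`, `model_b`,
#'   `p_value`, `significant`), `threshold`, `n_comparisons`.
#' @export
compare_models <- function(errors, alpha = 0.05, n_comparisons = NULL) {
  assert_that(is.list(errors) && length(errors) >= 2 && !is.null(names(errors)),
              "errors must be a named list of at least two models")
  len <- unique(vapply(errors, length, 0L))
  assert_that(length(len) == 1, "all error vectors must be paired (equal length)")
  models <- names(errors)
  pairs <- utils::combn(models, 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  threshold <- alpha / n_comparisons
  res <- apply(pairs, 2, function(pr) {
    x <- errors[[pr[1]]]; y <- errors[[pr[2]]]
    d <- x - y
    nz <- d[d != 0]
    if (length(nz) == 0) {
      warning(sprintf("all paired differences are zero for %s vs %s", pr[1], pr[2]))
      p <- 1
    } else {
      p <- suppressWarnings(stats::wilcox.test(
        x, y, paired = TRUE, exact = length(nz) <= 25, correct = TRUE))$p.value
    }
    c(p = p)
  })
  comparisons <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                            p_value = as.numeric(res),
                            significant = as.numeric(res) < threshold,
                            stringsAsFactors = FALSE)
  list(comparisons = comparisons, threshold = threshold,
       n_comparisons = n_comparisons, alpha = alpha)
}
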