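# Post-processing, calibration, prediction, MAE, model comparison.

test_that("Gaussian smoothing preserves constants and localizes impulses", {
  cfg <- postprocess_config(gaussian_sd = 10)
  expect_equal(smooth_curve(rep(4.2, 300), cfg), rep(4.2, 300), tolerance = 1e-12)
  # interior unit impulse: symmetric bell peaking at the impulse
  t <- 301
  x <- numeric(t); x[151] <- 1
  sm <- smooth_curve(x, cfg)
  expect_equal(which.max(sm), 151)
  expect_equal(sm[151 - 20], sm[151 + 20], tolerance = 1e-12)
  # direct convolution oracle at the impulse (kernel truncated at 4 sd)
  kern <- stats::dnorm(-40:40, sd = 10); kern <- kern / sum(kern)
  expect_equal(sm[111:191], rev(kern), tolerance = 1e-12)
  # near-zero sd approaches the identity
  tiny <- postprocess_config(gaussian_sd = 1e-4)
  y <- stats::runif(50)
  expect_equal(smooth_curve(y, tiny), y, tolerance = 1e-9)
})

test_that("smoothing and normalization commute (both linear)", {
  set.seed(1)
  raw <- cumsum(stats::runif(200))
  params <- structure(list(MinValue = 5, MaxValue = 80,
                           low_landmark = "a", high_landmark = "b"),
                      class = "bpr_normalization")
  cfg <- postprocess_config()
  a <- normalize_curve(smooth_curve(raw, cfg), params)
  b <- smooth_curve(normalize_curve(raw, params), cfg)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("normalization anchors map to 0, 100 and the midpoint to 50", {
  params <- fit_normalization(list(c(2, 5, 12)), list(c(femoral_head_start = 1L,
                                                        esophagus_end = 3L)))
  expect_equal(params$MinValue, 2)
  expect_equal(params$MaxValue, 12)
  expect_equal(normalize_curve(2, params), 0)
  expect_equal(normalize_curve(12, params), 100)
  expect_equal(normalize_curve(7, params), 50)
  # below the anchor stays negative (no clipping)
  expect_lt(normalize_curve(1, params), 0)
})

test_that("normalization anchors average across training volumes", {
  curves <- list(c(2, 6, 12), c(4, 6, 14))
  lms <- list(c(femoral_head_start = 1L, esophagus_end = 3L),
              c(femoral_head_start = 1L, esophagus_end = 3L))
  params <- fit_normalization(curves, lms)
  expect_equal(params$MinValue, 3)
  expect_equal(params$MaxValue, 13)
  # a decreasing-score model cannot be calibrated
  expect_error(fit_normalization(list(c(12, 6, 2)),
                                 list(c(femoral_head_start = 1L, esophagus_end = 3L))),
               class = "bpr_calibration_error")
})

test_that("a single-volume landmark table has zero SDs and exact anchors", {
  t <- 200
  curve <- linear_curve(t, 0, 20)
  lm <- c(femoral_head_start = 5L, liver_start = 90L, esophagus_end = 190L)
  tab <- fit_landmark_table(list(curve), list(lm))
  expect_true(all(tab$sd == 0))
  expect_true(all(tab$n == 1))
  # by construction of the normalization on the same data
  expect_equal(tab$mean[tab$landmark == "femoral_head_start"], 0, tolerance = 1e-9)
  expect_equal(tab$mean[tab$landmark == "esophagus_end"], 100, tolerance = 1e-9)
})

test_that("landmark means increase in anatomical order on phantom truth", {
  # ideal monotone score curves: table means must follow template order.
  # Jitter is kept small relative to the smallest template gap (0.005 of
  # scan length), since the ordering of cohort-mean landmark scores is
  # only guaranteed when inter-subject jitter does not swamp the gaps.
  spec <- small_phantom_spec(positional_sd = 0.003)
  subjects <- lapply(1:8, function(i) generate_phantom(spec, i))
  curves <- lapply(subjects, function(s) linear_curve(n_slices(s$volume), 0, 10))
  lms <- lapply(subjects, `[[`, "landmarks")
  tab <- fit_landmark_table(curves, lms)
  tpl <- default_organ_template()
  fr <- c(stats::setNames(tpl$z_start, paste0(tpl$organ, "_start")),
          stats::setNames(tpl$z_end, paste0(tpl$organ, "_end")))
  template_order <- names(sort(fr))
  means <- tab$mean[match(template_order, tab$landmark)]
  expect_false(is.unsorted(means))
})

test_that("landmarks missing everywhere are omitted with a warning", {
  curves <- list(linear_curve(50))
  lms <- list(c(femoral_head_start = 2L, esophagus_end = 48L))
  expect_silent(tab <- fit_landmark_table(curves, lms))
  lms2 <- list(c(femoral_head_start = 2L, esophagus_end = 48L, lung_start = NA))
  expect_warning(tab <- fit_landmark_table(curves, lms2), "lung_start")
  expect_equal(nrow(tab), 2)
  expect_false("lung_start" %in% tab$landmark)
})

test_that("predicted landmark slice is the nearest-score slice", {
  curve <- c(0, 10, 20, 30, 40)
  expect_equal(predict_landmark_slice(curve, 22), 3L)   # nearest is 20
  expect_equal(predict_landmark_slice(curve, 25), 3L)   # tie -> lower index
  expect_equal(predict_landmark_slice(curve, 999), 5L)  # above max -> last max
  expect_equal(predict_landmark_slice(curve, -5), 1L)
  # inverse-interpolation neighbour property on a monotone curve
  set.seed(2)
  mono <- sort(stats::rnorm(100))
  for (ref in stats::runif(20, min(mono), max(mono))) {
    p <- predict_landmark_slice(mono, ref)
    expect_true(all(abs(mono[p] - ref) <= abs(mono - ref) + 1e-12))
  }
})

test_that("rescaled MAE follows |pred - true| * 100 / t", {
  preds <- list(c(a_start = 100L, b_end = 50L), c(a_start = 10L, b_end = 20L))
  truth <- list(c(a_start = 110L, b_end = 50L), c(a_start = 10L, b_end = 25L))
  ev <- evaluate_mae(preds, truth, t = c(200L, 100L))
  expect_equal(sort(ev$errors$error), sort(c(5, 0, 0, 5)))
  expect_equal(ev$overall_mae, 2.5)
  # perfect predictions give MAE 0
  ev0 <- evaluate_mae(truth, truth, t = c(200L, 100L))
  expect_equal(ev0$overall_mae, 0)
  # pooled aggregation equals the brute-force mean of all pair errors
  set.seed(3)
  n <- 7
  preds <- lapply(1:n, function(i) stats::setNames(sample(1:150, 5), letters[1:5]))
  truth <- lapply(1:n, function(i) stats::setNames(sample(1:150, 5), letters[1:5]))
  tt <- sample(150:300, n)
  ev <- evaluate_mae(preds, truth, tt)
  brute <- unlist(lapply(1:n, function(i)
    abs(preds[[i]] - truth[[i]]) * 100 / tt[i]))
  expect_equal(ev$overall_mae, mean(brute), tolerance = 1e-12)
})

test_that("Bonferroni thresholds follow the comparison count", {
  set.seed(4)
  errs5 <- lapply(1:5, function(i) stats::runif(30, 0, 10))
  names(errs5) <- paste0("m", 1:5)
  res <- compare_models(errs5, alpha = 0.05)
  expect_equal(res$n_comparisons, 10)
  expect_equal(res$threshold, 0.005)
  expect_equal(nrow(res$comparisons), 10)
  # explicit family size, e.g. 20 per-organ tests
  res20 <- compare_models(errs5[1:2], alpha = 0.05, n_comparisons = 20)
  expect_equal(res20$threshold, 0.0025)
})

test_that("identical error vectors are degenerate, not significant", {
  e <- stats::runif(12)
  expect_warning(res <- compare_models(list(a = e, b = e)), "zero")
  expect_equal(res$comparisons$p_value, 1)
  expect_false(res$comparisons$significant)
})

test_that("a clearly better model is flagged after correction", {
  set.seed(5)
  base <- stats::runif(40, 4, 8)
  better <- base - stats::runif(40, 1, 3)
  res <- compare_models(list(good = better, bad = base), alpha = 0.05)
  expect_lt(res$comparisons$p_value, 0.05 / 1)
  expect_true(res$comparisons$significant)
})
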