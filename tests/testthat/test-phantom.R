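# Phantom generator: determinism, landmark truth, cohort splits,
# ordering and informativeness properties.

test_that("the same spec and seed give a bit-identical subject", {
  spec <- small_phantom_spec()
  a <- generate_phantom(spec, 12)
  b <- generate_phantom(spec, 12)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$landmarks, b$landmarks)
  c2 <- generate_phantom(spec, 13)
  expect_false(identical(a$landmarks, c2$landmarks))
})

test_that("zero positional jitter reproduces the template fractions exactly", {
  t <- 150
  spec <- phantom_spec(slice_count_range = c(t, t), in_plane_size = c(32, 32),
                       positional_sd = 0, noise_sd = 0)
  ph <- generate_phantom(spec, 5)
  tpl <- default_organ_template()
  expect_equal(unname(ph$landmarks[paste0(tpl$organ, "_start")]),
               1 + round(tpl$z_start * (t - 1)))
  expect_equal(unname(ph$landmarks[paste0(tpl$organ, "_end")]),
               1 + round(tpl$z_end * (t - 1)))
})

test_that("landmark truth equals first/last labeled slice and stays in range", {
  spec <- small_phantom_spec()
  for (seed in 1:5) {
    ph <- generate_phantom(spec, seed)
    t <- n_slices(ph$volume)
    ids <- ph$labels$organ_ids
    for (organ in names(ids)) {
      present <- which(apply(ph$labels$labels == ids[[organ]], 1, any))
      expect_equal(unname(ph$landmarks[[paste0(organ, "_start")]]), min(present))
      expect_equal(unname(ph$landmarks[[paste0(organ, "_end")]]), max(present))
    }
    expect_true(all(ph$landmarks >= 1 & ph$landmarks <= t))
    starts <- ph$landmarks[grep("_start$", names(ph$landmarks))]
    ends <- ph$landmarks[sub("_start$", "_end", names(starts))]
    expect_true(all(starts <= ends))
  }
})

test_that("cohort split sizes follow largest-remainder rounding", {
  spec <- small_phantom_spec()
  co <- generate_cohort(spec, 10, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(co$split), c(train = 8L, eval = 1L, test = 1L))
  # the published-style split fractions recover exact sizes
  expect_equal(bpregress:::split_sizes(359, c(288, 32, 39) / 359),
               c(288L, 32L, 39L))
  # splits are disjoint and exhaustive
  all_idx <- sort(unname(unlist(co$split)))
  expect_equal(all_idx, 1:10)
})

test_that("different cohort seeds give different anatomies", {
  spec <- small_phantom_spec()
  a <- generate_cohort(spec, 3, c(1, 0, 0) , seed = 1)
  b <- generate_cohort(spec, 3, c(1, 0, 0), seed = 2)
  expect_false(identical(a$landmarks, b$landmarks))
})

test_that("landmark ranks follow the template order when jitter is small", {
  # jitter SD far below the smallest template gap; t large enough that
  # slice rounding rarely reorders closely spaced landmarks
  spec <- phantom_spec(slice_count_range = c(300, 400), in_plane_size = c(32, 32),
                       positional_sd = 0.001)
  tpl <- default_organ_template()
  fr <- c(stats::setNames(tpl$z_start, paste0(tpl$organ, "_start")),
          stats::setNames(tpl$z_end, paste0(tpl$organ, "_end")))
  template_order <- names(sort(fr))
  n_ok <- 0
  n_subj <- 200
  for (seed in seq_len(n_subj)) {
    lm <- generate_phantom(spec, seed)$landmarks
    if (!is.unsorted(lm[template_order])) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / n_subj, 0.99)
})

test_that("per-slice mean intensity encodes axial position", {
  ph <- small_subject()
  m <- apply(ph$volume$voxels, 1, mean)
  rho <- stats::cor(seq_along(m), m, method = "spearman")
  expect_gte(abs(rho), 0.8)
})

test_that("invalid specs are rejected", {
  tpl <- default_organ_template()
  tpl$z_end[1] <- tpl$z_start[1]        # zero-length organ
  expect_error(phantom_spec(organ_order_template = tpl), "z_start < z_end")
  tpl2 <- default_organ_template()
  tpl2$z_end[2] <- 1.4
  expect_error(phantom_spec(organ_order_template = tpl2), "0, 1")
  expect_error(phantom_spec(slice_count_range = c(8, 10)), "slice_count_range")
  expect_error(generate_cohort(small_phantom_spec(), 2), "at least 3")
})

test_that("write_cohort produces images, labels, sidecars and a manifest", {
  spec <- small_phantom_spec()
  co <- generate_cohort(spec, 3, c(1/3, 1/3, 1/3), seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 3)
  expect_setequal(manifest$split, c("train", "eval", "test"))
  expect_equal(manifest$t, vapply(co$volumes, n_slices, 0L))
  v1 <- read_volume(file.path(dir, "subject_001_image.nii.gz"))
  expect_equal(v1$voxels, co$volumes[[1]]$voxels, tolerance = 1e-6)
  lm <- jsonlite::read_json(file.path(dir, "subject_001_landmarks.json"))
  expect_equal(unlist(lm), unlist(as.list(co$landmarks[[1]])))
})
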