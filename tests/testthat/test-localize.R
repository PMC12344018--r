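# Region bounds, cropping, mask embedding, Dice.

make_table <- function(landmarks, means, sds = 0) {
  tab <- data.frame(landmark = landmarks, mean = means,
                    sd = rep(sds, length.out = length(means)),
                    n = 5, stringsAsFactors = FALSE)
  structure(tab,
            normalization = structure(list(MinValue = 0, MaxValue = 1,
                                           low_landmark = landmarks[1],
                                           high_landmark = landmarks[length(landmarks)]),
                                      class = "bpr_normalization"),
            config = postprocess_config(),
            class = c("bpr_landmark_table", "data.frame"))
}

test_that("the score window follows mean +/- margin * SD", {
  tab <- make_table(c("bladder_start", "bladder_end"), c(10, 40), sds = 2)
  spec <- region_spec("pelvis", "bladder", margin_multiplier = 1.5)
  curve <- linear_curve(101, 0, 100)
  b <- region_bounds(curve, spec, tab)
  expect_equal(b$score_low, 10 - 1.5 * 2)
  expect_equal(b$score_high, 40 + 1.5 * 2)
  # zero margin collapses to the landmark means
  b0 <- region_bounds(curve, region_spec("pelvis", "bladder",
                                         margin_multiplier = 0), tab)
  expect_equal(b0$score_low, 10)
  expect_equal(b0$score_high, 40)
})

test_that("score bounds invert to slices on a linear curve", {
  # curve 0..100 over 101 slices: score s lives on slice s + 1
  tab <- make_table(c("a_start", "a_end"), c(10, 40), sds = 2)
  spec <- region_spec("r", "a", margin_multiplier = 1.5)
  b <- region_bounds(linear_curve(101, 0, 100), spec, tab)
  expect_equal(b$z_low, 7 + 1)
  expect_equal(b$z_high, 43 + 1)
  # a wider margin can only widen the crop
  margins <- c(0, 1, 2, 4)
  zl <- zh <- numeric(length(margins))
  for (i in seq_along(margins)) {
    bm <- region_bounds(linear_curve(101, 0, 100),
                        region_spec("r", "a", margin_multiplier = margins[i]), tab)
    zl[i] <- bm$z_low; zh[i] <- bm$z_high
  }
  expect_true(all(diff(zl) <= 0))
  expect_true(all(diff(zh) >= 0))
})

test_that("degenerate score windows are errors", {
  tab <- make_table(c("a_start", "a_end"), c(30, 31), sds = 10)
  spec <- region_spec("r", "a", margin_multiplier = 1.5)  # window [15, 46] ok
  expect_silent(region_bounds(linear_curve(101, 0, 100), spec, tab))
  tab2 <- make_table(c("a_start", "a_end"), c(31, 30), sds = 0)
  expect_error(region_bounds(linear_curve(101, 0, 100),
                             region_spec("r", "a",
                                         inferior_landmark = "a_start",
                                         superior_landmark = "a_end",
                                         margin_multiplier = 0), tab2),
               class = "bpr_degenerate_region_error")
})

test_that("crop_volume keeps inclusive slice ranges with provenance", {
  ph <- small_subject()
  t <- n_slices(ph$volume)
  b <- list(z_low = 7L, z_high = 43L, region = "test")
  sub <- crop_volume(ph$volume, b)
  expect_equal(n_slices(sub), 37L)
  expect_equal(sub$voxels[1, , ], ph$volume$voxels[7, , ])
  prov <- attr(sub, "provenance")
  expect_equal(prov$original_t, t)
  # identity crop
  full <- crop_volume(ph$volume, list(z_low = 1L, z_high = t, region = "all"))
  expect_equal(full$voxels, ph$volume$voxels)
  # out-of-range bounds clip with a warning, never silently empty
  expect_warning(clipped <- crop_volume(ph$volume,
                                        list(z_low = -5L, z_high = t + 10L,
                                             region = "x")), "clipped")
  expect_equal(n_slices(clipped), t)
})

test_that("embed_mask places the crop at its offset with background elsewhere", {
  sub <- array(0L, c(3, 4, 4))
  sub[1, 1, 1] <- 7L
  prov <- list(original_t = 10L, z_low = 7L, z_high = 9L, region = "r")
  whole <- embed_mask(sub, prov)
  expect_equal(dim(whole), c(10L, 4L, 4L))
  expect_equal(whole[7, 1, 1], 7L)
  expect_equal(sum(whole != 0), 1)
  # all-zero sub-mask embeds to all zeros
  expect_true(all(embed_mask(array(0L, c(3, 4, 4)), prov) == 0))
  # full-volume crop is the identity
  m <- array(sample(0:2, 160, TRUE), c(10, 4, 4))
  expect_equal(embed_mask(m, list(original_t = 10L, z_low = 1L, z_high = 10L)), m)
  # inconsistent provenance errors
  expect_error(embed_mask(sub, list(original_t = 10L, z_low = 7L, z_high = 8L)),
               "slices")
})

test_that("crop then embed reproduces a mask inside the bounds exactly", {
  ph <- small_subject()
  lab <- ph$labels$labels
  t <- dim(lab)[1]
  b <- list(z_low = 5L, z_high = t - 3L, region = "mid")
  vol <- as_volume(lab + 0)   # treat labels as a volume for cropping
  sub <- crop_volume(vol, b)
  whole <- embed_mask(sub$voxels, attr(sub, "provenance"))
  expect_equal(whole[5:(t - 3), , ], lab[5:(t - 3), , ] + 0)
  expect_true(all(whole[1:4, , ] == 0))
})

test_that("dice matches its closed forms and symmetry", {
  a <- array(0L, c(2, 3, 3)); b <- array(0L, c(2, 3, 3))
  a[1, 1:2, 1:2] <- 1L
  expect_equal(dice(a, a), 1)            # identical non-empty
  b[2, 1:2, 1:2] <- 1L
  expect_equal(dice(a, b), 0)            # disjoint
  # |A| = |B| = 4 with overlap 2 -> 2*2/8 = 0.5
  b2 <- array(0L, c(2, 3, 3)); b2[1, 1:2, 2:3] <- 1L
  expect_equal(sum(a != 0), 4); expect_equal(sum(b2 != 0), 4)
  expect_equal(dice(a, b2), 0.5)
  expect_equal(dice(b2, a), dice(a, b2)) # symmetric
  # both empty for the evaluated label -> 1 by convention
  expect_equal(dice(a * 0L, b * 0L), 1)
  expect_equal(dice(a, a, label = 9), 1)
  expect_error(dice(a, array(0L, c(3, 3, 3))), "shape")
})

test_that("route_regions reports failing regions and returns the rest", {
  ph <- small_subject()
  t <- n_slices(ph$volume)
  curve <- linear_curve(t, 0, 100)
  # table with landmarks for all four regions
  lms <- ph$landmarks
  means <- 100 * (lms - 1) / (t - 1)
  tab <- make_table(names(lms), as.numeric(means), sds = 1)
  out <- route_regions(ph$volume, curve, default_region_specs(), tab)
  expect_length(out$regions, 4)
  expect_length(out$failed, 0)
  for (r in out$regions) expect_gte(n_slices(r$volume), 1)
  # remove the pelvis landmarks: pelvis fails, others survive
  tab2 <- tab[!grepl("femoral_head|bladder|rectum", tab$landmark), ]
  attr(tab2, "normalization") <- attr(tab, "normalization")
  attr(tab2, "config") <- attr(tab, "config")
  class(tab2) <- class(tab)
  out2 <- route_regions(ph$volume, curve, default_region_specs(), tab2)
  expect_named(out2$failed, "pelvis")
  expect_length(out2$regions, 3)
})
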