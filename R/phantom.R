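# Procedural CT phantom: a cohort of axial volumes containing z-ordered
# "organ" bands inside a torso-like body whose cross-section grows
# towards the head. Each organ occupies its own in-plane disc whose
# radius varies smoothly (and asymmetrically) along the band, so every
# slice's 2-D appearance encodes its axial position; the growing,
# brightening body makes the per-slice mean intensity monotone in z, and
# a flat bone marker plus flat air anchor each slice's intensity range.

#' Default organ band template
#'
#' Sixteen organ bands mirroring a torso's inferior-to-superior layout,
#' from femoral head to esophagus, each with mean start/end expressed as a
#' fraction of the scan length. Bands overlap in z as real organs do; the
#' femoral head start is the lowest landmark, the esophagus end the
#' highest. All 32 landmark fractions are distinct.
#'
#' @return data.frame with columns `organ`, `z_start`, `z_end`.
#' @export
default_organ_template <- function() {
  data.frame(
    organ = c("femoral_head", "rectum", "bladder", "large_intestine",
              "small_intestine", "kidney", "duodenum", "liver",
              "gallbladder", "pancreas", "spleen", "stomach",
              "adrenal", "esophagus", "lung", "heart"),
    z_start = c(0.000, 0.015, 0.070, 0.130, 0.160, 0.370, 0.400, 0.430,
                0.460, 0.475, 0.490, 0.515, 0.550, 0.610, 0.625, 0.680),
    z_end   = c(0.110, 0.125, 0.190, 0.385, 0.420, 0.520, 0.505, 0.635,
                0.545, 0.560, 0.615, 0.640, 0.605, 0.965, 0.890, 0.835),
    stringsAsFactors = FALSE)
}

#' Phantom cohort specification
#'
#' @param organ_order_template data.frame of organ bands (see
#'   [default_organ_template()]); start fractions must be strictly below
#'   end fractions and all fractions in `[0, 1]`.
#' @param slice_count_range inclusive range of per-subject slice counts
#'   (default `c(120, 400)`; lower bound must be at least 16).
#' @param in_plane_size in-plane image size in pixels (default `c(96, 96)`).
#' @param positional_sd inter-subject landmark jitter, expressed as a
#'   fraction of the scan length (default 0.02).
#' @param texture_params optional data.frame with per-organ `intensity`,
#'   `contrast` and `shape` columns; a deterministic default assigns each
#'   organ a distinct intensity and an asymmetric radius profile.
#' @param noise_sd SD of the additive bounded (uniform) voxel noise, on
#'   the phantom's 0--1 intensity scale (default 0.01, matching the
#'   10--20 HU scanner noise of real CT relative to its air-to-bone
#'   range).
#' @param seed base seed used by [generate_cohort()].
#' @return an object of class `bpr_phantom_spec`.
#' @export
phantom_spec <- function(organ_order_template = default_organ_template(),
                         slice_count_range = c(120L, 400L),
                         in_plane_size = c(96L, 96L),
                         positional_sd = 0.02,
                         texture_params = NULL,
                         noise_sd = 0.01,
                         seed = 0L) {
  tpl <- organ_order_template
  assert_that(is.data.frame(tpl) &&
                all(c("organ", "z_start", "z_end") %in% names(tpl)),
              "organ_order_template needs columns organ, z_start, z_end")
  assert_that(all(tpl$z_start >= 0 & tpl$z_end <= 1),
              "all z-fractions must lie in [0, 1]")
  assert_that(all(tpl$z_start < tpl$z_end),
              "every organ needs z_start < z_end")
  assert_that(!anyDuplicated(tpl$organ), "duplicate organ names in template")
  if (length(in_plane_size) == 1L) in_plane_size <- rep(in_plane_size, 2L)
  assert_that(length(slice_count_range) == 2L &&
                slice_count_range[1] <= slice_count_range[2] &&
                slice_count_range[1] >= 16,
              "slice_count_range must be an ordered pair with lower bound >= 16")
  assert_that(positional_sd >= 0, "positional_sd must be >= 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  n <- nrow(tpl)
  if (is.null(texture_params)) {
    # deterministic textures: well-separated, nearly homogeneous interior
    # intensities (soft tissue spans a narrow intensity range) assigned in
    # an alternating order so neighbouring bands contrast, plus per-organ
    # asymmetry in the along-z radius profile
    ord <- as.vector(rbind(seq_len(ceiling(n / 2)),
                           n + 1 - seq_len(ceiling(n / 2))))[seq_len(n)]
    texture_params <- data.frame(
      organ = tpl$organ,
      intensity = seq(0.15, 0.85, length.out = n)[ord],
      contrast = rep(c(0.04, 0.08), length.out = n),
      shape = seq(0.7, 1.4, length.out = n),
      stringsAsFactors = FALSE)
  }
  assert_that(nrow(texture_params) == n, "one texture row per organ required")
  structure(list(organ_order_template = tpl,
                 n_organs = n,
                 slice_count_range = as.integer(slice_count_range),
                 in_plane_size = as.integer(in_plane_size),
                 positional_sd = positional_sd,
                 texture_params = texture_params,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bpr_phantom_spec")
}

# one-sided truncation to [0,1] via resampling, clamping as a last resort
rtrunc01 <- function(mean, sd) {
  if (sd == 0) return(mean)
  for (i in 1:50) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
  min(max(stats::rnorm(1, mean, sd), 0), 1)
}

# disjoint in-plane disc layout on a near-square grid
organ_layout <- function(n, size) {
  gc <- ceiling(sqrt(n))
  gr <- ceiling(n / gc)
  cell <- c(size[1] / gr, size[2] / gc)
  centers <- cbind(
    y = cell[1] * ((seq_len(n) - 1) %/% gc + 0.5),
    x = cell[2] * ((seq_len(n) - 1) %% gc + 0.5))
  r_max <- min(cell) / 2 - 1
  assert_that(r_max >= 2, "in_plane_size too small for %d disjoint organ regions", n)
  list(centers = centers, r_max = r_max)
}

#' Generate one phantom subject
#'
#' Draws a slice count from the spec's range, jitters each organ's start
#' and end fraction with a truncated normal of SD `positional_sd`
#' (endpoints re-sorted so start stays at or below end), and renders the
#' volume: a torso disc that widens and brightens toward the head, one
#' near-homogeneous disc per organ band whose radius swells and shrinks
#' along the band, a constant bone marker, and bounded voxel noise.
#' Landmark truth is read back from the rendered label map
#' (first and last labeled slice per organ), so it is consistent with the
#' labels by construction.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer; the same `(spec, subject_seed)` pair always
#'   produces a bit-identical subject.
#' @return list with `volume` (`bpr_volume`), `labels` (`bpr_labelmap`)
#'   and `landmarks` (named integer vector `<organ>_start`/`<organ>_end`,
#'   1-based slice indices).
#' @export
generate_phantom <- function(spec, subject_seed) {
  assert_that(inherits(spec, "bpr_phantom_spec"), "spec must be a phantom_spec")
  tpl <- spec$organ_order_template
  n <- spec$n_organs
  size <- spec$in_plane_size
  lay <- organ_layout(n, size)
  with_seed(subject_seed, {
    t <- if (spec$slice_count_range[1] == spec$slice_count_range[2])
      spec$slice_count_range[1]
    else sample(spec$slice_count_range[1]:spec$slice_count_range[2], 1L)
    # jitter band endpoints
    f_start <- vapply(tpl$z_start, rtrunc01, 0, sd = spec$positional_sd)
    f_end <- vapply(tpl$z_end, rtrunc01, 0, sd = spec$positional_sd)
    swap <- f_start > f_end
    tmp <- f_start[swap]; f_start[swap] <- f_end[swap]; f_end[swap] <- tmp
    z1 <- 1L + as.integer(round(f_start * (t - 1)))
    z2 <- 1L + as.integer(round(f_end * (t - 1)))
    # render: body cross-section and organ discs have anti-aliased (1 px
    # soft) edges, so sub-voxel geometry changes vary continuously with z
    # and every axial slice is appearance-distinguishable from its
    # neighbours. A flat full-intensity "bone" marker and flat air anchor
    # every slice's intensity extremes (organ intensities stay strictly
    # inside), so per-slice min-max normalization has a stable scale.
    labels <- array(0L, c(t, size[1], size[2]))
    yy <- matrix(seq_len(size[1]), size[1], size[2])
    xx <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
    cy <- (size[1] + 1) / 2; cx <- (size[2] + 1) / 2
    d_body <- sqrt(((yy - cy) / (size[1] / 2))^2 + ((xx - cx) / (size[2] / 2))^2)
    d_center <- sqrt((yy - cy)^2 + (xx - cx)^2)
    organ_d <- lapply(seq_len(n), function(o)
      sqrt((yy - lay$centers[o, "y"])^2 + (xx - lay$centers[o, "x"])^2))
    vox <- array(0, c(t, size[1], size[2]))
    aa <- 1                       # soft-edge width, pixels
    # organs taper to (almost) nothing at their band endpoints: the
    # radius still covers the centre voxel (so the landmark slices stay
    # labeled) but the cross-section emerges continuously, with no area
    # jump at the band boundaries
    r_min <- 0.9
    soft <- function(d, r) pmin(1, pmax(0, (r - d) / aa + 0.5))
    zfrac <- (seq_len(t) - 1) / (t - 1)
    # torso cross-sectional area grows linearly towards the head (radius
    # ~ sqrt(z)), so the per-slice appearance change is uniform along z
    body_r <- sqrt(0.55^2 + (0.93^2 - 0.55^2) * zfrac)
    body_val <- 0.30 + 0.25 * zfrac       # and its tissue brightens
    bone_r <- min(size) / 13              # central bone marker, intensity 1
    bone_mask <- soft(d_center, bone_r)
    air <- 0
    aa_body <- aa / (min(size) / 2)       # soft edge in normalized radius
    for (z in seq_len(t)) {
      bmask <- pmin(1, pmax(0, (body_r[z] - d_body) / aa_body + 0.5))
      sl <- air + (body_val[z] - air) * bmask
      for (o in seq_len(n)) {
        if (z < z1[o] || z > z2[o]) next
        tex <- spec$texture_params[o, ]
        span <- max(z2[o] - z1[o], 1L)
        u <- (z - z1[o]) / span
        r <- r_min + (lay$r_max - r_min) * sin(pi * u^tex$shape)
        omask <- soft(organ_d[[o]], r)
        val <- tex$intensity * (1 - tex$contrast * (organ_d[[o]] / lay$r_max)^2)
        sl <- sl * (1 - omask) + val * omask
        labels[z, , ][omask > 0.5 & bone_mask < 0.5] <- o
      }
      sl <- sl * (1 - bone_mask) + bone_mask   # bone marker at intensity 1
      vox[z, , ] <- sl
    }
    # bounded (uniform) voxel noise: CT-like intensities are bounded, and
    # bounded noise keeps the per-slice min-max normalization anchors
    # stable (Gaussian tails would jitter the normalization divisor)
    if (spec$noise_sd > 0)
      vox <- vox + stats::runif(length(vox), -spec$noise_sd * sqrt(3),
                                spec$noise_sd * sqrt(3))
    organ_ids <- stats::setNames(seq_len(n), tpl$organ)
    labmap <- as_labelmap(labels, organ_ids)
    volume <- as_volume(vox, subject_id = sprintf("phantom_%04d", subject_seed %% 10000L))
    lms <- extract_landmarks(labmap, tpl$organ)
    list(volume = volume, labels = labmap, landmarks = lms$landmarks)
  })
}

# largest-remainder rounding of n * fractions to integers summing to n
split_sizes <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    take <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' Generate a phantom cohort with train/eval/test split
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (at least 3).
#' @param split_fractions train/eval/test fractions summing to 1.
#' @param seed master seed; per-subject seeds are derived from it, so each
#'   subject's anatomy is jittered independently.
#' @return an object of class `bpr_cohort`: lists `volumes`, `labels`,
#'   `landmarks` (per subject), and `split` (disjoint, exhaustive index
#'   sets `train`, `eval`, `test`).
#' @export
generate_cohort <- function(spec, n_subjects,
                            split_fractions = c(train = 0.8, eval = 0.1, test = 0.1),
                            seed = spec$seed) {
  assert_that(is_count(n_subjects, 3), "n_subjects must be at least 3")
  assert_that(length(split_fractions) == 3 && all(split_fractions >= 0) &&
                abs(sum(split_fractions) - 1) < 1e-8,
              "split_fractions must be three nonnegative values summing to 1")
  assert_that(n_subjects >= sum(split_fractions > 0),
              "fewer subjects than nonempty splits")
  sizes <- split_sizes(n_subjects, split_fractions)
  subjects <- lapply(seq_len(n_subjects), function(i)
    generate_phantom(spec, derive_seed(seed, paste0("subject", i))))
  perm <- with_seed(derive_seed(seed, "split"), sample.int(n_subjects))
  split <- list(train = sort(perm[seq_len(sizes[1])]),
                eval = sort(perm[sizes[1] + seq_len(sizes[2])]),
                test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  structure(list(volumes = lapply(subjects, `[[`, "volume"),
                 labels = lapply(subjects, `[[`, "labels"),
                 landmarks = lapply(subjects, `[[`, "landmarks"),
                 split = split,
                 spec = spec,
                 n_subjects = as.integer(n_subjects)),
            class = "bpr_cohort")
}

#' @export
print.bpr_cohort <- function(x, ...) {
  t_all <- vapply(x$volumes, n_slices, 0L)
  cat(sprintf("Phantom cohort: %d subjects (%d train / %d eval / %d test), t in [%d, %d]\n",
              x$n_subjects, length(x$split$train), length(x$split$eval),
              length(x$split$test), min(t_all), max(t_all)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-subject NIfTI image and label volumes, a JSON landmark-truth
#' sidecar per subject, and a cohort manifest CSV (subject id, slice count,
#' split).
#'
#' @param cohort a `bpr_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "bpr_cohort"), "not a bpr_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_of <- integer(0)
  for (s in names(cohort$split)) split_of[cohort$split[[s]]] <- s
  rows <- lapply(seq_len(cohort$n_subjects), function(i) {
    id <- sprintf("subject_%03d", i)
    write_volume(cohort$volumes[[i]], file.path(dir, paste0(id, "_image.nii.gz")))
    write_volume(cohort$labels[[i]], file.path(dir, paste0(id, "_labels.nii.gz")))
    jsonlite::write_json(as.list(cohort$landmarks[[i]]),
                         file.path(dir, paste0(id, "_landmarks.json")),
                         auto_unbox = TRUE)
    data.frame(subject_id = id, t = n_slices(cohort$volumes[[i]]),
               split = split_of[i], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
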