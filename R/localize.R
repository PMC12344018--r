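# Score-driven anatomical region cropping. A region is bounded by the
# calibration-table scores of its most inferior and most superior organ
# landmarks, widened by margin_multiplier standard deviations on each
# side; the score window is mapped back to slice indices on the volume's
# normalized smoothed score curve.

#' Define a body region for score-driven cropping
#'
#' @param name region name.
#' @param organs organs the region must cover.
#' @param inferior_landmark,superior_landmark bounding landmark names; if
#'   `NULL` they are resolved against the calibration table at crop time
#'   as the lowest/highest-scoring landmark among the region's organs.
#' @param margin_multiplier crop margin in landmark-score standard
#'   deviations (default 1.5).
#' @return an object of class `bpr_region_spec`.
#' @export
region_spec <- function(name, organs, inferior_landmark = NULL,
                        superior_landmark = NULL, margin_multiplier = 1.5) {
  assert_that(margin_multiplier >= 0, "margin_multiplier must be >= 0")
  assert_that(length(organs) >= 1, "region needs at least one organ")
  structure(list(name = name, organs = organs,
                 inferior_landmark = inferior_landmark,
                 superior_landmark = superior_landmark,
                 margin_multiplier = margin_multiplier),
            class = "bpr_region_spec")
}

#' The four default body regions
#'
#' Thorax, upper abdomen, lower abdomen and pelvis, each listing the
#' organs it must cover. Bounding landmarks are resolved per calibration
#' table as the most inferior and most superior landmark (by reference
#' score) among each region's organs.
#'
#' @param margin_multiplier crop margin in SD units (default 1.5).
#' @return named list of four `bpr_region_spec`s.
#' @export
default_region_specs <- function(margin_multiplier = 1.5) {
  mk <- function(name, organs) region_spec(name, organs,
                                           margin_multiplier = margin_multiplier)
  list(
    thorax = mk("thorax", c("heart", "esophagus", "lung")),
    upper_abdomen = mk("upper_abdomen",
                       c("liver", "stomach", "pancreas", "spleen", "adrenal",
                         "gallbladder", "kidney")),
    lower_abdomen = mk("lower_abdomen",
                       c("duodenum", "small_intestine", "large_intestine")),
    pelvis = mk("pelvis", c("bladder", "rectum", "femoral_head")))
}

table_row <- function(table, landmark) {
  i <- match(landmark, table$landmark)
  if (is.na(i))
    stop_bpr("landmark %s not in calibration table", landmark,
             class = "bpr_key_error")
  list(mean = table$mean[i], sd = table$sd[i])
}

resolve_bounding_landmarks <- function(spec, table) {
  if (!is.null(spec$inferior_landmark) && !is.null(spec$superior_landmark))
    return(list(inferior = spec$inferior_landmark,
                superior = spec$superior_landmark))
  candidates <- as.vector(outer(spec$organs, c("_start", "_end"), paste0))
  present <- candidates[candidates %in% table$landmark]
  if (length(present) < 2)
    stop_bpr("region %s: fewer than two of its landmarks are in the table",
             spec$name, class = "bpr_key_error")
  means <- table$mean[match(present, table$landmark)]
  list(inferior = spec$inferior_landmark %||% present[which.min(means)],
       superior = spec$superior_landmark %||% present[which.max(means)])
}

#' Compute crop bounds for one region
#'
#' The score window is `[mean(inferior) - margin * sd(inferior),
#' mean(superior) + margin * sd(superior)]`; its ends are mapped to slice
#' indices by nearest-score lookup on the volume's normalized smoothed
#' curve and clipped to `[1, t]`.
#'
#' @param curve normalized smoothed score curve of the target volume.
#' @param spec a [region_spec()].
#' @param table a `bpr_landmark_table` containing the bounding landmarks.
#' @return an object of class `bpr_crop_bounds`: list with `z_low`,
#'   `z_high`, `score_low`, `score_high`, `region`.
#' @export
region_bounds <- function(curve, spec, table) {
  assert_that(inherits(spec, "bpr_region_spec"), "spec must be a region_spec")
  lms <- resolve_bounding_landmarks(spec, table)
  inf <- table_row(table, lms$inferior)
  sup <- table_row(table, lms$superior)
  score_low <- inf$mean - spec$margin_multiplier * inf$sd
  score_high <- sup$mean + spec$margin_multiplier * sup$sd
  if (score_low >= score_high)
    stop_bpr("degenerate region %s: score window [%.3f, %.3f] is empty",
             spec$name, score_low, score_high, class = "bpr_degenerate_region_error")
  t <- length(curve)
  z_low <- min(max(predict_landmark_slice(curve, score_low), 1L), t)
  z_high <- min(max(predict_landmark_slice(curve, score_high), 1L), t)
  if (z_low > z_high) { tmp <- z_low; z_low <- z_high; z_high <- tmp }
  structure(list(region = spec$name, z_low = z_low, z_high = z_high,
                 score_low = score_low, score_high = score_high,
                 inferior_landmark = lms$inferior,
                 superior_landmark = lms$superior),
            class = "bpr_crop_bounds")
}

#' Crop a volume to axial bounds
#'
#' Keeps slices `z_low..z_high` inclusive and attaches the provenance
#' needed to re-embed results into the original frame. Bounds outside the
#' volume are clipped with a warning (never silently empty).
#'
#' @param volume a `bpr_volume`.
#' @param bounds a `bpr_crop_bounds` (or a list with `z_low`, `z_high`).
#' @return a `bpr_volume` with attribute `provenance` (list: `original_t`,
#'   `z_low`, `z_high`, `region`).
#' @export
crop_volume <- function(volume, bounds) {
  t <- n_slices(volume)
  z_low <- bounds$z_low
  z_high <- bounds$z_high
  if (z_low < 1 || z_high > t) {
    warning(sprintf("crop bounds [%d, %d] clipped to volume [1, %d]",
                    z_low, z_high, t))
    z_low <- max(z_low, 1L)
    z_high <- min(z_high, t)
  }
  assert_that(z_low <= z_high, "empty crop after clipping")
  sub <- volume$voxels[z_low:z_high, , , drop = FALSE]
  out <- as_volume(sub, spacing = volume$spacing,
                   subject_id = paste0(volume$subject_id, "_",
                                       bounds$region %||% "crop"))
  attr(out, "provenance") <- list(original_t = t, z_low = as.integer(z_low),
                                  z_high = as.integer(z_high),
                                  region = bounds$region %||% NA_character_)
  out
}

#' Crop a volume into the four default body regions
#'
#' Computes [region_bounds()] and [crop_volume()] per region; a region
#' whose bounds cannot be resolved (missing landmark, degenerate window)
#' is reported in `failed` while the remaining regions are still
#' returned.
#'
#' @param volume a `bpr_volume`.
#' @param curve normalized smoothed score curve of that volume.
#' @param specs list of `bpr_region_spec`s (default
#'   [default_region_specs()]).
#' @param table a `bpr_landmark_table`.
#' @return list with `regions` (named list of `list(volume, bounds)`) and
#'   `failed` (named character vector of error messages).
#' @export
route_regions <- function(volume, curve, specs = default_region_specs(), table) {
  regions <- list()
  failed <- character(0)
  for (spec in specs) {
    res <- tryCatch({
      b <- region_bounds(curve, spec, table)
      list(volume = crop_volume(volume, b), bounds = b)
    }, error = function(e) e)
    if (inherits(res, "error")) failed[spec$name] <- conditionMessage(res)
    else regions[[spec$name]] <- res
  }
  list(regions = regions, failed = failed)
}

#' Embed a cropped mask back into the whole-volume frame
#'
#' Places the sub-volume mask at its recorded axial offset; every voxel
#' outside the crop is background (0). This is how localized segmentation
#' outputs are evaluated against whole-volume references, with cropped-out
#' regions counting as background.
#'
#' @param mask 3-D array (or `bpr_volume`) with the crop's shape.
#' @param provenance provenance list from [crop_volume()] (taken from the
#'   mask's attribute if present).
#' @return 3-D array of the original volume's slice count.
#' @export
embed_mask <- function(mask, provenance = attr(mask, "provenance")) {
  if (inherits(mask, "bpr_volume")) {
    provenance <- provenance %||% attr(mask, "provenance")
    mask <- mask$voxels
  }
  assert_that(!is.null(provenance), "no provenance available")
  d <- dim(mask)
  span <- provenance$z_high - provenance$z_low + 1L
  assert_that(d[1] == span,
              "mask has %d slices but provenance records a %d-slice crop",
              d[1], span)
  out <- array(0, c(provenance$original_t, d[2], d[3]))
  storage.mode(out) <- storage.mode(mask)
  out[provenance$z_low:provenance$z_high, , ] <- mask
  out
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for one label, evaluated voxelwise on
#' equal-shape masks. When the label is empty in both masks the
#' coefficient is defined as 1 (perfect agreement on absence); this
#' convention is isolated here.
#'
#' @param mask_a,mask_b integer/logical arrays of equal shape.
#' @param label label id to evaluate (default: any non-zero voxel).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b, label = NULL) {
  assert_that(identical(dim(mask_a), dim(mask_b)),
              "masks must have identical shapes")
  a <- if (is.null(label)) mask_a != 0 else mask_a == label
  b <- if (is.null(label)) mask_b != 0 else mask_b == label
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
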