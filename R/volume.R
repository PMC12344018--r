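# Volume and label-map containers. The axial axis is array dimension 1 and
# runs inferior -> superior: slice 1 is the most inferior slice, matching
# the convention that lower slice scores are more inferior.

#' Construct a volume
#'
#' @param voxels numeric 3-D array ordered `(z, y, x)` with `z` running
#'   inferior to superior.
#' @param spacing voxel spacing in mm per axis, `c(z, y, x)`.
#' @param subject_id identifier string.
#' @return an object of class `bpr_volume`.
#' @export
as_volume <- function(voxels, spacing = c(3, 1, 1), subject_id = "subject") {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3L,
              "voxels must be a 3-D array (z, y, x)")
  assert_that(dim(voxels)[1] >= 1, "volume must contain at least one slice")
  assert_that(length(spacing) == 3L && all(spacing > 0), "spacing must be 3 positive values")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 subject_id = as.character(subject_id)),
            class = "bpr_volume")
}

#' Number of axial slices in a volume
#' @param volume a `bpr_volume`.
#' @return integer slice count `t`.
#' @export
n_slices <- function(volume) {
  assert_that(inherits(volume, "bpr_volume"), "not a bpr_volume")
  dim(volume$voxels)[1]
}

#' @export
print.bpr_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volume '%s': %d slices of %d x %d (spacing %s mm)\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Construct a label map
#'
#' @param labels integer 3-D array aligned with its volume; 0 is background.
#' @param organ_ids named integer vector mapping organ name to positive id.
#' @return an object of class `bpr_labelmap`.
#' @export
as_labelmap <- function(labels, organ_ids) {
  assert_that(is.array(labels) && length(dim(labels)) == 3L,
              "labels must be a 3-D array")
  assert_that(!is.null(names(organ_ids)) && all(organ_ids > 0),
              "organ_ids must be a named vector of positive ids")
  structure(list(labels = labels,
                 organ_ids = stats::setNames(as.integer(organ_ids), names(organ_ids))),
            class = "bpr_labelmap")
}

# internal: (z, y, x) -> NIfTI's (x, y, z) and back
zyx_to_xyz <- function(a) aperm(a, c(3, 2, 1))
xyz_to_zyx <- function(a) aperm(a, c(3, 2, 1))

#' Write a volume (or label map) as NIfTI
#'
#' Voxels are stored in RAS+ orientation with the axial axis as the NIfTI
#' third axis, so the file round-trips through [read_volume()] unchanged.
#'
#' @param volume a `bpr_volume`, or a `bpr_labelmap` (written as integers).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "bpr_labelmap")) {
    arr <- zyx_to_xyz(volume$labels)
    storage.mode(arr) <- "integer"
    spacing <- c(1, 1, 1)
  } else {
    assert_that(inherits(volume, "bpr_volume"), "not a bpr_volume or bpr_labelmap")
    arr <- zyx_to_xyz(volume$voxels)
    spacing <- rev(volume$spacing)  # (x, y, z) mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(diag(c(spacing, 1)), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI file or a DICOM series directory
#'
#' The voxel array is reoriented so axis 1 runs inferior to superior
#' (using the NIfTI xform or the DICOM geometry). NIfTI files without
#' orientation metadata are assumed to already be inferior -> superior,
#' with a warning.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory containing one
#'   uncompressed single-frame DICOM series.
#' @param subject_id identifier attached to the result (defaults to the
#'   file or directory name).
#' @return a `bpr_volume` in canonical orientation.
#' @export
read_volume <- function(path, subject_id = NULL) {
  assert_that(file.exists(path), "path does not exist: %s", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (dir.exists(path)) return(read_dicom_series(path, subject_id = subject_id))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_bpr("cannot read NIfTI file %s: %s",
                                               path, conditionMessage(e),
                                               class = "bpr_format_error"))
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    RNifti::orientation(img) <- "RAS"   # third axis then runs inferior -> superior
  } else {
    warning("no orientation metadata in ", path,
            "; assuming axis 3 already runs inferior -> superior")
  }
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  as_volume(xyz_to_zyx(arr), spacing = rev(pd[seq_len(3)]), subject_id = subject_id)
}

#' Read a label map written by [write_volume()]
#'
#' @param path NIfTI file of integer labels.
#' @param organ_ids named integer vector naming the label ids.
#' @return a `bpr_labelmap`.
#' @export
read_labelmap <- function(path, organ_ids) {
  vol <- read_volume(path)
  lab <- vol$voxels
  storage.mode(lab) <- "integer"
  as_labelmap(lab, organ_ids)
}
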