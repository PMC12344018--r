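# Organ landmarks: for each organ, the first (most inferior, "start") and
# last (most superior, "end") axial slice on which its label id occurs.

#' Extract organ landmarks from a label map
#'
#' For every requested organ, finds the lowest and highest axial slice
#' index containing its label id and records them as `<organ>_start` and
#' `<organ>_end` (1-based slice indices). Organs registered in the label
#' map but absent from the voxels are omitted from the landmark set and
#' listed in the `missing` field.
#'
#' @param labels a `bpr_labelmap`.
#' @param organs organ names to extract; all must be registered in
#'   `labels$organ_ids`.
#' @return list with `landmarks` (named integer vector) and `missing`
#'   (character vector of organs with no voxels).
#' @export
extract_landmarks <- function(labels, organs = names(labels$organ_ids)) {
  assert_that(inherits(labels, "bpr_labelmap"), "labels must be a bpr_labelmap")
  unknown <- setdiff(organs, names(labels$organ_ids))
  if (length(unknown) > 0)
    stop_bpr("organ(s) with no registered id: %s",
             paste(unknown, collapse = ", "), class = "bpr_key_error")
  arr <- labels$labels
  t <- dim(arr)[1]
  # one pass: which ids occur on each slice
  per_slice <- lapply(seq_len(t), function(z) unique(as.vector(arr[z, , ])))
  out <- integer(0)
  missing <- character(0)
  for (organ in organs) {
    id <- labels$organ_ids[[organ]]
    present <- which(vapply(per_slice, function(u) id %in% u, TRUE))
    if (length(present) == 0) {
      missing <- c(missing, organ)
    } else {
      out[paste0(organ, "_start")] <- min(present)
      out[paste0(organ, "_end")] <- max(present)
    }
  }
  list(landmarks = out, missing = missing)
}
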