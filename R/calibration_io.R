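# JSON persistence for calibration tables.

CALIBRATION_SCHEMA <- "bpregress-calibration-1"

#' Save a landmark calibration table as JSON
#'
#' The file stores the schema version, the normalization block
#' (`MinValue`, `MaxValue`, anchor names), the post-processing
#' configuration, and one entry per landmark with full-precision mean/SD.
#'
#' @param table a `bpr_landmark_table`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_calibration <- function(table, path) {
  assert_that(inherits(table, "bpr_landmark_table"), "table must be a bpr_landmark_table")
  assert_that(nrow(table) >= 1, "cannot save an empty calibration table")
  params <- attr(table, "normalization")
  config <- attr(table, "config")
  payload <- list(
    schema = CALIBRATION_SCHEMA,
    normalization = list(MinValue = params$MinValue, MaxValue = params$MaxValue,
                         low_landmark = params$low_landmark,
                         high_landmark = params$high_landmark),
    postprocess = list(gaussian_sd = config$gaussian_sd,
                       boundary_mode = config$boundary_mode),
    landmarks = lapply(seq_len(nrow(table)), function(i)
      list(landmark = table$landmark[i], mean = table$mean[i],
           sd = table$sd[i], n = table$n[i])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a landmark calibration table from JSON
#'
#' @param path JSON file written by [save_calibration()].
#' @return a `bpr_landmark_table`.
#' @export
load_calibration <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, CALIBRATION_SCHEMA))
    stop_bpr("calibration schema mismatch in %s: found %s, expected %s",
             path, payload$schema %||% "<none>", CALIBRATION_SCHEMA,
             class = "bpr_schema_error")
  if (is.null(payload$normalization))
    stop_bpr("calibration file %s missing the normalization block", path,
             class = "bpr_schema_error")
  nb <- payload$normalization
  params <- structure(list(MinValue = nb$MinValue, MaxValue = nb$MaxValue,
                           low_landmark = nb$low_landmark,
                           high_landmark = nb$high_landmark),
                      class = "bpr_normalization")
  config <- postprocess_config(gaussian_sd = payload$postprocess$gaussian_sd,
                               boundary_mode = payload$postprocess$boundary_mode)
  tab <- do.call(rbind, lapply(payload$landmarks, function(e)
    data.frame(landmark = e$landmark, mean = e$mean, sd = e$sd, n = e$n,
               stringsAsFactors = FALSE)))
  structure(tab, normalization = params, config = config,
            class = c("bpr_landmark_table", "data.frame"))
}
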