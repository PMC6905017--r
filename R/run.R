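#' Batch-measure a set of plate photographs
#'
#' Runs [preprocess_root()] and [measure_root()] over every image in
#' `input` (a directory of PNG/TIFF/JPEG files, or a character vector of
#' file paths), writing a summary CSV, a JSON record per image and -- with
#' `debug = TRUE` -- the intermediate binary masks. Files that fail to
#' process are logged to stderr and skipped.
#'
#' @param input Directory or vector of image paths.
#' @param output_dir Output directory (created if missing).
#' @param cal A `"pixel_calibration"` from [calibrate_plate()].
#' @param config A [preprocess_config()].
#' @param volume_mode `"cylinder"` (default) or `"literal"`.
#' @param debug Write intermediate masks as PNG.
#' @return The summary data frame (one row per processed image), invisibly.
#'   Attribute `"n_failed"` counts skipped files.
#' @export
run_measure <- function(input, output_dir, cal,
                        config = preprocess_config(),
                        volume_mode = c("cylinder", "literal"),
                        debug = FALSE) {
  volume_mode <- match.arg(volume_mode)
  stopifnot(inherits(cal, "pixel_calibration"))
  paths <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
               ignore.case = TRUE, full.names = TRUE)
  } else input
  if (length(paths) == 0L)
    stop("run_measure: no input images found", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  n_failed <- 0L
  for (path in paths) {
    nm <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      img <- read_plate_image(path)
      pp <- preprocess_root(img, config)
      meas <- measure_root(pp, cal, volume_mode = volume_mode)
      rec <- as.data.frame(meas)
      rec <- cbind(data.frame(image = nm), rec)
      jsonlite::write_json(c(list(image = nm), unclass(meas)),
                           file.path(output_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
      if (debug)
        write_mask_png(pp$mask, file.path(output_dir, paste0(nm, "_mask.png")))
      rec
    }, error = function(e) {
      message(sprintf("run_measure: skipping %s: %s", path,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[nm]] <- res
  }
  if (length(rows) == 0L)
    stop("run_measure: all input images failed", call. = FALSE)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  utils::write.csv(summary, file.path(output_dir, "measurements.csv"),
                   row.names = FALSE)
  attr(summary, "n_failed") <- n_failed
  invisible(summary)
}

#' Validate this system's measurements against a reference instrument
#'
#' Reads two aligned CSV files (one row per sample, one numeric column per
#' morphological parameter; columns matched by name), runs
#' [validate_instruments()] and writes the report as CSV and JSON.
#'
#' @param test_csv CSV of this system's measurements.
#' @param reference_csv CSV of the reference instrument's measurements.
#' @param output_dir Output directory (created if missing).
#' @param alpha Significance level for the t-test verdict.
#' @return The report data frame, invisibly.
#' @export
run_validate <- function(test_csv, reference_csv, output_dir, alpha = 0.01) {
  test <- utils::read.csv(test_csv)
  reference <- utils::read.csv(reference_csv)
  report <- validate_instruments(test, reference, alpha)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report, file.path(output_dir, "validation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(output_dir, "validation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(report)
}
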