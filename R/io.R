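## File I/O: multi-page TIFF stacks with calibration metadata, deterministic
## CSV tables, and JSON summaries.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                     ".meta.json")

#' Read a multi-page TIFF as an ImageFrameSeries
#'
#' Reads all pages of a grayscale TIFF. The pixel calibration is resolved in
#' this order: explicit arguments (the run configuration) win; otherwise a
#' JSON metadata sidecar written by [writeStack()] is used; otherwise TIFF
#' resolution tags (pixels per centimetre or inch); otherwise 1 um. A
#' conflict between an explicit argument and file metadata is logged via
#' `message()` and the argument wins.
#'
#' @param path path to a readable TIFF file.
#' @param pixelSizeUm,frameIntervalMin,zStepUm optional calibration overrides.
#' @return An [ImageFrameSeries-class].
#' @export
readStack <- function(path, pixelSizeUm = NULL, frameIntervalMin = NULL,
                      zStepUm = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) {
      if (dim(p)[3] > 1)
        stop("page ", i, " has ", dim(p)[3],
             " channels; expected grayscale")
      p <- p[, , 1, drop = TRUE]
    }
    if (!is.matrix(p)) stop("page ", i, " is not a 2D image")
    p
  })
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1)
    stop("ragged TIFF: page sizes differ (first mismatch at page ",
         which(vapply(mats, function(m) !identical(dim(m), dims[[1]]),
                      logical(1)))[1], ")")
  meta <- list()
  sc <- sidecarPath(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  # TIFF resolution tag (pixels per unit) as a fallback pixel size
  tagPx <- NULL
  a <- attributes(pages[[1]])
  if (!is.null(a$x.resolution) && a$x.resolution > 0 &&
      !is.null(a$resolution.unit)) {
    perUm <- switch(as.character(a$resolution.unit),
                    cm = a$x.resolution / 1e4,
                    inch = a$x.resolution / 25400,
                    NULL)
    if (!is.null(perUm)) tagPx <- 1 / perUm
  }
  pick <- function(arg, key, fallback, what) {
    fileVal <- meta[[key]]
    if (is.null(fileVal)) fileVal <- fallback
    if (!is.null(arg)) {
      if (!is.null(fileVal) && !is.na(fileVal) &&
          abs(arg - fileVal) > 1e-9 * max(1, abs(arg)))
        message("calibration conflict for ", what, " in ", basename(path),
                ": file says ", fileVal, ", configuration says ", arg,
                "; using the configuration")
      return(arg)
    }
    if (!is.null(fileVal)) fileVal else NA_real_
  }
  px <- pick(pixelSizeUm, "pixel_size_um", tagPx, "pixel size")
  if (is.na(px)) px <- 1
  ImageFrameSeries(
    array(unlist(mats), c(dims[[1]], length(mats))),
    pixelSizeUm = px,
    frameIntervalMin = pick(frameIntervalMin, "frame_interval_min", NULL,
                            "frame interval"),
    zStepUm = pick(zStepUm, "z_step_um", NULL, "z step"))
}

#' Write an ImageFrameSeries as a multi-page TIFF
#'
#' Writes 16-bit grayscale pages (values must lie in `[0, 1]`; rescale first
#' if necessary) and a JSON metadata sidecar (`<basename>.meta.json`) holding
#' the calibration, which [readStack()] restores.
#'
#' @param series an [ImageFrameSeries-class], a matrix, or a list of
#'   matrices.
#' @param path output TIFF path.
#' @param bitsPerSample 8, 16 (default) or 32.
#' @return `path`, invisibly.
#' @export
writeStack <- function(series, path, bitsPerSample = 16) {
  if (!is(series, "ImageFrameSeries")) series <- ImageFrameSeries(series)
  frames <- lapply(seq_len(nFrames(series)), getFrame, x = series)
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("pixel values must lie in [0, 1] for TIFF output; rescale first")
  tiff::writeTIFF(frames, path, bits.per.sample = bitsPerSample)
  meta <- list(pixel_size_um = series@pixelSizeUm)
  if (!is.na(series@frameIntervalMin))
    meta$frame_interval_min <- series@frameIntervalMin
  if (!is.na(series@zStepUm)) meta$z_step_um <- series@zStepUm
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a measurement table as deterministic CSV
#'
#' UTF-8, '.' decimal CSV with a header and a deterministic row order (sorted
#' by the key columns), so identical measurements give byte-identical files.
#'
#' @param rows a data.frame (may have zero rows).
#' @param path output path.
#' @param keyColumns columns to sort by; default all columns left to right.
#' @return `path`, invisibly.
#' @export
writeMeasurementTable <- function(rows, path,
                                  keyColumns = names(rows)) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) && length(keyColumns)) {
    keyColumns <- intersect(keyColumns, names(rows))
    rows <- rows[do.call(order, rows[keyColumns]), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e)
    stop("failed to write table to ", path, ": ", conditionMessage(e)))
  invisible(path)
}
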