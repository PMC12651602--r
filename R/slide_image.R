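#' Multichannel slide image
#'
#' A `slide_image` is the unit of detection: a set of equally sized 16-bit
#' intensity matrices (one per channel) plus the physical pixel scale.
#' Channels follow the four-colour liquid-biopsy layout: `dapi` (nuclear),
#' `ck` (cytokeratin), `cd45` (pan-leukocyte / membrane) and `bf`
#' (brightfield).
#'
#' @param channels named list of numeric matrices with identical dimensions;
#'   intensities on the 16-bit scale `[0, 65535]`.
#' @param pixel_scale physical size of one pixel in micrometres.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(channels, pixel_scale) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- vapply(channels, function(m) dim(m), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all channels must have identical dimensions")
  }
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0) {
    stop("pixel_scale must be a positive scalar (um/px)")
  }
  structure(list(channels = channels, pixel_scale = pixel_scale),
            class = "slide_image")
}

#' @export
dim.slide_image <- function(x) dim(x$channels[[1L]])

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<slide_image> %d x %d px (%.3g um/px), channels: %s\n",
              d[1L], d[2L], x$pixel_scale,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel matrix from a slide image
#'
#' @param image a [slide_image()].
#' @param name channel name, e.g. `"dapi"`.
#' @return The intensity matrix.
#' @export
get_channel <- function(image, name) {
  stopifnot(inherits(image, "slide_image"))
  if (!name %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(image$channels), collapse = ", ")))
  }
  image$channels[[name]]
}

#' Write a slide (and its ground truth, if any) to disk
#'
#' Writes one 16-bit TIFF per channel (`<prefix>_<channel>.tiff`), the pixel
#' scale and simulation configuration as YAML (`<prefix>_meta.yaml`), and the
#' ground-truth table as CSV (`<prefix>_truth.csv`) when the object carries
#' one.
#'
#' @param x a [slide_image()] or the result of [generate_slide()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, default `"slide"`.
#' @return Invisibly, the vector of files written.
#' @export
write_slide <- function(x, dir, prefix = "slide") {
  truth <- NULL; config <- NULL
  if (inherits(x, "synthetic_slide")) {
    truth <- x$truth; config <- x$config; image <- x$image
  } else {
    image <- x
  }
  stopifnot(inherits(image, "slide_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(image$channels)) {
    f <- file.path(dir, sprintf("%s_%s.tiff", prefix, nm))
    m <- pmin(pmax(image$channels[[nm]], 0), 65535) / 65535
    tiff::writeTIFF(t(m), f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  meta <- list(pixel_scale = image$pixel_scale,
               channels = names(image$channels))
  if (!is.null(config)) meta$sim_config <- unclass(config)
  fmeta <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  yaml::write_yaml(meta, fmeta)
  files <- c(files, fmeta)
  if (!is.null(truth)) {
    ftruth <- file.path(dir, sprintf("%s_truth.csv", prefix))
    utils::write.csv(truth, ftruth, row.names = FALSE)
    files <- c(files, ftruth)
  }
  invisible(files)
}

#' Read a slide written by [write_slide()]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used at write time.
#' @return A [slide_image()]; if a ground-truth CSV is present it is attached
#'   as attribute `"truth"`.
#' @export
read_slide <- function(dir, prefix = "slide") {
  meta <- yaml::read_yaml(file.path(dir, sprintf("%s_meta.yaml", prefix)))
  channels <- lapply(meta$channels, function(nm) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tiff", prefix, nm)))
    t(m) * 65535
  })
  names(channels) <- meta$channels
  img <- slide_image(channels, meta$pixel_scale)
  ftruth <- file.path(dir, sprintf("%s_truth.csv", prefix))
  if (file.exists(ftruth)) {
    attr(img, "truth") <- utils::read.csv(ftruth)
  }
  img
}
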