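#' Construct a slide raster
#'
#' The unit of pipeline input: an 8-bit RGB raster plus its physical
#' resolution in microns per pixel (mpp).
#'
#' @param pixels integer array `H x W x 3`, values in 0..255.
#' @param microns_per_pixel positive physical resolution (micron/pixel).
#' @param slide_id character identifier used in output file names.
#' @return An object of class `slide_raster`.
#' @export
slide_raster <- function(pixels, microns_per_pixel, slide_id = "slide") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      microns_per_pixel <= 0)
    stop("microns_per_pixel must be a single positive number")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         microns_per_pixel = as.numeric(microns_per_pixel),
         slide_id = as.character(slide_id)),
    class = "slide_raster")
}

#' @export
print.slide_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_raster '%s'> %d x %d px @ %.4g micron/px (%.1f x %.1f mm)\n",
              x$slide_id, d[2], d[1], x$microns_per_pixel,
              d[2] * x$microns_per_pixel / 1000,
              d[1] * x$microns_per_pixel / 1000))
  invisible(x)
}

#' @export
dim.slide_raster <- function(x) dim(x$pixels)

#' Write a slide to PNG with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `microns_per_pixel` and `slide_id`,
#' plus any extra metadata supplied (e.g. ground truth for synthetic
#' slides).
#'
#' @param slide a [slide_raster()].
#' @param path output PNG path.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, extra = list()) {
  stopifnot(inherits(slide, "slide_raster"))
  png::writePNG(slide$pixels / 255, target = path)
  meta <- c(list(microns_per_pixel = slide$microns_per_pixel,
                 slide_id = slide$slide_id), extra)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a slide written by [write_slide()]
#'
#' @param path PNG path; `<path>.json` must exist alongside.
#' @return A [slide_raster()]; the full sidecar is attached as attribute
#'   `"sidecar"`.
#' @export
read_slide <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE]
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out <- slide_raster(array(as.integer(round(px * 255)), dim(px)),
                      meta$microns_per_pixel,
                      slide_id = meta$slide_id %||% basename(path))
  attr(out, "sidecar") <- meta
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric (mirror) reflection of 0-based indices onto 0..(n-1);
# folds repeatedly so it is valid for any offset
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n
  i <- i %% period
  i[i < 0] <- i[i < 0] + period
  too_big <- i >= n
  i[too_big] <- period - 1L - i[too_big]
  as.integer(i)
}
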