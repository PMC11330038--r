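# Reinhard color transfer works in the decorrelated log-opponent (l,
# alpha, beta) space: RGB -> LMS cone response -> log10 -> opponent axes.
# Matrices follow the original color-transfer formulation.

RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                    0.1967, 0.7244, 0.0782,
                    0.0241, 0.1288, 0.8444),
                  3, 3, byrow = TRUE)
LMS2RGB <- solve(RGB2LMS)
OPP <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
OPP_INV <- solve(OPP)
LMS_EPS <- 1e-4  # guard against log of zero for pure-black pixels

#' RGB to log-opponent (l-alpha-beta) color space
#'
#' @param rgbmat numeric `n x 3` matrix of RGB values in 0..255.
#' @return `n x 3` matrix of (l, alpha, beta) coordinates.
#' @export
rgb_to_lab_reinhard <- function(rgbmat) {
  lms <- (rgbmat / 255) %*% t(RGB2LMS)
  lms[lms < LMS_EPS] <- LMS_EPS
  log10(lms) %*% t(OPP)
}

#' @rdname rgb_to_lab_reinhard
#' @param labmat numeric `n x 3` matrix of (l, alpha, beta) coordinates.
#' @export
lab_reinhard_to_rgb <- function(labmat) {
  lms <- 10^(labmat %*% t(OPP_INV))
  rgb <- lms %*% t(LMS2RGB) * 255
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  rgb
}

slide_pixel_matrix <- function(slide) {
  px <- slide$pixels
  dim(px) <- c(prod(dim(px)[1:2]), 3L)
  px
}

#' Compute a stain profile
#'
#' Per-channel means and standard deviations in log-opponent space, the
#' statistics Reinhard normalization transfers between slides. With
#' `tissue_only = TRUE` (default) near-white glass background is excluded:
#' pixels whose mean RGB intensity is at least 90% of the maximum level.
#'
#' @param slide a [slide_raster()].
#' @param tissue_only exclude near-white background pixels before
#'   computing statistics.
#' @return An object of class `stain_profile` with `channel_means`,
#'   `channel_stds`, `n_pixels`.
#' @export
compute_stain_profile <- function(slide, tissue_only = TRUE) {
  stopifnot(inherits(slide, "slide_raster"))
  px <- slide_pixel_matrix(slide)
  if (tissue_only) {
    keep <- rowMeans(px) < 0.9 * 255
    if (!any(keep))
      stop("no tissue pixels left after background exclusion; ",
           "try tissue_only = FALSE")
    px <- px[keep, , drop = FALSE]
  }
  lab <- rgb_to_lab_reinhard(px)
  means <- colMeans(lab)
  stds <- apply(lab, 2, sd)
  if (any(stds == 0))
    warning("degenerate stain profile: zero variance in channel(s) ",
            paste(c("l", "alpha", "beta")[stds == 0], collapse = ", "))
  structure(list(channel_means = setNames(means, c("l", "alpha", "beta")),
                 channel_stds = setNames(stds, c("l", "alpha", "beta")),
                 tissue_only = tissue_only, n_pixels = nrow(px)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile> (log-opponent space)\n")
  print(rbind(mean = x$channel_means, sd = x$channel_stds))
  invisible(x)
}

#' Serialize a stain profile to JSON
#' @param profile a `stain_profile`.
#' @param path JSON file path.
#' @export
write_stain_profile <- function(profile, path) {
  x <- unclass(profile)
  x$channel_means <- as.list(x$channel_means)  # keep channel names in JSON
  x$channel_stds <- as.list(x$channel_stds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(channel_means = unlist(p$channel_means),
                 channel_stds = unlist(p$channel_stds),
                 tissue_only = p$tissue_only, n_pixels = p$n_pixels),
            class = "stain_profile")
}

#' Reinhard stain normalization
#'
#' Affine per-channel map in log-opponent space onto a reference profile:
#' `out = (in - mean_src) / sd_src * sd_ref + mean_ref`, then inverse
#' transform and clip to 0..255. All slides in a study are normalized
#' against the same reference profile so color characteristics are
#' consistent across scans.
#'
#' @param slide a [slide_raster()].
#' @param ref reference [compute_stain_profile()].
#' @param tissue_only compute the source profile on tissue pixels only
#'   (the map itself is still applied to every pixel).
#' @return A normalized [slide_raster()].
#' @export
reinhard_normalize <- function(slide, ref, tissue_only = TRUE) {
  stopifnot(inherits(slide, "slide_raster"), inherits(ref, "stain_profile"))
  if (any(ref$channel_stds <= 0))
    stop("reference profile has zero sd in channel(s) ",
         paste(names(ref$channel_stds)[ref$channel_stds <= 0], collapse = ", "))
  src <- compute_stain_profile(slide, tissue_only = tissue_only)
  if (any(src$channel_stds == 0))
    stop("source profile is degenerate (zero sd) in channel(s) ",
         paste(names(src$channel_stds)[src$channel_stds == 0], collapse = ", "))
  lab <- rgb_to_lab_reinhard(slide_pixel_matrix(slide))
  lab <- sweep(lab, 2, src$channel_means, "-")
  lab <- sweep(lab, 2, ref$channel_stds / src$channel_stds, "*")
  lab <- sweep(lab, 2, ref$channel_means, "+")
  rgb <- round(lab_reinhard_to_rgb(lab))
  out <- array(as.integer(rgb), dim(slide$pixels))
  slide_raster(out, slide$microns_per_pixel, slide$slide_id)
}

# sparse area-average resampling operator mapping n_in samples onto n_out
# equal boxes (each output value is the exact mean of its box)
area_average_operator <- function(n_in, n_out) {
  f <- n_in / n_out
  i <- rep(seq_len(n_out), each = ceiling(f) + 1L)
  j0 <- floor((rep(seq_len(n_out), each = ceiling(f) + 1L) - 1) * f)
  j <- j0 + rep(seq_len(ceiling(f) + 1L) - 1L, times = n_out)
  lo <- pmax(j, (i - 1) * f)
  hi <- pmin(j + 1, i * f)
  w <- (hi - lo) / f
  keep <- w > 1e-12 & j < n_in
  Matrix::sparseMatrix(i = i[keep], j = j[keep] + 1L, x = w[keep],
                       dims = c(n_out, n_in))
}

#' Harmonize slide resolution by area-average downsampling
#'
#' Brings a slide scanned at finer resolution onto the working resolution
#' (default 0.503 micron/pixel, a 20x scan). Output dimensions are
#' `round(n * mpp / target)`; each output pixel is the exact area average
#' of its source box, so mean intensity is preserved.
#'
#' @param slide a [slide_raster()].
#' @param target_mpp target resolution in micron/pixel.
#' @param allow_upsample permit `mpp > target_mpp` (off by default: the
#'   pipeline only downsamples; pass `TRUE` to override explicitly).
#' @return A [slide_raster()] at `target_mpp`.
#' @export
harmonize_resolution <- function(slide, target_mpp = 0.503,
                                 allow_upsample = FALSE) {
  stopifnot(inherits(slide, "slide_raster"))
  mpp <- slide$microns_per_pixel
  if (abs(mpp - target_mpp) <= 1e-9 * target_mpp) return(slide)
  if (mpp > target_mpp && !allow_upsample)
    stop("slide is coarser (", mpp, " micron/px) than target (", target_mpp,
         "); only downsampling is supported unless allow_upsample = TRUE")
  d <- dim(slide$pixels)
  H2 <- max(1L, as.integer(round(d[1] * mpp / target_mpp)))
  W2 <- max(1L, as.integer(round(d[2] * mpp / target_mpp)))
  Rop <- area_average_operator(d[1], H2)
  Cop <- Matrix::t(area_average_operator(d[2], W2))
  out <- array(0L, c(H2, W2, 3L))
  for (ch in 1:3) {
    m <- as.matrix(Rop %*% slide$pixels[, , ch] %*% Cop)
    m <- round(m)
    m[m < 0] <- 0; m[m > 255] <- 255
    out[, , ch] <- as.integer(m)
  }
  slide_raster(out, target_mpp, slide$slide_id)
}

#' Tile a slide into fixed-size tiles
#'
#' Tiles partition the reflection-padded canvas without gaps or overlap;
#' coordinates are 0-based pixel units, tile (row, col) has its top-left
#' at `(x0, y0) = (col * ts, row * ts)` with half-open extents.
#'
#' @param slide a [slide_raster()].
#' @param tile_size_px tile edge length (default 1536).
#' @return An object of class `tile_grid`.
#' @export
tile_slide <- function(slide, tile_size_px = 1536L) {
  stopifnot(inherits(slide, "slide_raster"))
  if (tile_size_px < 256) stop("tile_size_px must be >= 256")
  d <- dim(slide$pixels)
  nrows <- ceiling(d[1] / tile_size_px)
  ncols <- ceiling(d[2] / tile_size_px)
  tiles <- expand.grid(col = seq_len(ncols) - 1L, row = seq_len(nrows) - 1L)
  tiles <- tiles[, c("row", "col")]
  tiles$x0 <- tiles$col * tile_size_px
  tiles$y0 <- tiles$row * tile_size_px
  rownames(tiles) <- NULL
  structure(list(tile_size_px = as.integer(tile_size_px), tiles = tiles,
                 slide_height = d[1], slide_width = d[2],
                 slide_id = slide$slide_id),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid '%s'> %d tiles of %d px over %d x %d px\n",
              x$slide_id, nrow(x$tiles), x$tile_size_px,
              x$slide_width, x$slide_height))
  invisible(x)
}

#' Extract one tile (reflection-padded at the slide boundary)
#'
#' @param slide a [slide_raster()].
#' @param grid a [tile_grid()] for that slide.
#' @param row,col 0-based tile indices.
#' @return Integer array `ts x ts x 3`.
#' @export
extract_tile <- function(slide, grid, row, col) {
  ts <- grid$tile_size_px
  d <- dim(slide$pixels)
  rows <- reflect_index(row * ts + 0:(ts - 1), d[1]) + 1L
  cols <- reflect_index(col * ts + 0:(ts - 1), d[2]) + 1L
  slide$pixels[rows, cols, , drop = FALSE]
}

#' Reassemble tiles into the original slide
#'
#' Inverse of tiling: pastes tiles in grid order and crops the padding;
#' the round trip is bit-exact.
#'
#' @param tiles list of tile arrays in the order of `grid$tiles`.
#' @param grid the [tile_grid()] used to cut them.
#' @param microns_per_pixel,slide_id metadata for the rebuilt raster.
#' @return A [slide_raster()].
#' @export
reassemble_tiles <- function(tiles, grid, microns_per_pixel = 0.503,
                             slide_id = grid$slide_id) {
  ts <- grid$tile_size_px
  H <- grid$slide_height; W <- grid$slide_width
  out <- array(0L, c(H, W, 3L))
  for (k in seq_len(nrow(grid$tiles))) {
    r0 <- grid$tiles$y0[k]; c0 <- grid$tiles$x0[k]
    rows <- (r0 + 1):min(r0 + ts, H)
    cols <- (c0 + 1):min(c0 + ts, W)
    out[rows, cols, ] <- tiles[[k]][seq_along(rows), seq_along(cols), ,
                                    drop = FALSE]
  }
  slide_raster(out, microns_per_pixel, slide_id)
}
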