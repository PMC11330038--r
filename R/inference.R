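# Heatmap geometry. Cell (i, j) (0-based) represents the patch CENTERED
# at slide pixel (x, y) = (j*stride + stride/2, i*stride + stride/2);
# centers that fall past the slide edge (last row/column of cells on
# non-multiple-of-stride slides) are reflected back inside, matching the
# reflect padding used for patch extraction.

heatmap_geometry <- function(slide, stride_px, patch_size_px) {
  d <- dim(slide$pixels)
  list(n_rows = as.integer(ceiling(d[1] / stride_px)),
       n_cols = as.integer(ceiling(d[2] / stride_px)),
       stride_px = as.integer(stride_px),
       patch_size_px = as.integer(patch_size_px),
       slide_mpp = slide$microns_per_pixel,
       slide_height = d[1], slide_width = d[2],
       slide_id = slide$slide_id)
}

# 0-based center coordinates of every cell along one axis
cell_center_coords <- function(n_cells, stride_px, n_pixels) {
  reflect_index((seq_len(n_cells) - 1L) * stride_px + stride_px %/% 2L,
                n_pixels)
}

#' Single-class confidence heatmap
#'
#' Grid of classifier confidences at 1/stride of slide resolution, with
#' the geometry metadata needed to map cells back to slide pixels.
#'
#' @param values numeric matrix `n_rows x n_cols` in \[0, 1\].
#' @param class_label channel name.
#' @param geometry geometry list as attached by [sliding_window_infer()].
#' @return Object of class `confidence_heatmap`.
#' @export
confidence_heatmap <- function(values, class_label, geometry) {
  stopifnot(nrow(values) == geometry$n_rows,
            ncol(values) == geometry$n_cols)
  structure(list(values = values, class_label = class_label,
                 geometry = geometry),
            class = "confidence_heatmap")
}

#' @export
print.confidence_heatmap <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<confidence_heatmap '%s'> %d x %d cells (stride %d, patch %d) for '%s'\n",
              x$class_label, g$n_rows, g$n_cols, g$stride_px,
              g$patch_size_px, g$slide_id))
  invisible(x)
}

#' Categorical GM/WM/background region map
#'
#' Same grid geometry as the deposit heatmaps ("pixel-wise overlapping"),
#' with integer labels 0 = background, 1 = GM, 2 = WM.
#'
#' @param labels integer matrix of codes 0/1/2.
#' @param geometry shared heatmap geometry.
#' @return Object of class `region_map`.
#' @export
region_map <- function(labels, geometry) {
  stopifnot(nrow(labels) == geometry$n_rows,
            ncol(labels) == geometry$n_cols)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, geometry = geometry),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  g <- x$geometry
  tab <- tabulate(x$labels + 1L, 3L)
  cat(sprintf("<region_map> %d x %d cells: %d background, %d GM, %d WM\n",
              g$n_rows, g$n_cols, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Extract a reflect-padded patch centered on a slide pixel
#'
#' @param slide a [slide_raster()].
#' @param cx,cy 0-based pixel coordinates of the patch center.
#' @param size patch edge length.
#' @return Integer array `size x size x 3`.
#' @export
extract_patch <- function(slide, cx, cy, size = 256L) {
  half <- size %/% 2L
  d <- dim(slide$pixels)
  rows <- reflect_index((cy - half):(cy + half - 1L), d[1]) + 1L
  cols <- reflect_index((cx - half):(cx + half - 1L), d[2]) + 1L
  slide$pixels[rows, cols, , drop = FALSE]
}

#' Sliding-window inference over a slide
#'
#' Evaluates a patch classifier at every cell of the stride-reduced grid
#' ("from left to right, top to bottom") and assembles one confidence
#' heatmap per output channel. Patches overhanging the slide boundary use
#' reflect-padded context. Batching cannot change results (the classifier
#' contract requires determinism); with the default stride of 16 pixels
#' the heatmaps are at 1/16 of slide resolution.
#'
#' @param slide a [slide_raster()] (already stain-normalized when the
#'   classifier expects it).
#' @param classifier a [patch_classifier()].
#' @param stride_px stride in pixels; must divide the patch size.
#' @param batch_size patches per classifier call.
#' @param use_pixel_fn when the classifier provides a center-pixel fast
#'   path, use it (identical results by contract).
#' @return Named list of [confidence_heatmap()], one per channel.
#' @export
sliding_window_infer <- function(slide, classifier, stride_px = 16L,
                                 batch_size = 256L, use_pixel_fn = TRUE) {
  stopifnot(inherits(slide, "slide_raster"),
            inherits(classifier, "patch_classifier"))
  if (classifier$patch_size_px %% stride_px != 0)
    stop("stride_px must divide the classifier patch size")
  geom <- heatmap_geometry(slide, stride_px, classifier$patch_size_px)
  k <- length(classifier$channels)
  n_cells <- geom$n_rows * geom$n_cols

  cys <- cell_center_coords(geom$n_rows, stride_px, geom$slide_height)
  cxs <- cell_center_coords(geom$n_cols, stride_px, geom$slide_width)

  if (use_pixel_fn && !is.null(classifier$pixel_fn)) {
    # row-major cell enumeration: rows outer, cols inner
    ridx <- rep(cys + 1L, each = geom$n_cols)
    cidx <- rep(cxs + 1L, times = geom$n_rows)
    flat <- ridx + (cidx - 1L) * geom$slide_height
    px <- slide$pixels
    dim(px) <- c(geom$slide_height * geom$slide_width, 3L)
    conf <- classifier$pixel_fn(px[flat, , drop = FALSE])
  } else {
    conf <- matrix(0, n_cells, k)
    done <- 0L
    while (done < n_cells) {
      take <- min(batch_size, n_cells - done)
      idx <- done + seq_len(take)
      cell_row <- (idx - 1L) %/% geom$n_cols   # row-major enumeration
      cell_col <- (idx - 1L) %% geom$n_cols
      patches <- lapply(seq_len(take), function(t)
        extract_patch(slide, cxs[cell_col[t] + 1L], cys[cell_row[t] + 1L],
                      classifier$patch_size_px))
      out <- classifier$predict_patches(patches)
      if (!is.matrix(out) || nrow(out) != take || ncol(out) != k)
        stop("classifier returned malformed output for batch starting at patch ",
             done + 1L)
      done <- done + take
      conf[idx, ] <- out
    }
  }
  bad <- which(conf < 0 | conf > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("classifier returned confidence outside [0,1] at patch index ",
         bad[1, 1])

  out <- lapply(seq_len(k), function(ch)
    confidence_heatmap(matrix(conf[, ch], geom$n_rows, geom$n_cols,
                              byrow = TRUE),
                       classifier$channels[ch], geom))
  names(out) <- classifier$channels
  out
}

#' Infer the GM/WM/background region map
#'
#' Runs the region classifier with the same sliding window as the deposit
#' classifier so both outputs share one grid. Per cell the label is the
#' argmax of the three probabilities; exact ties resolve by the fixed
#' priority background > GM > WM.
#'
#' @param slide a [slide_raster()].
#' @param classifier_g a [patch_classifier()] with channels GM, WM,
#'   background.
#' @param stride_px stride in pixels.
#' @param ... passed to [sliding_window_infer()].
#' @return A [region_map()].
#' @export
infer_region_map <- function(slide, classifier_g, stride_px = 16L, ...) {
  hm <- sliding_window_infer(slide, classifier_g, stride_px = stride_px, ...)
  stopifnot(all(c("GM", "WM", "background") %in% names(hm)))
  gm <- hm$GM$values; wm <- hm$WM$values; bg <- hm$background$values
  lab <- matrix(0L, nrow(gm), ncol(gm))
  lab[gm > bg & gm >= wm] <- 1L            # GM beats background only strictly
  lab[wm > bg & wm > gm] <- 2L             # WM must beat both strictly
  region_map(lab, hm$GM$geometry)
}

same_geometry <- function(a, b) {
  ga <- a$geometry; gb <- b$geometry
  isTRUE(all.equal(ga[c("n_rows", "n_cols", "stride_px", "slide_mpp")],
                   gb[c("n_rows", "n_cols", "stride_px", "slide_mpp")]))
}

#' Persist heatmaps and region maps
#'
#' Heatmap values are written as 32-bit float TIFF plus a JSON geometry
#' sidecar; region maps as PNG (palette codes scaled to gray levels) plus
#' sidecar.
#'
#' @param hm a [confidence_heatmap()].
#' @param path output path.
#' @export
write_heatmap <- function(hm, path) {
  tiff::writeTIFF(hm$values, path, bits.per.sample = 32L)
  jsonlite::write_json(c(hm$geometry, list(class_label = hm$class_label)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  v <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cls <- meta$class_label
  meta$class_label <- NULL
  confidence_heatmap(v, cls, meta)
}

#' @rdname write_heatmap
#' @param rm a [region_map()].
#' @export
write_region_map <- function(rm, path) {
  png::writePNG(rm$labels / 2, path)
  jsonlite::write_json(rm$geometry, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_region_map <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  region_map(matrix(as.integer(round(v * 2)), nrow(v), ncol(v)), meta)
}
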