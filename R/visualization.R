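#' Overlay rendering specification
#'
#' Colors follow the field convention for GM/WM deposit maps: black
#' background, cyan GM, yellow WM, orange deposits.
#'
#' @param background,gm,wm,deposit RGB triples (0..255).
#' @param marker_style `"cells"` paints every blob cell; `"centroid"`
#'   paints one dot per blob at its centroid.
#' @param upscale integer pixel replication factor for the output image.
#' @return An object of class `overlay_spec`.
#' @export
overlay_spec <- function(background = c(0, 0, 0), gm = c(0, 255, 255),
                         wm = c(255, 255, 0), deposit = c(255, 165, 0),
                         marker_style = c("cells", "centroid"),
                         upscale = 1L) {
  marker_style <- match.arg(marker_style)
  cols <- rbind(background, gm, wm, deposit)
  if (anyDuplicated(cols)) stop("overlay colors must be distinct")
  structure(list(background = background, gm = gm, wm = wm,
                 deposit = deposit, marker_style = marker_style,
                 upscale = as.integer(upscale)),
            class = "overlay_spec")
}

#' Render a region + deposit overlay image
#'
#' One overlay per deposit class: the region map painted in its three
#' colors with the class's blob cells (or centroid dots) in orange on
#' top. A pure function of its inputs, rendered at heatmap resolution
#' with optional integer upscaling.
#'
#' @param regions a [region_map()].
#' @param labeled a [label_blobs()] result for one class (regions already
#'   assigned or not; excluded blobs are still drawn).
#' @param spec an [overlay_spec()].
#' @return Integer RGB array `(rows*upscale) x (cols*upscale) x 3`.
#' @export
render_overlay <- function(regions, labeled = NULL, spec = overlay_spec()) {
  stopifnot(inherits(regions, "region_map"))
  if (!is.null(labeled) && !same_geometry(labeled, regions))
    stop("blob labels and region map have mismatched geometry")
  H <- nrow(regions$labels); W <- ncol(regions$labels)
  colmat <- rbind(spec$background, spec$gm, spec$wm)
  paint <- regions$labels + 1L
  deposit_cells <- rep(FALSE, H * W)
  if (!is.null(labeled) && nrow(labeled$blobs)) {
    if (spec$marker_style == "cells") {
      deposit_cells <- as.vector(labeled$labels > 0)
    } else {
      r <- round(labeled$blobs$centroid_row) + 1L
      c <- round(labeled$blobs$centroid_col) + 1L
      deposit_cells[(c - 1L) * H + r] <- TRUE
    }
  }
  img <- array(0L, c(H, W, 3L))
  for (ch in 1:3) {
    v <- colmat[paint, ch]
    v[deposit_cells] <- spec$deposit[ch]
    img[, , ch] <- as.integer(v)
  }
  if (spec$upscale > 1L) {
    img <- img[rep(seq_len(H), each = spec$upscale),
               rep(seq_len(W), each = spec$upscale), , drop = FALSE]
  }
  img
}

#' Write per-class overlay PNGs for one slide
#'
#' Files are named `<slide_id>.<class>.overlay.png`.
#'
#' @param regions a [region_map()].
#' @param blobs_by_class named list of [label_blobs()] results.
#' @param dir output directory.
#' @param spec an [overlay_spec()].
#' @param slide_id identifier used in file names.
#' @return Character vector of written paths, invisibly.
#' @export
write_overlays <- function(regions, blobs_by_class, dir,
                           spec = overlay_spec(),
                           slide_id = regions$geometry$slide_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cls in names(blobs_by_class)) {
    img <- render_overlay(regions, blobs_by_class[[cls]], spec)
    path <- file.path(dir, sprintf("%s.%s.overlay.png", slide_id, cls))
    png::writePNG(img / 255, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
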