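#' Threshold a confidence heatmap into a binary mask
#'
#' Confidences below the threshold become zero, values at or above it
#' become one (the boundary value is kept).
#'
#' @param hm a [confidence_heatmap()].
#' @param threshold detection threshold in (0, 1].
#' @return An object of class `binary_mask`.
#' @export
threshold_heatmap <- function(hm, threshold) {
  stopifnot(inherits(hm, "confidence_heatmap"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  structure(list(values = hm$values >= threshold,
                 class_label = hm$class_label,
                 threshold_used = threshold,
                 geometry = hm$geometry),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s'> %d x %d cells, %d positive (threshold %g)\n",
              x$class_label, nrow(x$values), ncol(x$values),
              sum(x$values), x$threshold_used))
  invisible(x)
}

#' Remove small connected components from a mask
#'
#' The cleaning step between thresholding and counting: components with
#' fewer than `min_blob_cells` cells are dropped; nothing else changes.
#' Idempotent by construction.
#'
#' @param mask a [threshold_heatmap()] result.
#' @param min_blob_cells minimum component size to keep (>= 1).
#' @param connectivity 4 or 8.
#' @return The cleaned `binary_mask`.
#' @export
clean_mask <- function(mask, min_blob_cells = 2L, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_blob_cells < 1) stop("min_blob_cells must be >= 1")
  if (min_blob_cells == 1L || !any(mask$values)) return(mask)
  lab <- .cc_label(mask$values, as.integer(connectivity))
  sizes <- tabulate(lab)
  drop <- which(sizes < min_blob_cells)
  if (length(drop)) mask$values[lab %in% drop] <- FALSE
  mask
}

#' Label connected blobs in a binary mask
#'
#' Maximal connected components under the chosen connectivity, in
#' deterministic reading order (row-major by each component's first
#' cell). Cell coordinates are 0-based (row, col) on the heatmap grid.
#'
#' @param mask a `binary_mask`.
#' @param connectivity 4 (edge neighbors) or 8 (adds diagonals; the
#'   default for object counting on coarse grids).
#' @return A list: `blobs` (data frame: blob_id, class_label, cell_count,
#'   centroid_row, centroid_col, bounding box) and `labels` (integer
#'   label matrix).
#' @export
label_blobs <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .cc_label(mask$values, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    blobs <- data.frame(blob_id = integer(), class_label = character(),
                        cell_count = integer(),
                        centroid_row = numeric(), centroid_col = numeric(),
                        row_min = integer(), row_max = integer(),
                        col_min = integer(), col_max = integer())
  } else {
    idx <- which(lab > 0)
    rc <- arrayInd(idx, dim(lab))
    id <- factor(lab[idx], levels = seq_len(n))
    r0 <- rc[, 1] - 1L; c0 <- rc[, 2] - 1L   # 0-based cell coordinates
    blobs <- data.frame(
      blob_id = seq_len(n),
      class_label = mask$class_label,
      cell_count = as.integer(tabulate(as.integer(id), n)),
      centroid_row = as.numeric(tapply(r0, id, mean)),
      centroid_col = as.numeric(tapply(c0, id, mean)),
      row_min = as.integer(tapply(r0, id, min)),
      row_max = as.integer(tapply(r0, id, max)),
      col_min = as.integer(tapply(c0, id, min)),
      col_max = as.integer(tapply(c0, id, max)))
  }
  list(blobs = blobs, labels = lab, geometry = mask$geometry,
       class_label = mask$class_label)
}

#' Attribute blobs to gray or white matter
#'
#' Majority vote of each blob's cells over the region map: the blob goes
#' to whichever of GM/WM holds more of its cells (exact GM/WM ties go to
#' GM); when a strict majority of cells lie on background the blob is
#' excluded from counting (detections on glass).
#'
#' @param labeled result of [label_blobs()].
#' @param regions a [region_map()] on the same grid.
#' @return `labeled` with a `region` column (`"GM"`, `"WM"`,
#'   `"excluded"`) added to its `blobs` data frame.
#' @export
assign_region <- function(labeled, regions) {
  stopifnot(inherits(regions, "region_map"))
  if (!same_geometry(labeled, regions))
    stop("blob labels and region map have mismatched geometry")
  blobs <- labeled$blobs
  if (!nrow(blobs)) {
    blobs$region <- character()
    labeled$blobs <- blobs
    return(labeled)
  }
  lab <- labeled$labels
  idx <- which(lab > 0)
  id <- lab[idx]
  reg <- regions$labels[idx]
  n <- nrow(blobs)
  cnt <- matrix(0L, n, 3)
  for (code in 0:2) {
    t <- tabulate(id[reg == code], n)
    cnt[, code + 1] <- t
  }
  total <- rowSums(cnt)
  region <- ifelse(cnt[, 2] >= cnt[, 3], "GM", "WM")
  region[cnt[, 1] > total / 2] <- "excluded"
  blobs$region <- region
  labeled$blobs <- blobs
  labeled
}

#' Count vector constructor
#'
#' The pipeline's 1x6 tally of deposit objects: (GM, WM) x (cored,
#' diffuse, CAA), ordered GM-cored, GM-diffuse, GM-CAA, WM-cored,
#' WM-diffuse, WM-CAA.
#'
#' @param x named or unnamed nonnegative integer vector of length 6.
#' @param mode `"blob"` (objects) or `"patchvote"` (cell votes).
#' @return Named integer vector of class `count_vector`.
#' @export
count_vector <- function(x = integer(6), mode = "blob") {
  stopifnot(length(x) == 6, all(x >= 0))
  structure(setNames(as.integer(x), COUNT_SLOTS), mode_label = mode,
            class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("<count_vector, mode=%s>\n", attr(x, "mode_label")))
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Tally labeled blobs into the 1x6 count vector
#'
#' @param blobs_by_class list of [assign_region()] results (one per
#'   deposit class, or a single combined blob data frame).
#' @return A [count_vector()] of non-excluded blobs; its sum equals the
#'   number of counted objects.
#' @export
count_deposits <- function(blobs_by_class) {
  if (!is.null(blobs_by_class$blobs)) blobs_by_class <- list(blobs_by_class)
  df <- do.call(rbind, lapply(blobs_by_class, function(b)
    b$blobs[, c("class_label", "region")]))
  out <- setNames(integer(6), COUNT_SLOTS)
  if (!is.null(df) && nrow(df)) {
    df <- df[df$region != "excluded", , drop = FALSE]
    slot <- paste0(tolower(df$region), "_", tolower(df$class_label))
    tab <- table(factor(slot, levels = COUNT_SLOTS))
    out[] <- as.integer(tab)
  }
  count_vector(out, mode = "blob")
}

#' Patch-vote counting mode
#'
#' The alternative accumulator: for every tissue cell whose confidence
#' exceeds its class threshold, one vote is added to the slot (argmax
#' class, cell region). Votes are cells, not objects, so totals are much
#' larger than blob counts; outputs carry `mode = "patchvote"`.
#'
#' @param heatmaps named list of [confidence_heatmap()] for cored,
#'   diffuse, CAA.
#' @param regions a [region_map()] on the same grid.
#' @param thresholds named per-class thresholds.
#' @return A [count_vector()] with mode `"patchvote"`.
#' @export
patchvote_count <- function(heatmaps, regions,
                            thresholds = c(cored = 0.9, diffuse = 0.9,
                                           CAA = 0.9)) {
  stopifnot(all(DEPOSIT_CLASSES %in% names(heatmaps)))
  for (cls in DEPOSIT_CLASSES)
    if (!same_geometry(heatmaps[[cls]], regions))
      stop("heatmap '", cls, "' and region map have mismatched geometry")
  v_cored <- heatmaps$cored$values
  v_diff <- heatmaps$diffuse$values
  v_caa <- heatmaps$CAA$values
  any_hit <- (v_cored >= thresholds[["cored"]]) |
             (v_diff >= thresholds[["diffuse"]]) |
             (v_caa >= thresholds[["CAA"]])
  # argmax class per cell, ties to the first of (cored, diffuse, CAA)
  cls_idx <- matrix(1L, nrow(v_cored), ncol(v_cored))
  cls_idx[v_diff > v_cored] <- 2L
  best <- pmax(v_cored, v_diff)
  cls_idx[v_caa > best] <- 3L
  out <- setNames(integer(6), COUNT_SLOTS)
  for (code in 1:2) {
    in_region <- regions$labels == code & any_hit
    t <- tabulate(cls_idx[in_region], 3L)
    pre <- if (code == 1) "gm_" else "wm_"
    out[paste0(pre, c("cored", "diffuse", "caa"))] <- t
  }
  count_vector(out, mode = "patchvote")
}

#' Physical GM and WM areas of a region map
#'
#' Each heatmap cell represents a stride x stride pixel footprint, so a
#' cell covers `(stride_px * slide_mpp)^2` square microns. Areas are
#' measured at heatmap resolution, matching the grid on which counts are
#' defined.
#'
#' @param regions a [region_map()].
#' @return Named numeric vector `c(GM = ..., WM = ...)` in square microns.
#' @export
region_areas <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  g <- regions$geometry
  if (is.null(g$slide_mpp) || !is.finite(g$slide_mpp))
    stop("region map geometry is missing microns-per-pixel")
  cell_um2 <- (g$stride_px * g$slide_mpp)^2
  c(GM = sum(regions$labels == 1L) * cell_um2,
    WM = sum(regions$labels == 2L) * cell_um2)
}

#' Per-square-micron density table
#'
#' One row per (class, region): count, region area, and density =
#' count/area. When a region has zero area and zero count the density is
#' reported as missing; a positive count over zero area is an error.
#'
#' @param counts a [count_vector()].
#' @param areas named vector from [region_areas()].
#' @param slide_id identifier recorded in the table.
#' @return A data frame of class `density_table`.
#' @export
compute_densities <- function(counts, areas, slide_id = "slide") {
  stopifnot(inherits(counts, "count_vector"))
  if (any(areas < 0)) stop("areas must be nonnegative")
  region <- rep(c("GM", "WM"), each = 3)
  cls <- rep(DEPOSIT_CLASSES, 2)
  area <- as.numeric(areas[region])
  cnt <- as.integer(counts)
  if (any(area == 0 & cnt > 0))
    stop("positive count over a zero-area region")
  density <- ifelse(area > 0, cnt / area, NA_real_)
  out <- data.frame(slide_id = slide_id, region = region,
                    deposit_class = cls, count = cnt, area_um2 = area,
                    density_per_um2 = density,
                    mode = attr(counts, "mode_label"))
  class(out) <- c("density_table", "data.frame")
  out
}
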