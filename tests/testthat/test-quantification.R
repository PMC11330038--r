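test_that("thresholding keeps the boundary value and matches elementwise comparison", {
  geom_vals <- matrix(runif(64 * 64), 64, 64)
  hm <- confidence_heatmap(geom_vals, "cored",
                           abquant:::heatmap_geometry(
                             uniform_slide(c(0, 0, 0), 1024, 1024), 16, 256))
  mask <- threshold_heatmap(hm, 0.5)
  expect_identical(mask$values, geom_vals >= 0.5)

  hm$values[1, 1] <- 0.5
  expect_true(threshold_heatmap(hm, 0.5)$values[1, 1])
  hm$values[] <- 0
  expect_false(any(threshold_heatmap(hm, 0.9)$values))

  expect_error(threshold_heatmap(hm, 0), "\\(0, 1\\]")
  expect_error(threshold_heatmap(hm, 1.2), "\\(0, 1\\]")
})

test_that("cleaning removes only undersized components and is idempotent", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE                       # singleton
  m[5:6, 4:5] <- TRUE                   # 4-cell block
  m[8, 7:8] <- TRUE                     # 2-cell pair, wait: sizes 1 and 5
  mask <- as_mask(m)
  cleaned <- clean_mask(mask, min_blob_cells = 2)
  expect_false(cleaned$values[2, 2])
  expect_true(all(cleaned$values[5:6, 4:5]))
  expect_true(all(cleaned$values[8, 7:8]))

  expect_identical(clean_mask(mask, 1)$values, mask$values)
  expect_identical(clean_mask(cleaned, 2)$values, cleaned$values)

  # two components of sizes 1 and 5 with min 2: only the 5 survives
  m2 <- matrix(FALSE, 6, 6)
  m2[1, 1] <- TRUE
  m2[3, 1:5] <- TRUE
  c2 <- clean_mask(as_mask(m2), 2)
  expect_equal(sum(c2$values), 5)
  expect_false(c2$values[1, 1])
})

test_that("blob labeling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_blobs(as_mask(m), 8)$blobs), 1L)
  expect_equal(nrow(label_blobs(as_mask(m), 4)$blobs), 2L)
  expect_equal(nrow(label_blobs(as_mask(matrix(FALSE, 4, 4)))$blobs), 0L)
})

test_that("blob labeling agrees with a flood-fill oracle on random masks", {
  set.seed(99)
  for (rep in 1:25) {
    m <- matrix(runif(64 * 64) < 0.4, 64, 64)
    for (conn in c(4L, 8L)) {
      got <- label_blobs(as_mask(m), conn)
      want <- flood_fill_label(m, conn)
      expect_identical(got$labels, want)
    }
  }
})

test_that("blob labeling agrees with EBImage on 4-connectivity", {
  set.seed(5)
  m <- matrix(runif(128 * 128) < 0.35, 128, 128)
  got <- label_blobs(as_mask(m), 4L)$labels
  ref <- EBImage::bwlabel(m * 1)
  # same partition up to label names: cross-tabulation is a bijection
  expect_equal(max(got), max(ref))
  joint <- table(got[m], ref[m])
  expect_equal(sum(joint > 0), max(got))
})

test_that("blob metadata is in reading order with 0-based centroids", {
  m <- matrix(FALSE, 6, 8)
  m[2, 2:3] <- TRUE          # first in reading order
  m[5:6, 6:7] <- TRUE
  out <- label_blobs(as_mask(m), 8)
  expect_equal(out$blobs$blob_id, c(1L, 2L))
  expect_equal(out$blobs$cell_count, c(2L, 4L))
  expect_equal(out$blobs$centroid_row, c(1, 4.5))
  expect_equal(out$blobs$centroid_col, c(1.5, 5.5))
  expect_equal(out$blobs$row_min, c(1L, 4L))
  expect_equal(out$blobs$col_max, c(2L, 6L))
})

test_that("region attribution follows majority vote with documented ties", {
  labels <- matrix(0L, 6, 10)
  labels[, 1:5] <- 1L; labels[, 6:10] <- 2L
  regions <- as_region_map(labels)

  # fully inside GM
  m <- matrix(FALSE, 6, 10); m[2:3, 2:3] <- TRUE
  out <- assign_region(label_blobs(as_mask(m), 8), regions)
  expect_equal(out$blobs$region, "GM")

  # 6 WM cells vs 4 GM cells -> WM
  m2 <- matrix(FALSE, 6, 10); m2[1, 2:5] <- TRUE; m2[1, 6:10] <- TRUE
  m2[2, 6] <- TRUE
  out2 <- assign_region(label_blobs(as_mask(m2), 8), regions)
  expect_equal(out2$blobs$region, "WM")

  # 5 GM vs 5 WM tie -> GM
  m3 <- matrix(FALSE, 6, 10); m3[3, 1:10] <- TRUE
  out3 <- assign_region(label_blobs(as_mask(m3), 8), regions)
  expect_equal(out3$blobs$region, "GM")

  # strict majority on background -> excluded
  labels_bg <- matrix(0L, 6, 10); labels_bg[, 1] <- 1L
  m4 <- matrix(FALSE, 6, 10); m4[2, 1:5] <- TRUE
  out4 <- assign_region(label_blobs(as_mask(m4), 8),
                        as_region_map(labels_bg))
  expect_equal(out4$blobs$region, "excluded")

  # geometry mismatch is an error
  other <- as_region_map(matrix(0L, 5, 5))
  expect_error(assign_region(label_blobs(as_mask(m), 8), other),
               "geometry")
})

test_that("blob counts recover ground truth end to end and add componentwise", {
  spec <- spec_with_deposits(
    c(rep("cored", 5), rep("diffuse", 3), rep("CAA", 2)),
    c(rep("GM", 5), rep("WM", 3), rep("GM", 2)),
    width = 1536, height = 1536, radius = 32, seed = 21)
  sl <- render_slide(spec)
  res <- quantify_slide(sl$slide)
  expect_equal(as.integer(res$counts), c(5L, 0L, 2L, 0L, 3L, 0L))
  expect_equal(as.integer(res$counts),
               as.integer(sl$truth$expected_counts))

  # additivity: two disjoint slides' blob lists add componentwise
  spec2 <- spec_with_deposits("diffuse", "GM", width = 512, height = 512,
                              seed = 22)
  res2 <- quantify_slide(render_slide(spec2)$slide)
  merged <- count_deposits(c(res$blobs_by_class, res2$blobs_by_class))
  expect_equal(as.integer(merged),
               as.integer(res$counts) + as.integer(res2$counts))

  expect_equal(as.integer(count_deposits(list())), rep(0L, 6))
})

test_that("patch-vote counting counts cells, not objects", {
  spec <- spec_with_deposits("cored", "GM", width = 768, height = 768,
                             radius = 40, seed = 6)
  sl <- render_slide(spec)
  res <- quantify_slide(sl$slide)
  d <- spec$deposits[1, ]
  nr <- res$heatmaps$cored$geometry$n_rows
  nc <- res$heatmaps$cored$geometry$n_cols
  inside <- outer(((seq_len(nr) - 1) * 16 + 8 - d$y)^2,
                  ((seq_len(nc) - 1) * 16 + 8 - d$x)^2, "+") <= d$radius_px^2
  expect_equal(res$counts_patchvote[["gm_cored"]], sum(inside))
  expect_equal(res$counts[["gm_cored"]], 1L)
  expect_equal(attr(res$counts_patchvote, "mode_label"), "patchvote")

  # lowering a threshold never decreases that class's patch-vote count
  thresholds <- c(cored = 0.9, diffuse = 0.9, CAA = 0.9)
  base <- patchvote_count(res$heatmaps, res$region_map, thresholds)
  lower <- patchvote_count(res$heatmaps, res$region_map,
                           c(cored = 0.3, diffuse = 0.9, CAA = 0.9))
  expect_gte(lower[["gm_cored"]] + lower[["wm_cored"]],
             base[["gm_cored"]] + base[["wm_cored"]])

  # empty heatmaps give the zero vector
  empty <- res$heatmaps
  for (cls in names(empty)) empty[[cls]]$values[] <- 0
  expect_equal(as.integer(patchvote_count(empty, res$region_map)), rep(0L, 6))
})

test_that("region areas follow the cell-footprint arithmetic", {
  labels <- matrix(0L, 40, 40)
  labels[seq_len(1000)] <- 1L
  areas <- region_areas(as_region_map(labels, stride = 16, mpp = 0.503))
  expect_equal(unname(areas["GM"]), 1000 * (16 * 0.503)^2)
  expect_equal(unname(areas["GM"]), 64770.304)
  expect_equal(unname(areas["WM"]), 0)

  empty <- as_region_map(matrix(0L, 10, 10))
  expect_equal(unname(region_areas(empty)), c(0, 0))

  # stride refinement leaves the physical area invariant within one
  # boundary row of cells
  spec <- synthetic_slide_spec(1024, 1024, seed = 2)
  sl <- render_slide(spec)$slide
  a16 <- region_areas(infer_region_map(sl, oracle_classifier_g(), 16))
  a8 <- region_areas(infer_region_map(sl, oracle_classifier_g(), 8))
  boundary_cells <- 2 * (1024 / 16) * (16 * 0.503)^2
  expect_lt(abs(a16[["GM"]] - a8[["GM"]]), boundary_cells)

  # missing mpp is an error
  rmx <- as_region_map(labels)
  rmx$geometry$slide_mpp <- NA_real_
  expect_error(region_areas(rmx), "micron")
})

test_that("density tables divide counts by areas with missing/error edge cases", {
  counts <- count_vector(c(5L, 0L, 0L, 0L, 0L, 0L))
  areas <- c(GM = 64770.304, WM = 10000)
  dt <- compute_densities(counts, areas, "s1")
  gm_cored <- dt[dt$region == "GM" & dt$deposit_class == "cored", ]
  expect_equal(gm_cored$density_per_um2, 5 / 64770.304, tolerance = 1e-12)
  expect_equal(dt$density_per_um2[dt$count == 0 & dt$area_um2 > 0],
               rep(0, 5))

  # doubling count and area leaves density unchanged
  dt2 <- compute_densities(count_vector(c(10L, 0L, 0L, 0L, 0L, 0L)),
                           areas * 2, "s1")
  expect_equal(dt2$density_per_um2[1], dt$density_per_um2[1])

  # zero area: missing when count 0, error when count positive
  dt3 <- compute_densities(counts, c(GM = 64770.304, WM = 0))
  expect_true(all(is.na(dt3$density_per_um2[dt3$region == "WM"])))
  expect_error(compute_densities(count_vector(c(0L, 0L, 0L, 1L, 0L, 0L)),
                                 c(GM = 1, WM = 0)),
               "zero-area")

  # densities scale as 1/area under a declared mpp change
  half_mpp_areas <- c(GM = 64770.304 / 4, WM = 2500)
  dt4 <- compute_densities(counts, half_mpp_areas)
  expect_equal(dt4$density_per_um2[1], 4 * dt$density_per_um2[1])
})
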