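#' Quantify one slide end to end
#'
#' The per-slide flow: sliding-window inference of the three deposit
#' heatmaps and the GM/WM region map on a shared grid, per-class
#' thresholding, cleaning, blob labeling, region attribution, the 1x6
#' count vector in both counting modes, region areas, and densities.
#'
#' @param slide a [slide_raster()] at the working resolution (normalize
#'   first with [reinhard_normalize()] when using stain-sensitive
#'   classifiers).
#' @param config a [pipeline_config()].
#' @param classifier_f,classifier_g optional [patch_classifier()]s;
#'   defaults are looked up from the registry names in `config`.
#' @return List: `counts` (blob mode), `counts_patchvote`, `densities`
#'   (both modes stacked), `blobs_by_class`, `heatmaps`, `region_map`,
#'   `areas`.
#' @export
quantify_slide <- function(slide, config = pipeline_config(),
                           classifier_f = NULL, classifier_g = NULL) {
  stopifnot(inherits(slide, "slide_raster"))
  validate_config(config)
  if (is.null(classifier_f)) classifier_f <- get_classifier(config$classifier_f)
  if (is.null(classifier_g)) classifier_g <- get_classifier(config$classifier_g)
  slide <- harmonize_resolution(slide, config$target_mpp)
  heatmaps <- sliding_window_infer(slide, classifier_f,
                                   stride_px = config$stride_px)
  regions <- infer_region_map(slide, classifier_g,
                              stride_px = config$stride_px)
  blobs_by_class <- lapply(DEPOSIT_CLASSES, function(cls) {
    mask <- threshold_heatmap(heatmaps[[cls]], config$thresholds[[cls]])
    mask <- clean_mask(mask, config$min_blob_cells, config$connectivity)
    assign_region(label_blobs(mask, config$connectivity), regions)
  })
  names(blobs_by_class) <- DEPOSIT_CLASSES
  counts <- count_deposits(blobs_by_class)
  counts_pv <- patchvote_count(heatmaps, regions, config$thresholds)
  areas <- region_areas(regions)
  densities <- rbind(compute_densities(counts, areas, slide$slide_id),
                     compute_densities(counts_pv, areas, slide$slide_id))
  list(counts = counts, counts_patchvote = counts_pv, densities = densities,
       blobs_by_class = blobs_by_class, heatmaps = heatmaps,
       region_map = regions, areas = areas)
}

#' Simulate a batch of synthetic slides plus a synthetic cohort
#'
#' Writes, per slide, a PNG raster with a JSON sidecar carrying the
#' microns-per-pixel tag and the full ground truth (placements, expected
#' counts, and the slide spec needed to regenerate the region mask), and
#' one cohort CSV. Deterministic given the seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param n_slides number of slides.
#' @param slide_px slide edge length(s), recycled over slides.
#' @param deposits_per_slide deposit count(s), recycled over slides.
#' @param cohort_spec optional [cohort_sim_spec()]; when supplied the
#'   simulated cohort table is written as `cohort.csv`.
#' @return Invisible list with `slide_paths` and `cohort_path`.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir,
                         n_slides = 4L, slide_px = 1024L,
                         deposits_per_slide = 8L, cohort_spec = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slide_px <- rep_len(slide_px, n_slides)
  deposits_per_slide <- rep_len(deposits_per_slide, n_slides)
  paths <- character(n_slides)
  for (i in seq_len(n_slides)) {
    seed_i <- config$seed + i
    spec <- random_slide_spec(slide_px[i], slide_px[i],
                              deposits_per_slide[i], seed = seed_i,
                              microns_per_pixel = config$target_mpp)
    sl <- render_slide(spec, slide_id = sprintf("sim_%03d", i))
    message(sprintf("simulate: slide %s (%d px, %d deposits)",
                    sl$slide$slide_id, slide_px[i], deposits_per_slide[i]))
    gt <- list(
      placements = sl$truth$placements,
      expected_counts = as.list(sl$truth$expected_counts),
      spec = list(width_px = spec$width_px, height_px = spec$height_px,
                  gm_fraction = spec$gm_fraction, layout = spec$layout,
                  noise_sd = spec$noise_sd, seed = spec$seed),
      provenance = provenance_block(config))
    paths[i] <- file.path(out_dir, sprintf("sim_%03d.png", i))
    write_slide(sl$slide, paths[i], extra = list(ground_truth = gt))
  }
  cohort_path <- NULL
  if (!is.null(cohort_spec)) {
    cohort <- simulate_cohort(cohort_spec)
    cohort_path <- file.path(out_dir, "cohort.csv")
    write.csv(cohort, cohort_path, row.names = FALSE)
    message("simulate: cohort with ", nrow(cohort), " cases -> ", cohort_path)
  }
  invisible(list(slide_paths = paths, cohort_path = cohort_path))
}

# rebuild the ground truth stored in a slide sidecar
read_ground_truth <- function(slide_path) {
  meta <- jsonlite::read_json(paste0(slide_path, ".json"),
                              simplifyVector = TRUE)
  gt <- meta$ground_truth
  if (is.null(gt)) return(NULL)
  counts <- setNames(as.integer(unlist(gt$expected_counts)[COUNT_SLOTS]),
                     COUNT_SLOTS)
  placements <- gt$placements
  if (is.null(placements) || !length(placements)) {
    placements <- deposit_placements()
  }
  list(placements = placements, expected_counts = counts, spec = gt$spec)
}

#' Quantify a batch of slides
#'
#' Runs [quantify_slide()] over each readable slide and appends one
#' density row per slide, class, region, and counting mode to
#' `densities.csv`; blob inventories go to `blobs.csv` and overlays are
#' written per class. Unreadable slides are skipped with a logged error
#' and reflected in the returned `n_failed`.
#'
#' @param config a [pipeline_config()].
#' @param slide_paths character vector of PNG paths written by
#'   [cmd_simulate()] or [write_slide()].
#' @param out_dir output directory.
#' @param overlays write per-class overlay PNGs.
#' @return Invisible list with `densities`, `blobs`, `n_failed`.
#' @export
cmd_quantify <- function(config = pipeline_config(), slide_paths, out_dir,
                         overlays = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_dens <- list(); all_blobs <- list(); n_failed <- 0L
  for (path in slide_paths) {
    slide <- tryCatch(read_slide(path), error = function(e) {
      message("quantify: SKIP unreadable slide ", path, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(slide)) { n_failed <- n_failed + 1L; next }
    message(sprintf("quantify: %s (%d x %d px, stride %d, thresholds %s)",
                    slide$slide_id, dim(slide$pixels)[2],
                    dim(slide$pixels)[1], config$stride_px,
                    paste(config$thresholds, collapse = "/")))
    res <- quantify_slide(slide, config)
    all_dens[[length(all_dens) + 1]] <- res$densities
    blobs <- do.call(rbind, lapply(res$blobs_by_class, `[[`, "blobs"))
    if (nrow(blobs)) {
      blobs <- cbind(slide_id = slide$slide_id, blobs)
      all_blobs[[length(all_blobs) + 1]] <- blobs
    }
    if (overlays)
      write_overlays(res$region_map, res$blobs_by_class, out_dir,
                     slide_id = slide$slide_id)
  }
  dens <- if (length(all_dens)) do.call(rbind, all_dens) else
    compute_densities(count_vector(), c(GM = 1, WM = 1))[0, ]
  blobs <- if (length(all_blobs)) do.call(rbind, all_blobs) else NULL
  write.csv(dens, file.path(out_dir, "densities.csv"), row.names = FALSE)
  if (!is.null(blobs))
    write.csv(blobs, file.path(out_dir, "blobs.csv"), row.names = FALSE)
  jsonlite::write_json(provenance_block(config),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (n_failed) message("quantify: ", n_failed, " slide(s) failed")
  invisible(list(densities = dens, blobs = blobs, n_failed = n_failed))
}

#' Run the statistics battery on a cohort CSV
#'
#' @param config a [pipeline_config()].
#' @param cohort_csv path to a cohort table (one row per case).
#' @param grouping grouping column name.
#' @param outcomes outcome column names; default: all `density_*`
#'   columns.
#' @param out_dir output directory for the results CSV and report.
#' @param exclude_levels group labels excluded before testing (e.g. a
#'   deferred most-recent-assessment).
#' @return Invisible [run_analysis_battery()] result.
#' @export
cmd_stats <- function(config = pipeline_config(), cohort_csv, grouping,
                      outcomes = NULL, out_dir,
                      exclude_levels = character()) {
  cohort <- read.csv(cohort_csv, stringsAsFactors = FALSE)
  if (!grouping %in% names(cohort))
    stop("cohort CSV has no grouping column '", grouping, "'; columns: ",
         paste(names(cohort), collapse = ", "))
  if (is.null(outcomes))
    outcomes <- grep("^density_", names(cohort), value = TRUE)
  missing_out <- setdiff(outcomes, names(cohort))
  if (length(missing_out))
    stop("cohort CSV is missing outcome column(s): ",
         paste(missing_out, collapse = ", "))
  battery <- run_analysis_battery(cohort, grouping, outcomes,
                                  exclude_levels = exclude_levels)
  write_battery_report(battery, out_dir)
  jsonlite::write_json(provenance_block(config),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(battery)
}
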