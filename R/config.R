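#' Pipeline configuration
#'
#' All stage parameters in one validated object. Defaults follow the
#' workflow's published operating point: working resolution 0.503
#' micron/pixel (20x), 1536-pixel tiles, 256-pixel patches, stride 16.
#' Per-class thresholds and the blob-size floor govern mask cleaning;
#' defaults keep every class at 0.9 with a 2-cell minimum.
#'
#' @param target_mpp working resolution in micron/pixel.
#' @param tile_size_px tile edge length.
#' @param patch_size_px classifier patch edge length.
#' @param stride_px sliding-window stride; must divide `patch_size_px`.
#' @param thresholds named per-class detection thresholds in (0, 1].
#' @param min_blob_cells minimum surviving component size.
#' @param connectivity blob connectivity, 4 or 8.
#' @param counting_mode `"blob"` (objects, default) or `"patchvote"`
#'   (cell votes); [cmd_quantify()] reports both.
#' @param classifier_f,classifier_g registry names of the two
#'   classifiers.
#' @param seed base seed for any stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_mpp = 0.503, tile_size_px = 1536L,
                            patch_size_px = 256L, stride_px = 16L,
                            thresholds = c(cored = 0.9, diffuse = 0.9,
                                           CAA = 0.9),
                            min_blob_cells = 2L, connectivity = 8L,
                            counting_mode = c("blob", "patchvote"),
                            classifier_f = "oracle_f",
                            classifier_g = "oracle_g",
                            seed = 1L) {
  counting_mode <- match.arg(counting_mode)
  cfg <- list(target_mpp = target_mpp, tile_size_px = as.integer(tile_size_px),
              patch_size_px = as.integer(patch_size_px),
              stride_px = as.integer(stride_px),
              thresholds = thresholds,
              min_blob_cells = as.integer(min_blob_cells),
              connectivity = as.integer(connectivity),
              counting_mode = counting_mode,
              classifier_f = classifier_f, classifier_g = classifier_g,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$target_mpp <= 0) stop("target_mpp must be positive")
  if (cfg$patch_size_px %% cfg$stride_px != 0)
    stop("stride_px must divide patch_size_px")
  if (!all(DEPOSIT_CLASSES %in% names(cfg$thresholds)))
    stop("thresholds must name cored, diffuse, CAA")
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  if (!cfg$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (cfg$min_blob_cells < 1) stop("min_blob_cells must be >= 1")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read/write pipeline configuration as YAML
#'
#' The round trip is lossless for every field.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- as.list(x$thresholds)  # keep names in the YAML mapping
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$thresholds <- unlist(raw$thresholds)
  do.call(pipeline_config, raw)
}

# provenance block stamped into outputs: identical provenance implies
# identical outputs
provenance_block <- function(config) {
  list(package = "abquant",
       version = as.character(utils::packageVersion("abquant")),
       seed = config$seed,
       config = unclass(config))
}
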