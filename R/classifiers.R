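#' Patch classifier contract
#'
#' The only coupling between the inference engine and a model. A
#' classifier evaluates a batch of fixed-size RGB patches and returns one
#' confidence vector per patch, each value in \[0, 1\]; results must be
#' deterministic and independent of batching. A classifier may optionally
#' provide `pixel_fn`, a vectorized map from patch-center RGB values to
#' the same confidences, declared exactly equivalent to `predict_patches`;
#' the engine uses it as a fast path when present (the equivalence is part
#' of the contract and is exercised by the test suite for the oracles).
#'
#' @param name registry name.
#' @param channels character vector naming the output channels.
#' @param predict_patches function(list of `size x size x 3` arrays) ->
#'   numeric matrix `n x length(channels)`.
#' @param patch_size_px patch edge length in pixels.
#' @param pixel_fn optional function(`n x 3` RGB matrix) -> `n x k` matrix.
#' @return An object of class `patch_classifier`.
#' @export
patch_classifier <- function(name, channels, predict_patches,
                             patch_size_px = 256L, pixel_fn = NULL) {
  stopifnot(is.function(predict_patches), length(channels) >= 1)
  structure(list(name = name, channels = channels,
                 patch_size_px = as.integer(patch_size_px),
                 predict_patches = predict_patches, pixel_fn = pixel_fn),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("<patch_classifier '%s'> %d px patches -> [%s]%s\n",
              x$name, x$patch_size_px, paste(x$channels, collapse = ", "),
              if (is.null(x$pixel_fn)) "" else " (+pixel fast path)"))
  invisible(x)
}

# nearest-palette decoding shared by both oracles. Returns the palette row
# name per pixel, or "unknown" when no entry is within max_dist (arbitrary
# RGB input is accepted; unknown colors yield background/zero outputs).
decode_palette <- function(rgbmat, palette = ab_palette(), max_dist = 24) {
  n <- nrow(rgbmat)
  best <- rep(Inf, n)
  hit <- integer(n)
  for (k in seq_len(nrow(palette))) {
    d2 <- (rgbmat[, 1] - palette[k, 1])^2 +
          (rgbmat[, 2] - palette[k, 2])^2 +
          (rgbmat[, 3] - palette[k, 3])^2
    better <- d2 < best
    best[better] <- d2[better]
    hit[better] <- k
  }
  out <- rownames(palette)[hit]
  out[best > max_dist^2] <- "unknown"
  out
}

# palette row name -> deposit class one-hot (cored, diffuse, CAA)
palette_to_f <- function(names) {
  m <- matrix(0, length(names), 3,
              dimnames = list(NULL, DEPOSIT_CLASSES))
  m[grepl("^(cored|core)_", names), "cored"] <- 1
  m[grepl("^diffuse_", names), "diffuse"] <- 1
  m[grepl("^(caa|lumen)_", names), "CAA"] <- 1
  m
}

# palette row name -> region one-hot (GM, WM, background)
palette_to_g <- function(names) {
  m <- matrix(0, length(names), 3,
              dimnames = list(NULL, c("GM", "WM", "background")))
  gm <- names == "gm" | grepl("_gm$", names)
  wm <- names == "wm" | grepl("_wm$", names)
  m[gm, "GM"] <- 1
  m[wm, "WM"] <- 1
  m[!gm & !wm, "background"] <- 1
  m
}

patch_centers_rgb <- function(patches) {
  t(vapply(patches, function(p) {
    ctr <- floor(dim(p)[1] / 2) + 1L   # 0-based center size/2
    as.numeric(p[ctr, ctr, ])
  }, numeric(3)))
}

#' Oracle deposit classifier f
#'
#' Deterministic stand-in for a trained deposit CNN: returns confidence
#' 1.0 for class c exactly when the patch's center pixel lies inside a
#' class-c deposit footprint rendered by [render_slide()] (decoded from
#' the generator palette), else 0.0. Unknown colors give all zeros.
#'
#' @param palette generator palette, see [ab_palette()].
#' @return A [patch_classifier()] with channels cored, diffuse, CAA.
#' @export
oracle_classifier_f <- function(palette = ab_palette()) {
  pixel_fn <- function(rgbmat) palette_to_f(decode_palette(rgbmat, palette))
  patch_classifier(
    name = "oracle_f", channels = DEPOSIT_CLASSES,
    predict_patches = function(patches) pixel_fn(patch_centers_rgb(patches)),
    pixel_fn = pixel_fn)
}

#' Oracle region classifier g
#'
#' Deterministic stand-in for a GM/WM segmentation CNN: one-hot
#' probabilities over (GM, WM, background) keyed to the region label of
#' the patch's center pixel; deposit colors decode to the region they were
#' rendered in.
#'
#' @param palette generator palette, see [ab_palette()].
#' @return A [patch_classifier()] with channels GM, WM, background.
#' @export
oracle_classifier_g <- function(palette = ab_palette()) {
  pixel_fn <- function(rgbmat) palette_to_g(decode_palette(rgbmat, palette))
  patch_classifier(
    name = "oracle_g", channels = c("GM", "WM", "background"),
    predict_patches = function(patches) pixel_fn(patch_centers_rgb(patches)),
    pixel_fn = pixel_fn)
}

.classifier_registry <- new.env(parent = emptyenv())

#' Classifier registry
#'
#' Plug-in point for the pipeline configuration: classifiers are looked up
#' by name, so an adapter around a trained model can be registered without
#' changing any pipeline code.
#'
#' @param name registry key.
#' @param constructor zero-argument function returning a
#'   [patch_classifier()].
#' @return `register_classifier` returns the name invisibly;
#'   `get_classifier` returns the constructed classifier.
#' @export
register_classifier <- function(name, constructor) {
  stopifnot(is.function(constructor))
  assign(name, constructor, envir = .classifier_registry)
  invisible(name)
}

#' @rdname register_classifier
#' @export
get_classifier <- function(name) {
  if (!exists(name, envir = .classifier_registry))
    stop("unknown classifier '", name, "'; registered: ",
         paste(ls(.classifier_registry), collapse = ", "))
  get(name, envir = .classifier_registry)()
}

register_builtin_classifiers <- function() {
  register_classifier("oracle_f", oracle_classifier_f)
  register_classifier("oracle_g", oracle_classifier_g)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_classifiers()
}
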