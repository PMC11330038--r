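#' Generator color palette
#'
#' Colors used by the synthetic slide renderer. Each deposit signature
#' (cored rim, cored core, diffuse, CAA ring, CAA lumen) has a GM and a WM
#' variant so that both the deposit class and the underlying region can be
#' decoded from a single pixel. The minimum pairwise distance between any
#' two palette entries is ~49 RGB units; with the default pixel noise
#' (sd 2.5) nearest-color decoding is effectively error-free.
#'
#' @return A 13 x 3 integer matrix of RGB rows with informative rownames.
#' @export
ab_palette <- function() {
  rbind(
    background = c(245, 245, 243),
    gm         = c(198, 150, 140),
    wm         = c(240, 225, 185),
    cored_gm   = c( 70,  35,  10),
    core_gm    = c( 20,  10,   5),
    diffuse_gm = c(160, 120,  35),
    caa_gm     = c(135,  40,  70),
    lumen_gm   = c(235, 180, 150),
    cored_wm   = c(130,  80,  40),
    core_wm    = c( 60,  50,  70),
    diffuse_wm = c(205, 170,  90),
    caa_wm     = c(190,  95, 120),
    lumen_wm   = c(255, 215, 120)
  )
}

DEPOSIT_CLASSES <- c("cored", "diffuse", "CAA")
REGION_LEVELS <- c("GM", "WM")
# slot order of the 1x6 count vector: GM then WM, cored/diffuse/CAA within
COUNT_SLOTS <- c("gm_cored", "gm_diffuse", "gm_caa",
                 "wm_cored", "wm_diffuse", "wm_caa")

# fraction of the disc radius occupied by the dense core of a cored plaque
# and by the lumen of a CAA ring
CORE_FRACTION  <- 0.35
LUMEN_FRACTION <- 0.55

#' Deposit placement list
#'
#' @param deposit_class character vector in `c("cored","diffuse","CAA")`.
#' @param x,y deposit center, 0-based slide pixel coordinates.
#' @param radius_px footprint radius in pixels (>= 4).
#' @param region intended region, `"GM"` or `"WM"`.
#' @return A `data.frame` with one row per placement.
#' @export
deposit_placements <- function(deposit_class = character(), x = numeric(),
                               y = numeric(), radius_px = numeric(),
                               region = character()) {
  df <- data.frame(deposit_class = as.character(deposit_class),
                   x = as.numeric(x), y = as.numeric(y),
                   radius_px = as.numeric(radius_px),
                   region = as.character(region),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$deposit_class %in% DEPOSIT_CLASSES))
      stop("deposit_class must be one of: ",
           paste(DEPOSIT_CLASSES, collapse = ", "))
    if (!all(df$region %in% REGION_LEVELS))
      stop("region must be GM or WM")
    if (any(df$radius_px < 4))
      stop("radius_px must be >= 4")
  }
  df
}

#' Specification of a synthetic slide
#'
#' Describes a DAB-like section: an elliptical tissue mask split into GM
#' and WM zones, populated with disjoint deposit footprints. The seed
#' fully determines the rendered raster.
#'
#' @param width_px,height_px raster dimensions (>= 512).
#' @param microns_per_pixel physical resolution; default matches a 20x
#'   scan at 0.503 micron/pixel.
#' @param gm_fraction fraction of the tissue area assigned to GM, in (0,1).
#' @param layout `"radial"` (outer GM band around a WM core, mimicking the
#'   cortical ribbon) or `"vertical"` (left GM / right WM split).
#' @param deposits a [deposit_placements()] data frame.
#' @param noise_sd per-channel Gaussian pixel noise, gray levels.
#' @param palette 13 x 3 RGB matrix, see [ab_palette()].
#' @param seed integer; fully determines the raster.
#' @return An object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(width_px, height_px,
                                 microns_per_pixel = 0.503,
                                 gm_fraction = 0.6,
                                 layout = c("radial", "vertical"),
                                 deposits = deposit_placements(),
                                 noise_sd = 2.5,
                                 palette = ab_palette(),
                                 seed = 1L) {
  layout <- match.arg(layout)
  if (width_px < 512 || height_px < 512)
    stop("width_px and height_px must be >= 512")
  if (gm_fraction <= 0 || gm_fraction >= 1)
    stop("gm_fraction must be in (0, 1)")
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be positive")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         microns_per_pixel = microns_per_pixel, gm_fraction = gm_fraction,
         layout = layout, deposits = deposits, noise_sd = noise_sd,
         palette = palette, seed = as.integer(seed)),
    class = "synthetic_slide_spec")
}

# evaluate an expression under a fixed seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# region mask for the spec's tissue geometry: integer H x W matrix with
# 0 = background, 1 = GM, 2 = WM.  Ellipse semi-axes are 0.46 of each
# dimension so tissue keeps a clear margin from the slide edge.
region_mask_for <- function(width_px, height_px, gm_fraction, layout) {
  W <- width_px; H <- height_px
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  a <- 0.46 * W; b <- 0.46 * H
  xs2 <- ((seq_len(W) - 1 - cx) / a)^2
  ys2 <- ((seq_len(H) - 1 - cy) / b)^2
  rho2 <- outer(ys2, xs2, "+")
  mask <- matrix(0L, H, W)
  tissue <- rho2 <= 1
  if (layout == "radial") {
    # outer elliptical band of area fraction gm_fraction is GM
    inner <- rho2 <= (1 - gm_fraction)
    mask[tissue] <- 1L
    mask[inner] <- 2L
  } else {
    # vertical split: leftmost columns holding gm_fraction of tissue
    per_col <- colSums(tissue)
    cum <- cumsum(per_col) / sum(per_col)
    cut_col <- which(cum >= gm_fraction)[1]
    mask[tissue] <- 2L
    left <- tissue
    left[, seq_len(W) > cut_col] <- FALSE
    mask[left] <- 1L
  }
  mask
}

# local footprint check: TRUE iff every pixel with distance <= r of
# (x, y) lies inside the slide and carries the given region code
footprint_in_region <- function(regmask, x, y, r, code) {
  H <- nrow(regmask); W <- ncol(regmask)
  r_ceil <- ceiling(r)
  if (x - r_ceil < 0 || y - r_ceil < 0 ||
      x + r_ceil > W - 1 || y + r_ceil > H - 1) return(FALSE)
  cols <- (floor(x) - r_ceil):(ceiling(x) + r_ceil) + 1L
  rows <- (floor(y) - r_ceil):(ceiling(y) + r_ceil) + 1L
  sub <- regmask[rows, cols, drop = FALSE]
  dx <- (cols - 1) - x; dy <- (rows - 1) - y
  inside <- outer(dy^2, dx^2, "+") <= r^2
  all(sub[inside] == code)
}

#' Render a synthetic slide with ground truth
#'
#' Visual signatures: cored plaques are dense dark discs with a darker
#' core, diffuse plaques are low-contrast mottled discs, CAA is a ring
#' with a pale lumen wash; every signature has distinct GM and WM color
#' variants (see [ab_palette()]). Identical spec (including seed) yields a
#' bit-identical raster.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param slide_id identifier for the output raster.
#' @return A list with elements `slide` (a [slide_raster()]) and `truth`
#'   (list: `placements`, `region_mask`, `expected_counts`).
#' @export
render_slide <- function(spec, slide_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H <- spec$height_px; W <- spec$width_px
  pal <- spec$palette
  regmask <- region_mask_for(W, H, spec$gm_fraction, spec$layout)
  dep <- spec$deposits

  # validate placements: footprint inside its intended region, pairwise
  # separation >= 2 (r_i + r_j)
  if (nrow(dep)) {
    codes_by_region <- c(GM = 1L, WM = 2L)
    for (i in seq_len(nrow(dep))) {
      if (!footprint_in_region(regmask, dep$x[i], dep$y[i], dep$radius_px[i],
                               codes_by_region[[dep$region[i]]]))
        stop(sprintf(
          "placement %d (%s, r=%g at x=%g y=%g) is not fully inside its intended %s region",
          i, dep$deposit_class[i], dep$radius_px[i], dep$x[i], dep$y[i],
          dep$region[i]))
    }
    if (nrow(dep) > 1) {
      for (i in seq_len(nrow(dep) - 1)) for (j in (i + 1):nrow(dep)) {
        d <- sqrt((dep$x[i] - dep$x[j])^2 + (dep$y[i] - dep$y[j])^2)
        if (d < 2 * (dep$radius_px[i] + dep$radius_px[j]))
          stop(sprintf("placements %d and %d violate the minimum separation rule",
                       i, j))
      }
    }
  }

  # palette code raster: start from the region coloring, then paint
  # deposits locally
  codes <- regmask + 1L   # 1 background, 2 GM, 3 WM
  code_of <- function(name) which(rownames(pal) == name)
  for (i in seq_len(nrow(dep))) {
    x <- dep$x[i]; y <- dep$y[i]; r <- dep$radius_px[i]
    suffix <- if (dep$region[i] == "GM") "_gm" else "_wm"
    r_ceil <- ceiling(r)
    cols <- (floor(x) - r_ceil):(ceiling(x) + r_ceil) + 1L
    rows <- (floor(y) - r_ceil):(ceiling(y) + r_ceil) + 1L
    dx <- (cols - 1) - x; dy <- (rows - 1) - y
    rr <- outer(dy^2, dx^2, "+")
    sub <- codes[rows, cols]
    cls <- dep$deposit_class[i]
    if (cls == "cored") {
      sub[rr <= r^2] <- code_of(paste0("cored", suffix))
      sub[rr <= (CORE_FRACTION * r)^2] <- code_of(paste0("core", suffix))
    } else if (cls == "diffuse") {
      sub[rr <= r^2] <- code_of(paste0("diffuse", suffix))
    } else {
      sub[rr <= r^2] <- code_of(paste0("caa", suffix))
      sub[rr <= (LUMEN_FRACTION * r)^2] <- code_of(paste0("lumen", suffix))
    }
    codes[rows, cols] <- sub
  }

  # deterministic mottle on diffuse pixels (low-contrast texture)
  diffuse_idx <- which(codes == code_of("diffuse_gm") |
                       codes == code_of("diffuse_wm"))
  mottle <- NULL
  if (length(diffuse_idx)) {
    rc <- arrayInd(diffuse_idx, c(H, W))
    mottle <- as.integer(
      round(6 * sin(2 * pi * rc[, 2] / 11) * cos(2 * pi * rc[, 1] / 13)))
  }

  # achromatic (shared-channel) Gaussian noise: cheap, seed-determined,
  # and shifts colors along (1,1,1) so palette decoding margins are
  # unaffected
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed,
              as.integer(round(rnorm(H * W, sd = spec$noise_sd))))
  else integer(H * W)
  px <- array(0L, c(H, W, 3L))
  for (ch in 1:3) {
    palv <- as.integer(pal[, ch])
    v <- palv[codes] + noise
    if (length(diffuse_idx)) v[diffuse_idx] <- v[diffuse_idx] + mottle
    px[, , ch] <- pmin.int(pmax.int(v, 0L), 255L)
  }

  truth <- list(placements = dep,
                region_mask = regmask,
                expected_counts = expected_counts(dep))
  list(slide = slide_raster(px, spec$microns_per_pixel, slide_id),
       truth = truth)
}

#' Tally placements into the 1x6 ground-truth count vector
#'
#' @param placements a [deposit_placements()] data frame.
#' @return Named integer vector over the six (region, class) slots.
#' @export
expected_counts <- function(placements) {
  out <- setNames(integer(6), COUNT_SLOTS)
  if (nrow(placements)) {
    slot <- paste0(tolower(placements$region), "_",
                   tolower(placements$deposit_class))
    tab <- table(factor(slot, levels = COUNT_SLOTS))
    out[] <- as.integer(tab)
  }
  out
}

#' Randomized synthetic slide specification
#'
#' Dart-throwing placement of disjoint deposits: each deposit's footprint
#' lies strictly inside its intended region and centers respect the
#' minimum separation of twice the summed radii. Default radii (28-44 px
#' for plaques, 48-72 px for CAA, at 0.503 micron/px and stride 16)
#' guarantee each footprint covers at least four heatmap-cell centers, so
#' blob counting can recover the ground truth exactly.
#'
#' @param width_px,height_px slide dimensions.
#' @param n_deposits number of deposits to place.
#' @param seed integer seed; determines placements and rendering noise.
#' @param gm_fraction,layout,microns_per_pixel see [synthetic_slide_spec()].
#' @param class_probs sampling weights for (cored, diffuse, CAA).
#' @param p_gm probability a deposit is placed in GM (deposits predominate
#'   in gray matter on real sections).
#' @param max_tries rejection-sampling budget per deposit.
#' @return A [synthetic_slide_spec()].
#' @export
random_slide_spec <- function(width_px, height_px, n_deposits, seed = 1L,
                              gm_fraction = 0.6,
                              layout = c("radial", "vertical"),
                              microns_per_pixel = 0.503,
                              class_probs = c(cored = 0.35, diffuse = 0.5,
                                              CAA = 0.15),
                              p_gm = 0.7, max_tries = 4000L) {
  layout <- match.arg(layout)
  regmask <- region_mask_for(width_px, height_px, gm_fraction, layout)
  codes_by_region <- c(GM = 1L, WM = 2L)
  with_seed(seed, {
    cls <- sample(DEPOSIT_CLASSES, n_deposits, replace = TRUE,
                  prob = class_probs[DEPOSIT_CLASSES])
    placed <- deposit_placements()
    for (i in seq_len(n_deposits)) {
      r <- if (cls[i] == "CAA") runif(1, 48, 72) else runif(1, 28, 44)
      region <- if (runif(1) < p_gm) "GM" else "WM"
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, r + 1, width_px - r - 2)
        y <- runif(1, r + 1, height_px - r - 2)
        if (!footprint_in_region(regmask, x, y, r, codes_by_region[[region]]))
          next
        if (nrow(placed) &&
            any(sqrt((placed$x - x)^2 + (placed$y - y)^2) <
                2 * (placed$radius_px + r))) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("could not place deposit %d of %d after %d tries; reduce n_deposits or radii",
                     i, n_deposits, max_tries))
      placed <- rbind(placed,
                      deposit_placements(cls[i], x, y, r, region))
    }
    synthetic_slide_spec(width_px, height_px,
                         microns_per_pixel = microns_per_pixel,
                         gm_fraction = gm_fraction, layout = layout,
                         deposits = placed, seed = seed)
  })
}
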