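# Independent oracles and fixture builders shared across the suite.

# Brute-force flood-fill labeling (BFS with an explicit stack), the
# reference for connected-component tests. Label order matches reading
# order of each component's first cell.
flood_fill_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  nxt <- 0L
  stack_r <- integer(H * W); stack_c <- integer(H * W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || lab[r, c] > 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack_r[1] <- r; stack_c[1] <- c
    lab[r, c] <- nxt
    while (top > 0L) {
      cr <- stack_r[top]; cc <- stack_c[top]; top <- top - 1L
      for (k in seq_along(dr)) {
        rr <- cr + dr[k]; ccc <- cc + dc[k]
        if (rr >= 1L && rr <= H && ccc >= 1L && ccc <= W &&
            mask[rr, ccc] && lab[rr, ccc] == 0L) {
          lab[rr, ccc] <- nxt
          top <- top + 1L
          stack_r[top] <- rr; stack_c[top] <- ccc
        }
      }
    }
  }
  lab
}

# Brute-force sliding-window inference: evaluates the classifier on every
# cell's patch independently, one patch per call.
brute_force_infer <- function(slide, classifier, stride) {
  d <- dim(slide$pixels)
  nr <- ceiling(d[1] / stride); nc <- ceiling(d[2] / stride)
  k <- length(classifier$channels)
  arrs <- lapply(seq_len(k), function(i) matrix(0, nr, nc))
  half <- stride %/% 2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cy <- abquant:::reflect_index((i - 1) * stride + half, d[1])
    cx <- abquant:::reflect_index((j - 1) * stride + half, d[2])
    p <- extract_patch(slide, cx, cy, classifier$patch_size_px)
    out <- classifier$predict_patches(list(p))
    for (ch in seq_len(k)) arrs[[ch]][i, j] <- out[1, ch]
  }
  names(arrs) <- classifier$channels
  arrs
}

# uniform-color slide
uniform_slide <- function(color, h = 512, w = 512, mpp = 0.503,
                          slide_id = "uniform") {
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(color[ch])
  slide_raster(px, mpp, slide_id)
}

# slide spec with prescribed deposit classes/regions at feasible
# positions (rejection sampling on the analytic region mask)
spec_with_deposits <- function(classes, regions, width = 1024, height = 1024,
                               radius = 30, seed = 1, layout = "vertical",
                               gm_fraction = 0.6, noise_sd = 2.5) {
  regmask <- abquant:::region_mask_for(width, height, gm_fraction, layout)
  placed <- deposit_placements()
  set.seed(seed)
  for (i in seq_along(classes)) {
    code <- if (regions[i] == "GM") 1L else 2L
    ok <- FALSE
    for (try in 1:20000) {
      x <- runif(1, radius + 2, width - radius - 2)
      y <- runif(1, radius + 2, height - radius - 2)
      if (!abquant:::footprint_in_region(regmask, x, y, radius, code)) next
      if (nrow(placed) &&
          any(sqrt((placed$x - x)^2 + (placed$y - y)^2) <
              2 * (placed$radius_px + radius))) next
      ok <- TRUE; break
    }
    stopifnot(ok)
    placed <- rbind(placed,
                    deposit_placements(classes[i], x, y, radius, regions[i]))
  }
  synthetic_slide_spec(width, height, deposits = placed, layout = layout,
                       gm_fraction = gm_fraction, noise_sd = noise_sd,
                       seed = seed)
}

# wrap a plain matrix as a binary mask with minimal geometry
as_mask <- function(m, class_label = "cored", stride = 16, mpp = 0.503) {
  geom <- list(n_rows = nrow(m), n_cols = ncol(m), stride_px = stride,
               patch_size_px = 256L, slide_mpp = mpp,
               slide_height = nrow(m) * stride, slide_width = ncol(m) * stride,
               slide_id = "mask_fixture")
  structure(list(values = m > 0, class_label = class_label,
                 threshold_used = 0.9, geometry = geom),
            class = "binary_mask")
}

as_region_map <- function(labels, stride = 16, mpp = 0.503) {
  geom <- list(n_rows = nrow(labels), n_cols = ncol(labels),
               stride_px = stride, patch_size_px = 256L, slide_mpp = mpp,
               slide_height = nrow(labels) * stride,
               slide_width = ncol(labels) * stride, slide_id = "mask_fixture")
  region_map(labels, geom)
}

# the same slide under a mild scanner/stain color cast: the batch-effect
# scenario stain normalization is designed to undo
color_cast_slide <- function(slide, gains = c(1.06, 0.95, 1.02),
                             offsets = c(5, -7, 3)) {
  out <- slide
  for (ch in 1:3) {
    v <- as.integer(round(gains[ch] * slide$pixels[, , ch] + offsets[ch]))
    out$pixels[, , ch] <- pmin.int(pmax.int(v, 0L), 255L)
  }
  out$slide_id <- paste0(slide$slide_id, "_cast")
  out
}

# full-enumeration two-sided rank-sum p-value for small samples
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(N, na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mu <- na * (N + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# hypergeometric tail-sum oracle for the 2x2 Fisher exact test
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
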