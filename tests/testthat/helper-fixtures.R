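# Shared fixtures, all generated in code.

# Small phantom used across detector and quantification tests.
small_phantom <- function(seed = 7, speckle_sigma = 0, n_open = 3,
                          n_closed = 1, n_frames = 20,
                          tortuosity = 1, ...) {
  generate_phantom(phantom_spec(
    geometry = stack_geometry(200, 200, n_frames),
    n_open = n_open, n_closed = n_closed,
    ring_radius_px = 85, depression_frames = 2, depression_radius_px = 30,
    speckle_sigma = speckle_sigma, tortuosity = tortuosity,
    seed = seed, ...))
}

# MIP parameters scaled to the small-phantom lumen size (radii 2-4 px):
# no extra smoothing (the rendered frames are already optically blurred),
# 1-px erosion to trim the blur halo around each lumen.
phantom_mip_params <- function(offset = 0.02) {
  mip_params(gaussian_sigma_px = 0, adaptive_block_px = 31,
             adaptive_offset = offset, erosion_radius_px = 1,
             opening_radius_px = 1, min_area_px = 3, max_area_px = 5000,
             roi_radius_px = 85)
}

random_binary_matrix <- function(n, m, p = 0.3) {
  matrix(as.numeric(stats::runif(n * m) < p), n, m)
}

# Independent brute-force confusion tally (per-pixel loop).
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] > 0.5; t <- truth[i, j] > 0.5
      if (p && t) tp <- tp + 1L else if (p) fp <- fp + 1L
      else if (t) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# Kappa via the textbook observed/chance-agreement route.
po_pe_kappa <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  po <- (cc$TP + cc$TN) / n
  pe <- ((cc$TP + cc$FP) * (cc$TP + cc$FN) +
           (cc$FN + cc$TN) * (cc$FP + cc$TN)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

# Sample sparse training labels from phantom truth (uses the caller's RNG).
# near_frac > 0 draws that fraction of the background labels from the 3-px
# annulus around the lumens, emulating an annotator who concentrates
# background labels near the vessel boundaries.
sample_phantom_labels <- function(ph, n_per_class = 100, frames = 1,
                                  near_frac = 0) {
  mask <- ph$truth$mask$data
  rows <- list()
  for (f in frames) {
    m <- mask[, , f]
    lum <- which(m == 1, arr.ind = TRUE)
    dil <- octlumen:::ebi_matrix(
      EBImage::dilate(m, EBImage::makeBrush(7, "disc")))
    halo <- which(dil > 0.5 & m == 0, arr.ind = TRUE)
    bg <- which(m == 0 & dil <= 0.5, arr.ind = TRUE)
    n_l <- min(n_per_class, nrow(lum))
    li <- lum[sample(nrow(lum), n_l), , drop = FALSE]
    nh <- min(round(near_frac * n_per_class), nrow(halo))
    hi <- halo[sample(nrow(halo), nh), , drop = FALSE]
    bi <- bg[sample(nrow(bg), n_per_class - nh), , drop = FALSE]
    bb <- rbind(hi, bi)
    rows[[length(rows) + 1]] <- data.frame(
      frame = f, x = c(li[, 2], bb[, 2]), y = c(li[, 1], bb[, 1]),
      class = rep(c("lumen", "background"), c(n_l, nrow(bb))))
  }
  df <- do.call(rbind, rows)
  sparse_labels(df$frame, df$x, df$y, df$class)
}

subset_frames <- function(stack, frames) {
  intensity_stack(stack$data[, , frames, drop = FALSE], stack$axis_order,
                  stack$pixel_pitch_um, stack$frame_spacing_um)
}
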