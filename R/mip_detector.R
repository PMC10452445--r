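# Morphological image-processing (MIP) lumen detector: Gaussian blur,
# local-mean adaptive threshold, inversion, erosion + opening, component
# area filtering, and circular ROI masking; plus offset calibration against
# ground truth.

#' MIP detector parameters
#'
#' @param gaussian_sigma_px pre-smoothing Gaussian sigma in px (>= 0).
#' @param adaptive_block_px odd local-mean window size in px (>= 3).
#' @param adaptive_offset subtractive threshold offset on the `[0, 1]`
#'   intensity scale: a pixel is a lumen candidate when it is darker than
#'   its local mean by more than this amount. The one free parameter
#'   routinely calibrated against ground truth, see
#'   [calibrate_threshold()].
#' @param erosion_radius_px,opening_radius_px disc radii of the binary
#'   erosion and opening steps (0 disables a step). Defaults 1 and 2 px
#'   suit lumens a few tens of px across; shrink them for lumens only a few
#'   px in radius.
#' @param min_area_px,max_area_px per-frame 2D component area bounds;
#'   components outside `[min, max]` are removed.
#' @param roi_radius_px radius of the circular analysis ROI (default 250,
#'   the insert-edge exclusion radius at 10 um/px).
#' @return a `MipParams` list.
#' @export
mip_params <- function(gaussian_sigma_px = 2, adaptive_block_px = 51,
                       adaptive_offset = 0.02, erosion_radius_px = 1,
                       opening_radius_px = 2, min_area_px = 10,
                       max_area_px = 5000, roi_radius_px = 250) {
  stopifnot(gaussian_sigma_px >= 0, adaptive_block_px >= 3,
            erosion_radius_px >= 0, opening_radius_px >= 0,
            min_area_px >= 0, max_area_px > min_area_px, roi_radius_px > 0)
  if (adaptive_block_px %% 2 != 1) {
    stop("adaptive_block_px must be odd", call. = FALSE)
  }
  structure(list(gaussian_sigma_px = gaussian_sigma_px,
                 adaptive_block_px = as.integer(adaptive_block_px),
                 adaptive_offset = adaptive_offset,
                 erosion_radius_px = as.integer(erosion_radius_px),
                 opening_radius_px = as.integer(opening_radius_px),
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 roi_radius_px = as.integer(roi_radius_px)),
            class = "MipParams")
}

#' Build the per-frame analysis ROI mask
#'
#' The analyzable region of each frame is the centered disc of radius
#' `roi_radius_px` (excluding the bright culture-insert edge outside it)
#' intersected with a tissue-presence mask that drops the central vacancy
#' of the surface frames: pixels of the blurred frame above a global
#' threshold, holes filled, largest connected region kept.
#'
#' @param stack a converted (`XY_ZSTACK`) `IntensityStack`, normally after
#'   [equalize_histogram()].
#' @param roi_radius_px disc radius in px; radii beyond half the frame
#'   diagonal are clipped with a warning.
#' @param blur_sigma_px smoothing applied before the tissue threshold
#'   (default 2).
#' @param threshold_floor minimum global tissue threshold on the `[0, 1]`
#'   scale (default 0.1). The working threshold is half the mean of the
#'   clearly-lit pixels (those above `max(0.5 * frame mean,
#'   threshold_floor)`), which tracks the tissue level rather than being
#'   dragged down by large dark regions.
#' @param max_hole_px lumen-scale dark holes inside the tissue up to this
#'   area are filled back into the analyzable region (they are exactly the
#'   structures to segment); larger vacancies such as the central surface
#'   depression stay excluded. Default 2000.
#' @param boundary_margin_px conservative erosion of the tissue mask (px),
#'   keeping the partial-volume transition band around vacancies out of the
#'   analyzable region. Default 2.
#' @return a `BinaryStack` mask (1 = analyzable).
#' @export
build_roi_mask <- function(stack, roi_radius_px = 250, blur_sigma_px = 2,
                           threshold_floor = 0.1, max_hole_px = 2000,
                           boundary_margin_px = 2) {
  stopifnot(inherits(stack, "IntensityStack"))
  d <- dim(stack$data)
  half_diag <- sqrt(d[1]^2 + d[2]^2) / 2
  if (roi_radius_px > half_diag) {
    warning("roi_radius_px larger than half the frame diagonal; clipped")
    roi_radius_px <- half_diag
  }
  xs <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  ys <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  disc <- sqrt((xs - (d[2] + 1) / 2)^2 + (ys - (d[1] + 1) / 2)^2) <
    roi_radius_px
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    frame <- stack$data[, , i]
    blurred <- gblur_safe(frame, blur_sigma_px)
    thr0 <- max(0.5 * mean(blurred), threshold_floor)
    lit <- blurred > thr0
    thr <- if (any(lit)) max(0.5 * mean(blurred[lit]), threshold_floor)
           else thr0
    tissue <- blurred > thr
    if (any(tissue)) {
      # opening drops isolated above-threshold noise pixels inside vacancies
      tissue <- ebi_matrix(EBImage::opening(
        tissue * 1, EBImage::makeBrush(3, "disc"))) > 0.5
    }
    if (any(tissue)) {
      tissue <- fill_small_holes(tissue, max_hole_px)
      tissue <- largest_component_2d(tissue)
      tissue <- fill_small_holes(tissue, max_hole_px)
      if (boundary_margin_px > 0) {
        tissue <- ebi_matrix(EBImage::erode(
          tissue * 1,
          EBImage::makeBrush(2L * as.integer(boundary_margin_px) + 1L,
                             "disc"))) > 0.5
      }
    }
    out[, , i] <- (disc & tissue) * 1
  }
  binary_stack(out, stack$axis_order, stack$pixel_pitch_um,
               stack$frame_spacing_um)
}

ebi_matrix <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  m
}

# Gaussian blur with the kernel clamped to the frame size (the default
# 3-sigma support can exceed small frames).
gblur_safe <- function(x, sigma) {
  r <- 2L * ceiling(3 * sigma) + 1L
  rmax <- min(dim(x))
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  r <- min(r, rmax)
  if (r < 3L) return(x)
  ebi_matrix(EBImage::gblur(x, sigma = sigma, radius = r))
}

# Fill enclosed background holes up to max_hole_px; larger vacancies (e.g.
# the central surface depression) stay open.
fill_small_holes <- function(mask, max_hole_px) {
  bg <- label_frame_2d(!mask)
  if (max(bg) == 0L) return(mask)
  d <- dim(mask)
  border_labels <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
  areas <- tabulate(bg[bg > 0])
  fill <- setdiff(which(areas <= max_hole_px), border_labels)
  mask | (bg %in% fill & bg > 0)
}

largest_component_2d <- function(mask) {
  lab <- label_frame_2d(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0])
  lab == which.max(areas)
}

# 8-connected 2D labeling via the 3D labeler on a single-frame volume.
label_frame_2d <- function(mask) {
  vol <- label_components(binary_stack(matrix(as.numeric(mask),
                                              nrow(mask), ncol(mask))),
                          connectivity = 26)
  vol$labels[, , 1]
}

#' Segment lumens by the morphological chain
#'
#' Per frame: (1) Gaussian blur; (2) local-mean adaptive threshold with
#' window `adaptive_block_px` and subtractive `adaptive_offset`; (3)
#' inversion, so the dark pore-like lumens become foreground; (4) binary
#' erosion with a disc of `erosion_radius_px`; (5) binary opening with a
#' disc of `opening_radius_px`; (6) 8-connected component labeling and
#' removal of components smaller than `min_area_px` or larger than
#' `max_area_px`; (7) intersection with the ROI mask of [build_roi_mask()].
#'
#' @param stack a converted, preprocessed `IntensityStack`.
#' @param params a [mip_params()] object.
#' @param roi optional precomputed ROI `BinaryStack`; built from the stack
#'   when missing.
#' @return a `BinaryStack`, 1 = lumen; always a subset of the ROI mask.
#' @export
segment_mip <- function(stack, params = mip_params(), roi = NULL) {
  stopifnot(inherits(stack, "IntensityStack"), inherits(params, "MipParams"))
  if (is.null(roi)) roi <- build_roi_mask(stack, params$roi_radius_px)
  if (!identical(dim(roi$data), dim(stack$data))) {
    stop("roi geometry mismatch", call. = FALSE)
  }
  d <- dim(stack$data)
  out <- array(0, d)
  half <- (params$adaptive_block_px - 1L) / 2L
  ker_er <- if (params$erosion_radius_px > 0)
    EBImage::makeBrush(2L * params$erosion_radius_px + 1L, "disc")
  ker_op <- if (params$opening_radius_px > 0)
    EBImage::makeBrush(2L * params$opening_radius_px + 1L, "disc")
  for (i in seq_len(d[3])) {
    frame <- stack$data[, , i]
    if (params$gaussian_sigma_px > 0) {
      frame <- gblur_safe(frame, params$gaussian_sigma_px)
    }
    bright <- ebi_matrix(EBImage::thresh(frame, w = half, h = half,
                                         offset = -params$adaptive_offset))
    lumen <- bright < 0.5                      # invert: dark = foreground
    if (!is.null(ker_er)) {
      lumen <- ebi_matrix(EBImage::erode(lumen * 1, ker_er)) > 0.5
    }
    if (!is.null(ker_op)) {
      lumen <- ebi_matrix(EBImage::opening(lumen * 1, ker_op)) > 0.5
    }
    lumen <- filter_component_areas(lumen, params$min_area_px,
                                    params$max_area_px)
    out[, , i] <- (lumen & (roi$data[, , i] > 0.5)) * 1
  }
  binary_stack(out, stack$axis_order, stack$pixel_pitch_um,
               stack$frame_spacing_um)
}

filter_component_areas <- function(mask, min_area, max_area) {
  if (!any(mask)) return(mask)
  lab <- label_frame_2d(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  lab %in% keep & lab > 0
}

#' Calibrate the adaptive-threshold offset against ground truth
#'
#' Runs [segment_mip()] for every offset in the grid, scores each output by
#' the mean per-frame Cohen's kappa against the reference masks, and
#' returns the best parameter set -- the in-silico analogue of manually
#' adjusting the threshold until the segmentation matches the labeled
#' frames. Ties are broken toward the smaller absolute offset.
#'
#' @param stack a preprocessed `IntensityStack`.
#' @param truth ground-truth `BinaryStack` of the same geometry.
#' @param offset_grid numeric vector of candidate offsets (non-empty).
#' @param params base [mip_params()]; only `adaptive_offset` is varied.
#' @return list with `params` (best `MipParams`), `kappa` (its mean kappa)
#'   and `grid` (data.frame of offset vs mean kappa).
#' @export
calibrate_threshold <- function(stack, truth, offset_grid,
                                params = mip_params()) {
  stopifnot(inherits(stack, "IntensityStack"), inherits(truth, "BinaryStack"),
            length(offset_grid) > 0)
  if (!same_geometry(stack, truth)) {
    stop("stack and truth geometry mismatch", call. = FALSE)
  }
  roi <- build_roi_mask(stack, params$roi_radius_px)
  scores <- vapply(offset_grid, function(off) {
    p <- params; p$adaptive_offset <- off
    mean(kappa_profile(segment_mip(stack, p, roi = roi), truth)$kappa)
  }, numeric(1))
  best <- order(-scores, abs(offset_grid), seq_along(offset_grid))[1]
  out <- params
  out$adaptive_offset <- offset_grid[best]
  list(params = out, kappa = scores[best],
       grid = data.frame(offset = offset_grid, mean_kappa = scores))
}
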