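# Patch split/augment/stitch geometry for patch-based detectors, and the
# pluggable external-detector contract that lets any probability-map
# producer (e.g. a trained image-translation network) enter the evaluation
# and quantification stages.

#' Split a frame into a minimal covering grid of overlapping patches
#'
#' Uses `ceil(frame_dim / patch_size)` patches per axis with offsets evenly
#' spaced from 0 to `frame_dim - patch_size` (rounded), so every pixel is
#' covered and the grid is minimal. A 600 x 600 frame with 256-px patches
#' yields the classic 3 x 3 = nine overlapping patches at offsets
#' 0 / 172 / 344.
#'
#' @param frame a 2D matrix at least `patch_size_px` in each dimension.
#' @param patch_size_px patch side length in px (default 256).
#' @return list with `patches` (list of matrices, row-major grid order) and
#'   `grid` (a `PatchGrid`: patch size, grid shape, per-patch top-left
#'   offsets, frame size).
#' @export
split_patches <- function(frame, patch_size_px = 256L) {
  stopifnot(is.matrix(frame), patch_size_px >= 1)
  h <- nrow(frame); w <- ncol(frame)
  if (h < patch_size_px || w < patch_size_px) {
    stop("frame smaller than patch size", call. = FALSE)
  }
  off_y <- patch_offsets(h, patch_size_px)
  off_x <- patch_offsets(w, patch_size_px)
  grid <- structure(list(patch_size_px = as.integer(patch_size_px),
                         rows = length(off_y), cols = length(off_x),
                         offsets_y = off_y, offsets_x = off_x,
                         frame_size_px = c(width = w, height = h)),
                    class = "PatchGrid")
  patches <- list()
  for (oy in off_y) for (ox in off_x) {
    patches[[length(patches) + 1L]] <-
      frame[(oy + 1):(oy + patch_size_px), (ox + 1):(ox + patch_size_px)]
  }
  list(patches = patches, grid = grid)
}

patch_offsets <- function(dim, patch) {
  n <- ceiling(dim / patch)
  if (n == 1L) return(0L)
  as.integer(round(seq(0, dim - patch, length.out = n)))
}

#' Recombine patches into a frame
#'
#' Overlapping pixels are averaged; `stitch(split(f))` reproduces `f`
#' exactly, since every overlap averages identical values. When
#' `binary = TRUE` the averaged frame is thresholded at 0.5 with ties
#' mapping to foreground.
#'
#' @param patches list of matrices as produced by [split_patches()] (or a
#'   compatible producer), in row-major grid order.
#' @param grid the `PatchGrid` describing their placement.
#' @param binary threshold the stitched average at >= 0.5 (default
#'   `FALSE`).
#' @return the stitched 2D matrix.
#' @export
stitch_patches <- function(patches, grid, binary = FALSE) {
  stopifnot(inherits(grid, "PatchGrid"))
  if (length(patches) != grid$rows * grid$cols) {
    stop("patch count does not match grid", call. = FALSE)
  }
  p <- grid$patch_size_px
  ok <- vapply(patches, function(m) is.matrix(m) && all(dim(m) == p),
               logical(1))
  if (!all(ok)) stop("patch size does not match grid", call. = FALSE)
  h <- grid$frame_size_px["height"]; w <- grid$frame_size_px["width"]
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  k <- 0L
  for (oy in grid$offsets_y) for (ox in grid$offsets_x) {
    k <- k + 1L
    ry <- (oy + 1):(oy + p); rx <- (ox + 1):(ox + p)
    acc[ry, rx] <- acc[ry, rx] + patches[[k]]
    cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  out <- acc / cnt
  if (binary) out <- (out >= 0.5) * 1
  out
}

#' Flip augmentation
#'
#' Returns, for each input frame, the original, its horizontal flip and its
#' vertical flip (3x the input count) in stable order; optionally also the
#' 180-degree double flip (4x).
#'
#' @param frames non-empty list of 2D matrices.
#' @param include_double also emit the horizontal+vertical double flip
#'   (default `FALSE`).
#' @return list of matrices: for each input frame, `original, hflip, vflip`
#'   (`, hvflip`) in that order.
#' @export
augment_flips <- function(frames, include_double = FALSE) {
  stopifnot(is.list(frames), length(frames) > 0)
  out <- list()
  for (f in frames) {
    stopifnot(is.matrix(f))
    variants <- list(f, f[, rev(seq_len(ncol(f))), drop = FALSE],
                     f[rev(seq_len(nrow(f))), , drop = FALSE])
    if (include_double) {
      variants <- c(variants,
                    list(f[rev(seq_len(nrow(f))), rev(seq_len(ncol(f))),
                           drop = FALSE]))
    }
    out <- c(out, variants)
  }
  out
}

#' Import an externally produced segmentation
#'
#' The plug-in contract for detectors living outside the package (e.g. a
#' trained patch-based image-translation generator): the producer supplies
#' per-frame lumen probability maps -- as a multi-page TIFF / frame
#' directory readable by [read_stack()], or as an R function
#' `stack -> 3D probability array` -- and this wrapper validates the
#' geometry and thresholds probabilities at >= 0.5 (ties foreground).
#'
#' @param stack the `IntensityStack` the maps belong to (geometry
#'   reference).
#' @param producer a path to the probability maps, or a function taking the
#'   stack and returning a height x width x frames array of probabilities.
#' @return a `BinaryStack`, 1 = lumen.
#' @export
external_segment <- function(stack, producer) {
  stopifnot(inherits(stack, "IntensityStack"))
  if (is.function(producer)) {
    prob <- producer(stack)
    if (inherits(prob, "oct_stack")) prob <- prob$data
  } else if (is.character(producer)) {
    prob <- read_stack(producer, axis_order = stack$axis_order,
                       pixel_pitch_um = stack$pixel_pitch_um,
                       frame_spacing_um = stack$frame_spacing_um)$data
  } else {
    stop("producer must be a path or a function", call. = FALSE)
  }
  if (!identical(dim(prob), dim(stack$data))) {
    stop("probability maps do not match the stack geometry", call. = FALSE)
  }
  if (min(prob) < 0 || max(prob) > 1) {
    stop("probability maps must lie in [0, 1]", call. = FALSE)
  }
  binary_stack((prob >= 0.5) * 1, stack$axis_order, stack$pixel_pitch_um,
               stack$frame_spacing_um)
}
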