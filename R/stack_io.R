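# Stack reading/writing, acquisition-geometry conversion, depth truncation
# and contrast preprocessing.

#' Read an image stack from a multi-page TIFF or a frame directory
#'
#' Frames read from a directory are ordered lexicographically by file name.
#' Grayscale values of any bit depth are normalized to reals in `[0, 1]`;
#' multi-channel frames are averaged to one channel.
#'
#' @param path a multi-page TIFF file, or a directory of same-sized
#'   single-frame TIFF/PNG images.
#' @param axis_order geometry tag of the data on disk (default
#'   `"XY_ZSTACK"`).
#' @param pixel_pitch_um,frame_spacing_um calibration; defaults 10 um each,
#'   the low-resolution OCT acquisition setting.
#' @param binary if `TRUE`, return a [binary_stack()] (values are
#'   binarized at 0.5).
#' @return an `IntensityStack` (or `BinaryStack` when `binary = TRUE`).
#' @export
read_stack <- function(path, axis_order = "XY_ZSTACK",
                       pixel_pitch_um = 10, frame_spacing_um = 10,
                       binary = FALSE) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  frames <- if (dir.exists(path)) read_frame_dir(path) else read_tiff_pages(path)
  if (length(frames) == 0L) stop("no frames found at ", path, call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames of unequal size in ", path, call. = FALSE)
  }
  data <- array(unlist(frames, use.names = FALSE),
                dim = c(dims[1, 1], dims[2, 1], length(frames)))
  if (binary) {
    binary_stack((data >= 0.5) * 1, axis_order, pixel_pitch_um,
                 frame_spacing_um)
  } else {
    intensity_stack(data, axis_order, pixel_pitch_um, frame_spacing_um)
  }
}

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.array(pages) && !is.list(pages)) pages <- list(pages)
  lapply(pages, flatten_channels)
}

read_frame_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0L) {
    stop("no TIFF/PNG frames in directory ", path, call. = FALSE)
  }
  lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    flatten_channels(img)
  })
}

flatten_channels <- function(img) {
  if (length(dim(img)) == 3L)

    img <- apply(img, c(1, 2), mean)
  img
}

#' Write a stack as a multi-page TIFF
#'
#' Intensity stacks are written as 16-bit grayscale (8-bit source values are
#' exactly representable, so a write/read round trip is voxel-identical).
#' Binary stacks are written 8-bit with foreground 255, the most widely
#' viewable dialect for mask files.
#'
#' @param stack an `IntensityStack` or `BinaryStack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "oct_stack"))
  frames <- lapply(seq_len(n_frames(stack)), function(i) stack$data[, , i])
  bits <- if (inherits(stack, "BinaryStack")) 8L else 16L
  ok <- tryCatch(tiff::writeTIFF(frames, path, bits.per.sample = bits),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Convert acquisition geometry to analysis geometry
#'
#' The OCT system acquires x-z cross-sections stacked along y; analysis runs
#' on x-y frames stacked along depth z. The voxel at image position (x, z)
#' of input frame y appears at (x, y) of output frame z. Frame 1 of the
#' output corresponds to the bottom row of the input cross-sections, i.e. the
#' gel bottom carrying the endothelial monolayer. A 600-frame stack of
#' 600 x 60 px cross-sections becomes 60 frames of 600 x 600 px.
#'
#' @param stack an `IntensityStack` with `axis_order = "XZ_YSTACK"`.
#' @return the converted stack with `axis_order = "XY_ZSTACK"`. No value is
#'   interpolated: the operation is a pure index permutation.
#' @export
convert_axes <- function(stack) {
  stopifnot(inherits(stack, "oct_stack"))
  if (stack$axis_order != "XZ_YSTACK") {
    stop("convert_axes expects an XZ_YSTACK stack", call. = FALSE)
  }
  # in[z_row, x, y_frame] -> out[y_row, x, z_frame], z_frame 1 = bottom row
  out <- aperm(stack$data, c(3, 2, 1))[, , rev(seq_len(dim(stack$data)[1])),
                                       drop = FALSE]
  rebuild_stack(stack, out, axis_order = "XY_ZSTACK")
}

#' Inverse of [convert_axes()]
#'
#' Restores the acquired x-z cross-section stacking from a converted stack;
#' `revert_axes(convert_axes(s))` reproduces `s` voxel-exactly.
#'
#' @param stack an `IntensityStack` with `axis_order = "XY_ZSTACK"`.
#' @return the stack in `"XZ_YSTACK"` geometry.
#' @export
revert_axes <- function(stack) {
  stopifnot(inherits(stack, "oct_stack"))
  if (stack$axis_order != "XY_ZSTACK") {
    stop("revert_axes expects an XY_ZSTACK stack", call. = FALSE)
  }
  out <- aperm(stack$data[, , rev(seq_len(dim(stack$data)[3])),
                          drop = FALSE], c(3, 2, 1))
  rebuild_stack(stack, out, axis_order = "XZ_YSTACK")
}

rebuild_stack <- function(template, data, axis_order = template$axis_order) {
  cls <- if (inherits(template, "BinaryStack")) binary_stack
         else intensity_stack
  cls(data, axis_order = axis_order,
      pixel_pitch_um = template$pixel_pitch_um,
      frame_spacing_um = template$frame_spacing_um)
}

#' Truncate a converted stack to the visible depth
#'
#' Open lumen structures rarely extend beyond ~350 um and OCT frames blur
#' out at depth, so stacks are cropped before analysis. A frame at index i
#' (1-based) sits at depth (i - 1) * frame_spacing_um and is retained when
#' that depth is strictly less than `max_depth_um`: the result keeps
#' `floor(max_depth_um / frame_spacing_um)` frames (capped at the frames
#' available).
#'
#' @param stack an `IntensityStack` or `BinaryStack` in `"XY_ZSTACK"` order.
#' @param max_depth_um positive depth bound in micrometres (default 350).
#' @return the truncated stack; frame order unchanged, no interpolation.
#' @export
truncate_depth <- function(stack, max_depth_um = 350) {
  stopifnot(inherits(stack, "oct_stack"))
  if (!is.numeric(max_depth_um) || length(max_depth_um) != 1L ||
      max_depth_um <= 0) {
    stop("max_depth_um must be a positive number", call. = FALSE)
  }
  keep <- min(n_frames(stack), floor(max_depth_um / stack$frame_spacing_um))
  if (keep < 1L) stop("max_depth_um retains no frames", call. = FALSE)
  if (keep == n_frames(stack)) return(stack)
  rebuild_stack(stack, stack$data[, , seq_len(keep), drop = FALSE])
}

#' Histogram equalization
#'
#' Remaps intensities by the cumulative intensity distribution to spread the
#' histogram over the full representable range, the standard global-contrast
#' boost applied to OCT frames before segmentation. Equalization is per frame
#' by default: OCT brightness decays with depth, so a single stack-wide map
#' would compress the shallow frames to recover the deep ones. Set
#' `per_frame = FALSE` for one map over the whole stack.
#'
#' Values are binned to `levels` gray levels; a bin with cumulative mass
#' `cdf(v)` maps to `(cdf(v) - cdf_min) / (1 - cdf_min)` of full scale,
#' where `cdf_min` is the mass of the lowest occupied bin. A constant frame
#' has no contrast to redistribute and is returned unchanged (documented
#' convention for the degenerate denominator).
#'
#' @param stack an `IntensityStack`.
#' @param levels number of gray levels for the remap (default 256).
#' @param per_frame equalize each frame independently (default `TRUE`).
#' @return the equalized `IntensityStack`; within every frame the intensity
#'   ordering of pixels is preserved.
#' @export
equalize_histogram <- function(stack, levels = 256L, per_frame = TRUE) {
  stopifnot(inherits(stack, "IntensityStack"), levels >= 2)
  out <- stack$data
  if (per_frame) {
    for (i in seq_len(n_frames(stack))) {
      out[, , i] <- equalize_frame(out[, , i], levels)
    }
  } else {
    out <- equalize_frame(out, levels)
  }
  rebuild_stack(stack, out)
}

equalize_frame <- function(frame, levels) {
  q <- pmin(pmax(round(frame * (levels - 1)), 0), levels - 1)
  counts <- tabulate(q + 1L, nbins = levels)
  cdf <- cumsum(counts) / length(q)
  cdf_min <- cdf[which(counts > 0)[1]]
  if (cdf_min >= 1) return(frame)  # constant frame: nothing to equalize
  mapped <- round((cdf - cdf_min) / (1 - cdf_min) * (levels - 1)) / (levels - 1)
  out <- mapped[q + 1L]
  dim(out) <- dim(frame)
  out
}
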