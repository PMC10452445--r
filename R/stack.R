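# S3 containers for image stacks.
#
# A stack is a 3D numeric array dim = c(height, width, n_frames) with frame
# values in [0, 1] (IntensityStack) or in {0, 1} (BinaryStack), plus an axis
# tag and the physical calibration. Frames of an XY_ZSTACK are x-y sections
# ordered bottom-up: frame 1 is the gel bottom surface, the side carrying the
# endothelial monolayer and the open lumen ends.

AXIS_ORDERS <- c("XY_ZSTACK", "XZ_YSTACK")

new_stack <- function(data, axis_order, pixel_pitch_um, frame_spacing_um,
                      class) {
  structure(
    list(data = data, axis_order = axis_order,
         pixel_pitch_um = pixel_pitch_um,
         frame_spacing_um = frame_spacing_um),
    class = c(class, "oct_stack")
  )
}

#' Create an intensity stack
#'
#' Wraps a 3D numeric array (height x width x frames) as an `IntensityStack`.
#' Values are stored as reals in `[0, 1]`; integer arrays are rescaled by the
#' maximum representable value of their bit depth.
#'
#' @param data 3D numeric array, `dim = c(height, width, n_frames)`. A matrix
#'   is promoted to a single-frame stack.
#' @param axis_order `"XY_ZSTACK"` (converted geometry, frames are x-y planes
#'   stacked along depth z, frame 1 = gel bottom) or `"XZ_YSTACK"` (acquired
#'   geometry, frames are x-z cross-sections stacked along y).
#' @param pixel_pitch_um lateral pixel size in micrometres (default 10).
#' @param frame_spacing_um distance between consecutive frames in
#'   micrometres (default 10).
#' @return An `IntensityStack` object.
#' @export
intensity_stack <- function(data, axis_order = "XY_ZSTACK",
                            pixel_pitch_um = 10, frame_spacing_um = 10) {
  data <- as_stack_array(data)
  axis_order <- match.arg(axis_order, AXIS_ORDERS)
  check_calibration(pixel_pitch_um, frame_spacing_um)
  if (max(data) > 1 || min(data) < 0) {
    stop("intensity data must lie in [0, 1]; rescale integer data first",
         call. = FALSE)
  }
  new_stack(data, axis_order, pixel_pitch_um, frame_spacing_um,
            "IntensityStack")
}

#' Create a binary (lumen mask) stack
#'
#' @inheritParams intensity_stack
#' @param data 3D array of 0/1 (or logical) values; 1 marks lumen voxels.
#' @return A `BinaryStack` object.
#' @export
binary_stack <- function(data, axis_order = "XY_ZSTACK",
                         pixel_pitch_um = 10, frame_spacing_um = 10) {
  data <- as_stack_array(data)
  axis_order <- match.arg(axis_order, AXIS_ORDERS)
  check_calibration(pixel_pitch_um, frame_spacing_um)
  if (!all(data %in% c(0, 1))) {
    stop("binary stack data must contain only 0 and 1", call. = FALSE)
  }
  storage.mode(data) <- "double"
  new_stack(data, axis_order, pixel_pitch_um, frame_spacing_um, "BinaryStack")
}

as_stack_array <- function(data) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("stack data must be a 3D array (height x width x frames)",
         call. = FALSE)
  }
  if (any(dim(data) == 0L)) stop("stack must be non-empty", call. = FALSE)
  data
}

check_calibration <- function(pixel_pitch_um, frame_spacing_um) {
  stopifnot(is.numeric(pixel_pitch_um), length(pixel_pitch_um) == 1L,
            pixel_pitch_um > 0,
            is.numeric(frame_spacing_um), length(frame_spacing_um) == 1L,
            frame_spacing_um > 0)
}

#' Stack geometry descriptor
#'
#' @param width_px,height_px,n_frames positive integer dimensions.
#' @param pixel_pitch_um,frame_spacing_um physical calibration in
#'   micrometres per pixel / per frame.
#' @return A `StackGeometry` list with the five fields plus the physical
#'   extents in micrometres.
#' @export
stack_geometry <- function(width_px, height_px, n_frames,
                           pixel_pitch_um = 10, frame_spacing_um = 10) {
  stopifnot(width_px >= 1, height_px >= 1, n_frames >= 1)
  check_calibration(pixel_pitch_um, frame_spacing_um)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_frames = as.integer(n_frames),
    pixel_pitch_um = pixel_pitch_um, frame_spacing_um = frame_spacing_um,
    extent_um = c(x = width_px * pixel_pitch_um,
                  y = height_px * pixel_pitch_um,
                  z = n_frames * frame_spacing_um)
  ), class = "StackGeometry")
}

#' Geometry of a stack
#'
#' @param stack an `IntensityStack` or `BinaryStack`.
#' @return the `StackGeometry` of the stack.
#' @export
geometry <- function(stack) {
  stopifnot(inherits(stack, "oct_stack"))
  d <- dim(stack$data)
  stack_geometry(width_px = d[2], height_px = d[1], n_frames = d[3],
                 pixel_pitch_um = stack$pixel_pitch_um,
                 frame_spacing_um = stack$frame_spacing_um)
}

n_frames <- function(stack) dim(stack$data)[3]

#' Extract one frame of a stack as a matrix
#'
#' @param stack an `IntensityStack` or `BinaryStack`.
#' @param i frame index (1-based; frame 1 of an XY_ZSTACK is the gel bottom).
#' @return a height x width matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "oct_stack"), i >= 1, i <= n_frames(stack))
  stack$data[, , i]
}

#' @export
dim.oct_stack <- function(x) dim(x$data)

#' @export
print.oct_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d px, %d frames [%s]\n", class(x)[1],
              d[2], d[1], d[3], x$axis_order))
  cat(sprintf("  pixel pitch %g um, frame spacing %g um (%g x %g x %g um)\n",
              x$pixel_pitch_um, x$frame_spacing_um,
              d[2] * x$pixel_pitch_um, d[1] * x$pixel_pitch_um,
              d[3] * x$frame_spacing_um))
  invisible(x)
}

#' @export
print.StackGeometry <- function(x, ...) {
  cat(sprintf("<StackGeometry> %d x %d px x %d frames, %g um/px, %g um/frame\n",
              x$width_px, x$height_px, x$n_frames,
              x$pixel_pitch_um, x$frame_spacing_um))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$pixel_pitch_um, b$pixel_pitch_um)) &&
    isTRUE(all.equal(a$frame_spacing_um, b$frame_spacing_um))
}
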