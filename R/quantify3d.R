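# 3D vessel quantification: connected components, open/closed classification
# against the gel bottom, minimum-caliper diameters, Crofton lateral surface
# areas, and the effective-permeability helper.

#' 3D connected-component labeling of a lumen mask
#'
#' Labels foreground voxels of a `BinaryStack` into connected components
#' under 6-, 18- or 26-connectivity. Components are numbered 1..K in the
#' scan order (column-major within frame, then frame order) of their first
#' voxel, so labeling is deterministic.
#'
#' @param mask a `BinaryStack` in `"XY_ZSTACK"` order.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners; default).
#' @return a `LabelVolume`: list with `labels` (3D integer array, 0 =
#'   background), `connectivity`, `n_components`, and the stack calibration.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "BinaryStack"))
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  d <- dim(mask$data)
  # pad by one background voxel on every side so neighbor offsets never wrap
  pd <- d + 2L
  pad <- array(FALSE, pd)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data == 1
  offs <- connectivity_offsets(connectivity, pd)
  labels_pad <- integer(length(pad))
  fg <- which(pad)
  k <- 0L
  for (seed in fg) {
    if (labels_pad[seed] != 0L) next
    k <- k + 1L
    labels_pad[seed] <- k
    frontier <- seed
    while (length(frontier) > 0L) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[pad[nb] & labels_pad[nb] == 0L]
      labels_pad[nb] <- k
      frontier <- nb
    }
  }
  dim(labels_pad) <- pd
  labels <- labels_pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  structure(list(labels = labels, connectivity = connectivity,
                 n_components = k,
                 pixel_pitch_um = mask$pixel_pitch_um,
                 frame_spacing_um = mask$frame_spacing_um),
            class = "LabelVolume")
}

connectivity_offsets <- function(connectivity, pd) {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  manh <- abs(g$dy) + abs(g$dx) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = manh <= 3)
  g <- g[keep, ]
  g$dy + g$dx * pd[1] + g$dz * pd[1] * pd[2]
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<LabelVolume> %d x %d px, %d frames, %d components (%d-connectivity)\n",
              d[2], d[1], d[3], x$n_components, x$connectivity))
  invisible(x)
}

component_ids <- function(volume) seq_len(volume$n_components)

#' Classify components as open or closed
#'
#' A lumen is open when it is connected to the gel bottom surface -- i.e. the
#' component has at least one voxel in frame 1 -- and is therefore perfusable
#' in a permeability assay; otherwise it is closed. Segmentation dropout in
#' the first frames can demote a truly open vessel, so the anchor may be
#' widened to the first `anchor_frames` frames.
#'
#' @param volume a `LabelVolume`.
#' @param anchor_frames number of bottom frames counting as "the bottom
#'   surface" (default 1).
#' @return logical vector of length `n_components`; `TRUE` = open.
#' @export
classify_open_closed <- function(volume, anchor_frames = 1L) {
  stopifnot(inherits(volume, "LabelVolume"), anchor_frames >= 1)
  bottom <- volume$labels[, , seq_len(min(anchor_frames,
                                          dim(volume$labels)[3])), drop = FALSE]
  open_ids <- unique(bottom[bottom > 0])
  component_ids(volume) %in% open_ids
}

#' Remove closed components
#'
#' Keeps only open components (those reaching the gel bottom) and renumbers
#' them 1..K_open in the original label order; only open structures take part
#' in the permeability assay.
#'
#' @inheritParams classify_open_closed
#' @return a `LabelVolume` of the open components.
#' @export
remove_closed <- function(volume, anchor_frames = 1L) {
  open <- classify_open_closed(volume, anchor_frames)
  remap <- integer(volume$n_components + 1L)       # index 1 = background 0
  remap[which(open) + 1L] <- seq_len(sum(open))
  labels <- volume$labels
  labels[] <- remap[labels + 1L]
  structure(list(labels = labels, connectivity = volume$connectivity,
                 n_components = sum(open),
                 pixel_pitch_um = volume$pixel_pitch_um,
                 frame_spacing_um = volume$frame_spacing_um),
            class = "LabelVolume")
}

component_voxels <- function(volume, id) {
  if (!id %in% component_ids(volume)) {
    stop("no component with id ", id, call. = FALSE)
  }
  idx <- which(volume$labels == id, arr.ind = TRUE)
  colnames(idx) <- c("y", "x", "frame")
  idx
}

#' Mean minimum-caliper (min Feret) diameter of a component
#'
#' For each frame the component occupies, the minimum caliper width of its
#' 2D cross-section -- the smallest width over all projection directions,
#' i.e. the "minimum x-y distance across" the object -- is computed by
#' rotating calipers over the convex hull of the cross-section, with each
#' pixel treated as a unit square (so a single-pixel section has width 1 px
#' and a rasterized disc of radius r measures ~2r regardless of sub-pixel
#' centering). The per-frame widths are averaged and scaled to micrometres.
#'
#' @param volume a `LabelVolume`.
#' @param id component label.
#' @return diameter in micrometres.
#' @export
measure_diameter <- function(volume, id) {
  vox <- component_voxels(volume, id)
  widths <- vapply(split.data.frame(vox, vox[, "frame"]), function(m) {
    min_caliper_width(m[, "x"], m[, "y"])
  }, numeric(1))
  mean(widths) * volume$pixel_pitch_um
}

# Minimum caliper width of a union of unit pixel squares centered on the
# integer coordinates (x, y). The square support is the Minkowski sum of the
# pixel-center hull and a unit square, so its width in direction n is
# width(centers) + |nx| + |ny| and the minimum over directions is attained
# at an edge normal of the center hull or at an axis direction.
min_caliper_width <- function(x, y) {
  if (length(x) == 1L) return(1)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  dirs <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
      len <- sqrt(ex^2 + ey^2)
      if (len > 0) dirs <- rbind(dirs, c(ey, -ex) / len)
    }
  }
  w <- Inf
  for (q in seq_len(nrow(dirs))) {
    nv <- dirs[q, ]
    pr <- x * nv[1] + y * nv[2]
    w <- min(w, max(pr) - min(pr) + abs(nv[1]) + abs(nv[2]))
  }
  w
}

#' Lateral surface area of a component
#'
#' The lateral (side-wall) area of a vessel is accumulated frame by frame as
#' the product of the cross-section circumference and the frame spacing: for
#' each occupied frame the 2D perimeter is estimated by the 4-direction
#' Crofton formula, converted to micrometres, multiplied by
#' `frame_spacing_um`, and summed -- a Riemann sum of cylinder side area
#' (equivalently, mean circumference x frames x spacing).
#'
#' @inheritParams measure_diameter
#' @return lateral surface area in square micrometres.
#' @export
measure_surface_area <- function(volume, id) {
  vox <- component_voxels(volume, id)
  frames <- sort(unique(vox[, "frame"]))
  total <- 0
  for (f in frames) {
    sel <- vox[, "frame"] == f
    per_px <- crofton_perimeter(vox[sel, "x"], vox[sel, "y"])
    total <- total + per_px * volume$pixel_pitch_um * volume$frame_spacing_um
  }
  total
}

# 4-direction Crofton perimeter (px) of the pixel set given by integer
# coordinates. Standard 2x2-configuration LUT estimator; lower bias than
# edge counting on curved contours (axis-aligned polygons keep a small
# systematic underestimate, a known property of fixed-direction Crofton).
crofton_perimeter <- function(x, y) {
  x <- x - min(x) + 2L; y <- y - min(y) + 2L
  img <- matrix(0L, max(y) + 2L, max(x) + 2L)
  img[cbind(y, x)] <- 1L
  nr <- nrow(img); nc <- ncol(img)
  # 2x2 configuration code at each (i, j):
  #   1*img[i, j] + 4*img[i, j+1] + 2*img[i+1, j] + 8*img[i+1, j+1]
  a <- img[-nr, -nc]; b <- img[-nr, -1]; c2 <- img[-1, -nc]; d <- img[-1, -1]
  code <- a + 4L * b + 2L * c2 + 8L * d
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(h * coefs)
}

new_vessel_table <- function(records) {
  open <- records$open
  totals <- list(
    n_open = sum(open),
    n_closed = sum(!open),
    total_open_surface_area_um2 =
      sum(records$surface_area_um2[open]),
    mean_diameter_um = if (nrow(records)) mean(records$diameter_um) else 0
  )
  structure(list(records = records, totals = totals), class = "VesselTable")
}

#' Summarize a labeled volume into a vessel table
#'
#' One record per component: open flag, voxel count, frames spanned, mean
#' minimum-caliper diameter and lateral surface area; plus stack-level
#' totals (open/closed counts, total open surface area -- the `A` of the
#' permeability normalization -- and mean diameter).
#'
#' @param volume a `LabelVolume`.
#' @param open_only drop closed components from the records (default
#'   `FALSE`). Totals always count both classes of the input volume.
#' @param anchor_frames see [classify_open_closed()].
#' @return a `VesselTable`.
#' @export
summarize_vessels <- function(volume, open_only = FALSE, anchor_frames = 1L) {
  stopifnot(inherits(volume, "LabelVolume"))
  open <- classify_open_closed(volume, anchor_frames)
  ids <- component_ids(volume)
  if (length(ids) == 0L) {
    records <- data.frame(id = integer(), open = logical(),
                          n_voxels = integer(), frames_spanned = integer(),
                          diameter_um = numeric(), surface_area_um2 = numeric())
    return(new_vessel_table(records))
  }
  records <- do.call(rbind, lapply(ids, function(i) {
    vox <- component_voxels(volume, i)
    data.frame(id = i, open = open[i], n_voxels = nrow(vox),
               frames_spanned = length(unique(vox[, "frame"])),
               diameter_um = measure_diameter(volume, i),
               surface_area_um2 = measure_surface_area(volume, i))
  }))
  tab <- new_vessel_table(records)
  if (open_only) {
    tab$records <- tab$records[tab$records$open, , drop = FALSE]
    rownames(tab$records) <- NULL
  }
  tab
}

#' @export
print.VesselTable <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<VesselTable> %d records: %d open + %d closed\n",
              nrow(x$records), t$n_open, t$n_closed))
  cat(sprintf("  total open lateral surface area: %.0f um^2\n",
              t$total_open_surface_area_um2))
  cat(sprintf("  mean diameter: %.1f um\n", t$mean_diameter_um))
  if (nrow(x$records)) print(x$records, ...)
  invisible(x)
}

#' Effective permeability coefficient
#'
#' `Pe = PSe / A`: the permeability--surface-area product of the tested
#' compound divided by the total (open) endothelial surface area, the
#' normalization that turns an OCT-derived surface area into a permeability
#' readout.
#'
#' @param PSe permeability-surface-area product.
#' @param A total open vessel surface area (same area units as `PSe`; > 0).
#' @return `PSe / A`.
#' @export
effective_permeability <- function(PSe, A) {
  stopifnot(is.numeric(PSe), is.numeric(A))
  if (any(A <= 0)) stop("surface area A must be positive", call. = FALSE)
  PSe / A
}
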