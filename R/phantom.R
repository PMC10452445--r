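# Synthetic OCT-like phantom: tubular lumens in a bright speckled hydrogel,
# with exact analytic ground truth. Every downstream stage (detectors,
# evaluation, 3D quantification) is testable against this truth without any
# real acquisition.

#' Phantom specification
#'
#' Describes a synthetic OCT stack of a hydrogel culture: dark pore-like
#' lumen cross-sections inside bright multiplicative-speckle tissue, a
#' bright culture-insert edge ring, a central surface depression on the
#' first few frames, and depth-dependent contrast decay and blur. The
#' defaults emulate the low-resolution acquisition geometry of a transwell
#' BBB culture: 600 x 600 px frames at 10 um/px, 10 um frame spacing, and a
#' 350 um visible depth (35 frames).
#'
#' @param geometry a [stack_geometry()]; default 600 x 600 x 35 at
#'   10 um / 10 um.
#' @param n_open open tubes, anchored at frame 1 (the gel bottom).
#' @param n_closed closed lumens, fully interior (never touch frame 1).
#' @param radius_um_range tube radius range in um, default `c(20, 40)`
#'   (2-4 px at the default pitch), the capillary scale seen in the cultures.
#' @param tortuosity standard deviation (px) of the per-frame lateral random
#'   walk of each tube centerline; default 1.
#' @param max_extent_um maximum depth reached by open tubes (um, <= 350);
#'   open structures rarely extend beyond this in the real cultures.
#' @param speckle_sigma log-scale sigma of the multiplicative log-normal
#'   speckle; 0 disables noise. Default 0.25.
#' @param noise_floor standard deviation of the additive detector noise on
#'   the `[0, 1]` intensity scale (depth-independent, so deep frames whose
#'   signal has decayed toward it lose contrast, as in real OCT); 0
#'   disables it. Default 0.02.
#' @param depth_decay_um e-folding depth of the tissue mean level (um);
#'   default 150, giving the strong visible contrast loss by 350 um.
#' @param blur_sigma0_px,blur_gain_per_frame per-frame Gaussian blur sigma
#'   `blur_sigma0_px + blur_gain_per_frame * (frame - 1)`; defaults 0.8 and
#'   0.05 (deep frames are visibly blurrier).
#' @param ring_radius_px radius of the bright insert-edge ring (default 250).
#' @param depression_frames,depression_radius_px number of surface frames
#'   carrying the central hydrogel depression and its radius (defaults 3
#'   and 80).
#' @param lumen_polarity `"dark"` (default; pore-like low-signal lumens) or
#'   `"bright"`.
#' @param seed random seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return a `PhantomSpec` list.
#' @export
phantom_spec <- function(geometry = stack_geometry(600, 600, 35),
                         n_open = 5, n_closed = 2,
                         radius_um_range = c(20, 40),
                         tortuosity = 1,
                         max_extent_um = 350,
                         speckle_sigma = 0.25,
                         noise_floor = 0.02,
                         depth_decay_um = 150,
                         blur_sigma0_px = 0.8,
                         blur_gain_per_frame = 0.05,
                         ring_radius_px = 250,
                         depression_frames = 3,
                         depression_radius_px = 80,
                         lumen_polarity = c("dark", "bright"),
                         seed = 1L) {
  stopifnot(inherits(geometry, "StackGeometry"),
            n_open >= 0, n_closed >= 0,
            length(radius_um_range) == 2L, all(radius_um_range > 0),
            radius_um_range[1] <= radius_um_range[2],
            tortuosity >= 0, speckle_sigma >= 0, noise_floor >= 0,
            depth_decay_um > 0,
            blur_sigma0_px >= 0, blur_gain_per_frame >= 0,
            ring_radius_px > 0, depression_frames >= 0,
            depression_radius_px >= 0)
  if (max_extent_um > 350) {
    stop("max_extent_um must be <= 350 (open structures do not extend deeper)",
         call. = FALSE)
  }
  structure(list(
    geometry = geometry, n_open = n_open, n_closed = n_closed,
    radius_um_range = radius_um_range, tortuosity = tortuosity,
    max_extent_um = max_extent_um, speckle_sigma = speckle_sigma,
    noise_floor = noise_floor,
    depth_decay_um = depth_decay_um, blur_sigma0_px = blur_sigma0_px,
    blur_gain_per_frame = blur_gain_per_frame,
    ring_radius_px = ring_radius_px,
    depression_frames = depression_frames,
    depression_radius_px = depression_radius_px,
    lumen_polarity = match.arg(lumen_polarity),
    seed = as.integer(seed)
  ), class = "PhantomSpec")
}

#' Generate a synthetic OCT phantom with exact ground truth
#'
#' Renders the scene of [phantom_spec()]: tissue at mean level
#' `exp(-depth / depth_decay_um)` inside the insert ring, multiplicative
#' log-normal speckle, dark lumen interiors along jittered vertical
#' centerlines, the bright edge ring on every frame, the dark central disc
#' on the first `depression_frames` frames, and per-frame Gaussian blur.
#' The truth mask marks exactly the noise-free lumen voxels.
#'
#' Tubes are placed by rejection sampling so that no two centerlines come
#' closer than the sum of their radii; placement failing after a bounded
#' number of attempts is an error.
#'
#' @param spec a `PhantomSpec`.
#' @return a list with elements `stack` (`IntensityStack`) and `truth`
#'   (`PhantomTruth`: `mask`, a `BinaryStack`, and `tube_table`, one row per
#'   tube with its open flag, radius, analytic diameter and analytic lateral
#'   cylinder surface area `pi * diameter * length`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  g <- spec$geometry
  W <- g$width_px; H <- g$height_px; Fz <- g$n_frames
  set.seed(spec$seed)

  tubes <- place_tubes(spec)
  mask <- array(0, dim = c(H, W, Fz))
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  for (tb in tubes) {
    r_px <- tb$radius_um / g$pixel_pitch_um
    for (k in seq_along(tb$frames)) {
      f <- tb$frames[k]
      d2 <- (xs - tb$cx[k])^2 + (ys - tb$cy[k])^2
      mask[, , f][d2 <= r_px^2] <- 1
    }
  }

  cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
  rad <- sqrt((xs - cx0)^2 + (ys - cy0)^2)
  ring <- abs(rad - spec$ring_radius_px) <= 1.5
  inside <- rad < spec$ring_radius_px
  depression <- rad < spec$depression_radius_px

  dark <- spec$lumen_polarity == "dark"
  data <- array(0, dim = c(H, W, Fz))
  for (f in seq_len(Fz)) {
    depth <- (f - 1) * g$frame_spacing_um
    tissue_level <- exp(-depth / spec$depth_decay_um)
    frame <- matrix(0.05 * tissue_level, H, W)      # outside the insert
    frame[inside] <- tissue_level
    lum <- mask[, , f] == 1
    frame[lum] <- if (dark) 0.08 * tissue_level else
      min(1, 1.6 * tissue_level)
    if (f <= spec$depression_frames) frame[depression] <- 0.02
    frame[ring] <- min(1, 1.8 * tissue_level)
    if (spec$speckle_sigma > 0) {
      s <- spec$speckle_sigma
      noise <- exp(matrix(rnorm(H * W, -s^2 / 2, s), H, W))
      frame <- frame * noise
    }
    sigma <- spec$blur_sigma0_px + spec$blur_gain_per_frame * (f - 1)
    if (sigma > 0.01) frame <- gblur_safe(frame, sigma)
    # detector noise enters after the optical blur and is depth-independent
    if (spec$noise_floor > 0) {
      frame <- frame + matrix(rnorm(H * W, 0, spec$noise_floor), H, W)
    }
    data[, , f] <- pmin(pmax(frame, 0), 1)
  }

  tube_table <- do.call(rbind, lapply(tubes, function(tb) {
    length_um <- length(tb$frames) * g$frame_spacing_um
    data.frame(id = tb$id, open = tb$open,
               radius_um = tb$radius_um,
               diameter_um = 2 * tb$radius_um,
               first_frame = tb$frames[1],
               frames_spanned = length(tb$frames),
               surface_area_um2 = pi * 2 * tb$radius_um * length_um)
  }))
  if (is.null(tube_table)) {
    tube_table <- data.frame(id = integer(), open = logical(),
                             radius_um = numeric(), diameter_um = numeric(),
                             first_frame = integer(),
                             frames_spanned = integer(),
                             surface_area_um2 = numeric())
  }

  truth <- structure(list(
    mask = binary_stack(mask, "XY_ZSTACK", g$pixel_pitch_um,
                        g$frame_spacing_um),
    tube_table = tube_table,
    centerlines = lapply(tubes, function(tb) {
      data.frame(frame = tb$frames, cx = tb$cx, cy = tb$cy)
    })
  ), class = "PhantomTruth")

  list(stack = intensity_stack(data, "XY_ZSTACK", g$pixel_pitch_um,
                               g$frame_spacing_um),
       truth = truth)
}

# Rejection-sample non-overlapping jittered vertical tubes.
place_tubes <- function(spec, max_attempts = 200L) {
  g <- spec$geometry
  n_total <- spec$n_open + spec$n_closed
  if (n_total == 0L) return(list())
  cx0 <- (g$width_px + 1) / 2; cy0 <- (g$height_px + 1) / 2
  max_open_frames <- max(1L, min(g$n_frames,
                                 floor(spec$max_extent_um / g$frame_spacing_um)))
  tubes <- list()
  for (i in seq_len(n_total)) {
    open <- i <= spec$n_open
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      radius_um <- stats::runif(1, spec$radius_um_range[1],
                                spec$radius_um_range[2])
      r_px <- radius_um / g$pixel_pitch_um
      if (open) {
        first <- 1L
        len <- max(2L, round(stats::runif(1, 0.6, 1) * max_open_frames))
      } else {
        first <- sample(2:max(2L, floor(g$n_frames / 2)), 1L)
        len <- max(2L, round(stats::runif(1, 0.3, 0.7) *
                               (g$n_frames - first)))
      }
      frames <- first:min(g$n_frames, first + len - 1L)
      # keep centers between the surface depression and the insert ring
      rmin <- spec$depression_radius_px + r_px + 5
      rmax <- spec$ring_radius_px - r_px - 10
      if (rmax <= rmin) rmin <- max(0, rmax - 1)
      rho <- sqrt(stats::runif(1, (rmin / rmax)^2, 1)) * rmax
      ang <- stats::runif(1, 0, 2 * pi)
      cx <- cx0 + rho * cos(ang); cy <- cy0 + rho * sin(ang)
      jx <- cumsum(c(0, stats::rnorm(length(frames) - 1, 0, spec$tortuosity)))
      jy <- cumsum(c(0, stats::rnorm(length(frames) - 1, 0, spec$tortuosity)))
      cand <- list(id = i, open = open, radius_um = radius_um,
                   frames = frames, cx = cx + jx, cy = cy + jy)
      if (!tube_overlaps(cand, tubes, g$pixel_pitch_um)) {
        tubes[[length(tubes) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place tube ", i, " without overlap after ",
           max_attempts, " attempts; reduce tube count or radii",
           call. = FALSE)
    }
  }
  tubes
}

tube_overlaps <- function(cand, tubes, pitch) {
  for (tb in tubes) {
    common <- intersect(cand$frames, tb$frames)
    if (length(common) == 0L) next
    ia <- match(common, cand$frames); ib <- match(common, tb$frames)
    dmin <- sqrt(min((cand$cx[ia] - tb$cx[ib])^2 +
                       (cand$cy[ia] - tb$cy[ib])^2))
    if (dmin <= (cand$radius_um + tb$radius_um) / pitch + 2) return(TRUE)
  }
  FALSE
}

#' Match labeled components to phantom tubes
#'
#' Associates every component of a `LabelVolume` (computed on the phantom
#' truth mask or on a detector output) with the phantom tube it overlaps
#' most, enabling per-tube parameter-recovery comparisons. Components
#' overlapping no tube get `NA`.
#'
#' @param volume a `LabelVolume` over the phantom geometry.
#' @param truth the `PhantomTruth`.
#' @return integer vector of tube ids, one per component.
#' @export
match_components <- function(volume, truth) {
  stopifnot(inherits(volume, "LabelVolume"), inherits(truth, "PhantomTruth"))
  d <- dim(volume$labels)
  tube_vox <- array(0L, d)
  xs <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  ys <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  for (i in seq_len(nrow(truth$tube_table))) {
    cl <- truth$centerlines[[i]]
    r_px <- truth$tube_table$radius_um[i] / volume$pixel_pitch_um
    for (k in seq_len(nrow(cl))) {
      f <- cl$frame[k]
      if (f > d[3]) next
      sel <- (xs - cl$cx[k])^2 + (ys - cl$cy[k])^2 <= r_px^2
      tube_vox[, , f][sel] <- truth$tube_table$id[i]
    }
  }
  vapply(component_ids(volume), function(cid) {
    tubes <- tube_vox[volume$labels == cid]
    tubes <- tubes[tubes > 0]
    if (length(tubes) == 0L) return(NA_integer_)
    as.integer(names(which.max(table(tubes))))
  }, integer(1))
}

#' Analytic truth summary in the detector-output table shape
#'
#' Converts the analytic tube table of a `PhantomTruth` into the
#' `VesselTable` shape produced by [summarize_vessels()], for direct
#' comparison of recovered and true vessel statistics.
#'
#' @param truth a `PhantomTruth`.
#' @return a `VesselTable`.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "PhantomTruth"))
  tt <- truth$tube_table
  records <- data.frame(id = tt$id, open = tt$open,
                        n_voxels = rep(NA_integer_, nrow(tt)),
                        frames_spanned = tt$frames_spanned,
                        diameter_um = tt$diameter_um,
                        surface_area_um2 = tt$surface_area_um2)
  new_vessel_table(records)
}
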