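# 3D labeling, open/closed classification, diameters, surface areas,
# permeability helper.

cube_mask <- function(dims, ...) {
  arr <- array(0, dims)
  for (box in list(...)) {
    arr[box$y, box$x, box$z] <- 1
  }
  binary_stack(arr)
}

# independent flood-fill oracle (recursive, tiny volumes only)
flood_count <- function(arr, connectivity) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  nb <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  nb <- nb[!(nb$dy == 0 & nb$dx == 0 & nb$dz == 0), ]
  manh <- abs(nb$dy) + abs(nb$dx) + abs(nb$dz)
  nb <- nb[switch(as.character(connectivity),
                  "6" = manh == 1, "18" = manh <= 2, "26" = manh <= 3), ]
  k <- 0
  for (y in 1:d[1]) for (x in 1:d[2]) for (z in 1:d[3]) {
    if (arr[y, x, z] != 1 || seen[y, x, z]) next
    k <- k + 1
    queue <- list(c(y, x, z)); seen[y, x, z] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(nb))) {
        w <- v + c(nb$dy[r], nb$dx[r], nb$dz[r])
        if (any(w < 1) || any(w > d)) next
        if (arr[w[1], w[2], w[3]] == 1 && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  k
}

test_that("disjoint cubes label separately; corner contact depends on connectivity", {
  two <- cube_mask(c(10, 10, 10), list(y = 1:3, x = 1:3, z = 1:3),
                   list(y = 6:8, x = 6:8, z = 6:8))
  expect_equal(label_components(two, 26)$n_components, 2)
  # cubes touching only at one corner voxel pair
  corner <- cube_mask(c(8, 8, 8), list(y = 1:3, x = 1:3, z = 1:3),
                      list(y = 4:6, x = 4:6, z = 4:6))
  expect_equal(label_components(corner, 26)$n_components, 1)
  expect_equal(label_components(corner, 6)$n_components, 2)
  # empty mask
  empty <- binary_stack(array(0, c(4, 4, 4)))
  expect_equal(label_components(empty, 26)$n_components, 0)
  expect_error(label_components(two, 13), "connectivity")
})

test_that("labeling agrees with a brute-force flood fill on random volumes", {
  set.seed(8)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:5) {
      arr <- array(as.numeric(runif(6 * 6 * 6) < 0.25), c(6, 6, 6))
      mask <- binary_stack(arr)
      vol <- label_components(mask, conn)
      expect_equal(vol$n_components, flood_count(arr, conn))
      # conservation: labeled voxels = foreground voxels, labels contiguous
      expect_equal(sum(vol$labels > 0), sum(arr))
      if (vol$n_components > 0) {
        expect_setequal(unique(vol$labels[vol$labels > 0]),
                        seq_len(vol$n_components))
      }
    }
  }
})

test_that("open/closed classification anchors at the bottom frame", {
  arr <- array(0, c(12, 12, 12))
  arr[3:5, 3:5, 1:10] <- 1          # spans frame 1: open
  arr[8:10, 8:10, 5:8] <- 1         # floating blob: closed
  vol <- label_components(binary_stack(arr), 26)
  flags <- classify_open_closed(vol)
  expect_equal(sum(flags), 1)
  expect_equal(vol$n_components, 2)
  # n_open + n_closed = K
  expect_equal(sum(flags) + sum(!flags), vol$n_components)
  # component starting at frame 2 is closed unless the anchor is widened
  arr2 <- array(0, c(8, 8, 6)); arr2[2:4, 2:4, 2:5] <- 1
  vol2 <- label_components(binary_stack(arr2), 26)
  expect_false(any(classify_open_closed(vol2)))
  expect_true(all(classify_open_closed(vol2, anchor_frames = 2)))
})

test_that("remove_closed keeps open components with contiguous relabeling", {
  ph <- small_phantom(n_open = 3, n_closed = 2, seed = 13)
  vol <- label_components(ph$truth$mask, 26)
  open_vol <- remove_closed(vol)
  expect_equal(open_vol$n_components, 3)
  expect_setequal(unique(open_vol$labels[open_vol$labels > 0]), 1:3)
  expect_true(all(classify_open_closed(open_vol)))
  # all-closed volume -> empty
  arr <- array(0, c(6, 6, 6)); arr[2:3, 2:3, 3:4] <- 1
  vol2 <- label_components(binary_stack(arr), 26)
  expect_equal(remove_closed(vol2)$n_components, 0)
  # summarize(open_only) on original == summarize on remove_closed output
  t1 <- summarize_vessels(vol, open_only = TRUE)
  t2 <- summarize_vessels(open_vol)
  expect_equal(t1$records$diameter_um, t2$records$diameter_um)
  expect_equal(t1$records$surface_area_um2, t2$records$surface_area_um2)
  expect_equal(t1$records$n_voxels, t2$records$n_voxels)
  expect_equal(t1$totals$total_open_surface_area_um2,
               t2$totals$total_open_surface_area_um2)
})

test_that("diameter measurement matches brute-force caliper oracles", {
  # straight axis-aligned tube, circular cross-section radius 3 px, pitch 10
  arr <- array(0, c(20, 20, 6))
  xs <- matrix(rep(1:20, each = 20), 20); ys <- matrix(rep(1:20, 20), 20)
  sel <- (xs - 10.4)^2 + (ys - 9.7)^2 <= 3^2
  for (z in 1:6) arr[, , z][sel] <- 1
  vol <- label_components(binary_stack(arr), 26)
  expect_equal(measure_diameter(vol, 1), 60, tolerance = 10 / 60)

  # single-voxel component: caliper of one pixel = 1 px -> 10 um
  one <- array(0, c(5, 5, 2)); one[3, 3, 1] <- 1
  expect_equal(measure_diameter(label_components(binary_stack(one), 26), 1), 10)

  # elliptical cross-section, semi-axes 5 and 2 px: brute-force caliper
  ell <- array(0, c(20, 20, 1))
  sel <- ((xs - 10) / 5)^2 + ((ys - 10) / 2)^2 <= 1
  ell[, , 1][sel] <- 1
  volE <- label_components(binary_stack(ell), 26)
  px <- xs[sel]; py <- ys[sel]
  brute <- min(vapply(seq(0, 179.5, by = 0.5), function(deg) {
    th <- deg * pi / 180; nv <- c(cos(th), sin(th))
    pr <- px * nv[1] + py * nv[2]
    diff(range(pr)) + abs(nv[1]) + abs(nv[2])   # unit-pixel support width
  }, numeric(1)))
  expect_equal(measure_diameter(volE, 1), brute * 10, tolerance = 1e-3)
  expect_equal(brute, 5, tolerance = 0.1)  # ~4 px across centers + 1 px support
  expect_error(measure_diameter(vol, 99), "no component")
})

test_that("Crofton surface area approximates analytic cylinders", {
  # straight tube radius 30 um (3 px) spanning 20 frames at 10 um
  arr <- array(0, c(24, 24, 20))
  xs <- matrix(rep(1:24, each = 24), 24); ys <- matrix(rep(1:24, 24), 24)
  sel <- (xs - 12.3)^2 + (ys - 12.6)^2 <= 3^2
  for (z in 1:20) arr[, , z][sel] <- 1
  vol <- label_components(binary_stack(arr), 26)
  analytic <- pi * 60 * 200                     # ~37,699 um^2
  expect_equal(measure_surface_area(vol, 1), analytic, tolerance = 0.10)

  # one frame, one pixel: documented degenerate convention
  one <- array(0, c(5, 5, 1)); one[3, 3, 1] <- 1
  vol1 <- label_components(binary_stack(one), 26)
  per1 <- octlumen:::crofton_perimeter(3, 3)
  expect_equal(measure_surface_area(vol1, 1), per1 * 10 * 10)
})

test_that("Crofton estimator equals an independent intercept-count oracle", {
  # brute-force Crofton: configuration histogram assembled per 2x2 window
  brute_crofton <- function(img) {
    img <- rbind(0, cbind(0, img, 0), 0)
    s2 <- sqrt(2)
    coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
               pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
               pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
    total <- 0
    for (i in 1:(nrow(img) - 1)) for (j in 1:(ncol(img) - 1)) {
      code <- img[i, j] + 4 * img[i, j + 1] + 2 * img[i + 1, j] +
        8 * img[i + 1, j + 1]
      total <- total + coefs[code + 1]
    }
    total
  }
  set.seed(9)
  for (rep in 1:10) {
    img <- matrix(as.numeric(runif(100) < 0.4), 10, 10)
    if (!any(img == 1)) next
    idx <- which(img == 1, arr.ind = TRUE)
    expect_equal(octlumen:::crofton_perimeter(idx[, 2], idx[, 1]),
                 brute_crofton(img), tolerance = 1e-12)
  }
  # discs converge to the true circumference within 5% for r >= 6 px
  for (r in c(6, 10, 15)) {
    n <- 2 * r + 8
    xs <- matrix(rep(1:n, each = n), n); ys <- matrix(rep(1:n, n), n)
    sel <- (xs - n / 2)^2 + (ys - n / 2)^2 <= r^2
    per <- octlumen:::crofton_perimeter(xs[sel], ys[sel])
    expect_equal(per, 2 * pi * r, tolerance = 0.05)
  }
})

test_that("phantom parameter recovery: counts exact, diameter and area in band", {
  ph <- small_phantom(n_open = 4, n_closed = 2, seed = 17)
  vol <- label_components(ph$truth$mask, 26)
  tt <- ph$truth$tube_table
  flags <- classify_open_closed(vol)
  expect_equal(sum(flags), sum(tt$open))
  expect_equal(sum(!flags), sum(!tt$open))
  matched <- match_components(vol, ph$truth)
  tab <- summarize_vessels(vol)
  expect_true(all(abs(tab$records$diameter_um - tt$diameter_um[matched]) <= 10))
  rel <- tab$records$surface_area_um2 / tt$surface_area_um2[matched] - 1
  expect_true(all(abs(rel) <= 0.10))
  # voxel conservation across components
  expect_equal(sum(tab$records$n_voxels), sum(ph$truth$mask$data))
})

test_that("effective permeability is PSe / A with a positive-area guard", {
  expect_equal(effective_permeability(0, 5), 0)
  expect_equal(effective_permeability(10, 2), 5)
  expect_equal(effective_permeability(3.7, 37699), 9.814e-5, tolerance = 1e-3)
  expect_error(effective_permeability(1, 0), "positive")
})
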