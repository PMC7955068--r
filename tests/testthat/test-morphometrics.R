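test_that("shape-roughness anchors hold: square 16, fine disk 4*pi", {
  sq <- matrix(TRUE, 200, 200)
  p_sq <- ms_perimeter(sq, mpp = 1)
  expect_equal(p_sq^2 / 200^2, 16, tolerance = 0.5 / 16)

  dd <- disk_mask(1050, 500)
  p_disk <- ms_perimeter(dd, mpp = 1)
  expect_equal(p_disk^2 / sum(dd), 4 * pi, tolerance = 0.02)
})

test_that("perimeter scales with mpp and handles degenerate components", {
  rect <- matrix(TRUE, 120, 80)
  expect_equal(ms_perimeter(rect, mpp = 1), 2 * (120 + 80), tolerance = 0.01)
  expect_equal(ms_perimeter(rect, mpp = 4), 4 * ms_perimeter(rect, mpp = 1))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(ms_perimeter(single, mpp = 4), 16) # pixel square
  expect_equal(ms_perimeter(matrix(FALSE, 4, 4), mpp = 4), 0)
})

test_that("box-counting dimension: smooth border ~1, filled plane ~2", {
  # straight horizontal interface across a wide raster
  bp <- cbind(seq_len(1024), rep(100, 1024))
  expect_equal(fractal_dimension(bp[, 1], bp[, 2]), 1, tolerance = 0.05)

  # full plane region: N(eps) = (W/eps)^2 exactly on dyadic sizes
  xy <- expand.grid(x = 0:127, y = 0:127)
  d2 <- fractal_dimension(xy$x, xy$y)
  expect_equal(d2, 2, tolerance = 0.05)
  for (eps in c(2, 8, 32)) {
    expect_equal(oracle_box_count(xy$x, xy$y, eps), (128 / eps)^2)
  }
  expect_true(is.na(fractal_dimension(5, 5))) # degenerate single point
})

test_that("gliding-box lacunarity behaves like the moment statistic", {
  expect_equal(lacunarity(matrix(TRUE, 64, 64), 32), 1)
  expect_error(lacunarity(matrix(TRUE, 8, 8), 32), "larger than the raster")
  expect_true(is.na(lacunarity(matrix(FALSE, 64, 64), 8)))

  # iid Bernoulli(p): Lambda -> 1 + (1-p)/(p r^2)
  set.seed(5)
  p <- 0.3; r <- 8
  m <- matrix(runif(400 * 400) < p, 400, 400)
  expect_equal(lacunarity(m, r), 1 + (1 - p) / (p * r^2), tolerance = 0.01)

  # checkerboard: coarser boxes are more homogeneous
  tile <- 8
  cb <- outer(seq_len(128), seq_len(128), function(i, j) {
    (floor((i - 1) / tile) + floor((j - 1) / tile)) %% 2 == 0
  })
  expect_gt(lacunarity(cb, tile), lacunarity(cb, 2 * tile))

  # exhaustive window enumeration oracle on a small mask
  set.seed(9)
  sm <- matrix(runif(15 * 15) < 0.4, 15, 15)
  masses <- c()
  for (i in 1:(15 - 4 + 1)) for (j in 1:(15 - 4 + 1))
    masses <- c(masses, sum(sm[i:(i + 3), j:(j + 3)]))
  expect_equal(lacunarity(sm, 4), mean(masses^2) / mean(masses)^2)
})

test_that("euler number counts components minus holes", {
  ann <- disk_mask(30, 10) & !disk_mask(30, 5)
  expect_equal(euler_number(ann), 0)
  two <- matrix(FALSE, 20, 40)
  two[5:10, 5:10] <- TRUE; two[5:10, 25:30] <- TRUE
  expect_equal(euler_number(two), 2)
  # oracle: components (8-conn) minus holes (4-conn enclosed background)
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(30 * 30) < 0.55, 30, 30)
    ncomp <- max(oracle_flood_fill(m, 8))
    pad <- matrix(FALSE, 32, 32); pad[2:31, 2:31] <- m
    bg <- oracle_flood_fill(!pad, 4)
    nholes <- max(bg) - 1 # all but the outside component
    expect_equal(euler_number(m), ncomp - nholes)
  }
})

test_that("solidity and eccentricity follow their geometric definitions", {
  rect <- matrix(TRUE, 40, 25)
  cm <- component_metrics(rect, mpp = 4)
  expect_equal(unname(cm["solidity"]), 1)
  expect_equal(unname(cm["extent_bbox"]), 1)
  expect_equal(unname(cm["euler_number"]), 1)

  # plus-sign polyomino: solidity from an exhaustive hull oracle
  plus <- matrix(FALSE, 31, 31)
  plus[14:18, 4:28] <- TRUE
  plus[4:28, 14:18] <- TRUE
  cmp <- component_metrics(plus, mpp = 1)
  idx <- which(plus, arr.ind = TRUE)
  xs <- c(idx[, 2] - 1, idx[, 2], idx[, 2] - 1, idx[, 2])
  ys <- c(idx[, 1] - 1, idx[, 1] - 1, idx[, 1], idx[, 1])
  h <- grDevices::chull(xs, ys)
  hull_area <- abs(sum(xs[h] * c(ys[h][-1], ys[h][1]) -
                         c(xs[h][-1], xs[h][1]) * ys[h])) / 2
  expect_equal(unname(cmp["solidity"]), sum(plus) / hull_area, tolerance = 1e-9)
  expect_lt(unname(cmp["solidity"]), 1)

  dd <- disk_mask(101, 40)
  cmd <- component_metrics(dd, mpp = 1)
  expect_lt(unname(cmd["eccentricity"]), 0.02)
  thin <- matrix(TRUE, 400, 20)
  expect_gte(unname(component_metrics(thin, 1)["eccentricity"]), 0.99)
  # equal-second-moment axis length of a disk approximates its diameter
  expect_equal(unname(cmd["major_axis_um"]), 80, tolerance = 0.03 * 80)
})

test_that("shape metrics respect the isoperimetric bound and scale invariance", {
  shapes <- list(disk_mask(101, 40), matrix(TRUE, 60, 60),
                 disk_mask(121, 55), matrix(TRUE, 30, 90))
  for (m in shapes) {
    cm <- component_metrics(m, mpp = 2)
    expect_gte(unname(cm["shape_roughness"]), 4 * pi * 0.97)
  }
  small <- disk_mask(61, 25)
  big <- disk_mask(121, 50)
  for (metric in c("shape_roughness", "eccentricity", "solidity", "extent_bbox")) {
    a <- unname(component_metrics(small, 1)[metric])
    b <- unname(component_metrics(big, 1)[metric])
    expect_equal(a, b, tolerance = max(0.015, 0.015 * abs(b)))
  }
})
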