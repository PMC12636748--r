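make_grid <- function(n = 128) grid_spec(n, n, dx = 1 / n)

test_that("extraction partitions the thresholded region deterministically", {
  g <- make_grid()
  cc <- grid_centers(g)
  expect_identical(extract_air_bodies(matrix(-1, g$nx, g$ny), g), list())
  # two disjoint discs: areas within 2%, descending-area order
  r1 <- sqrt(outer((cc$x - 0.3)^2, (cc$y - 0.5)^2, "+"))
  r2 <- sqrt(outer((cc$x - 0.75)^2, (cc$y - 0.5)^2, "+"))
  m <- (r1 < 0.15 | r2 < 0.1) * 1
  bodies <- extract_air_bodies(m, g)
  expect_length(bodies, 2)
  expect_equal(bodies[[1]]$area, pi * 0.15^2, tolerance = 0.02)
  expect_equal(bodies[[2]]$area, pi * 0.1^2, tolerance = 0.02)
  expect_gt(bodies[[1]]$area, bodies[[2]]$area)
  # partition: total body area equals the thresholded area exactly
  expect_identical(sum(vapply(bodies, function(b) b$cell_count, 0L)),
                   sum(m > 0))
  # 4-connectivity: diagonal contact does not merge
  md <- matrix(0, g$nx, g$ny); md[10, 10] <- 1; md[11, 11] <- 1
  expect_length(extract_air_bodies(md, g), 2)
})

test_that("aspect ratio covers the serpentine worked example", {
  expect_equal(aspect_ratio(20, 500e-6), 4e4)
  expect_equal(aspect_ratio(3, 3), 1)
  expect_error(aspect_ratio(-1, 1), "> 0")
  # body-derived ratio on a rasterized ellipse
  g <- make_grid()
  cc <- grid_centers(g)
  e <- (outer((cc$x - 0.5)^2 / 0.3^2, (cc$y - 0.5)^2 / 0.15^2, "+") < 1) * 1
  b <- extract_air_bodies(e, g)[[1]]
  expect_equal(body_aspect_ratio(b), 2, tolerance = 0.03)
  expect_equal(b$major_axis, 0.6, tolerance = 0.03)
})

test_that("circularity matches closed forms for disc, square and ellipse", {
  g <- make_grid()
  cc <- grid_centers(g)
  disc <- (sqrt(outer((cc$x - 0.5)^2, (cc$y - 0.5)^2, "+")) < 0.2) * 1
  expect_equal(circularity(extract_air_bodies(disc, g)[[1]]), 1, tolerance = 0.05)
  sq <- (abs(outer(cc$x - 0.5, rep(1, g$ny))) < 0.15) *
    (abs(outer(rep(1, g$nx), cc$y - 0.5)) < 0.15)
  expect_equal(circularity(extract_air_bodies(sq, g)[[1]]), pi / 4,
               tolerance = 0.07)
  ell <- (outer((cc$x - 0.5)^2 / 0.3^2, (cc$y - 0.5)^2 / 0.15^2, "+") < 1) * 1
  h <- (0.3 - 0.15)^2 / (0.3 + 0.15)^2
  P <- pi * (0.3 + 0.15) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))  # Ramanujan
  expect_equal(circularity(extract_air_bodies(ell, g)[[1]]),
               4 * pi * (pi * 0.3 * 0.15) / P^2, tolerance = 0.05)
})

test_that("channel uniformity separates uniform, modulated and beaded bodies", {
  g <- make_grid()
  cc <- grid_centers(g)
  # constant-width channel, ~13 cells across
  ch <- ((abs(outer(rep(1, g$nx), cc$y - 0.5)) < 0.05) &
           (outer(cc$x, rep(1, g$ny)) > 0.1) &
           (outer(cc$x, rep(1, g$ny)) < 0.9)) * 1
  cv_flat <- channel_uniformity(extract_air_bodies(ch, g)[[1]])
  expect_lte(cv_flat, 0.05)
  # sinusoidal +-20% width, diffuse representation for subcell precision
  eps <- 2 / g$nx
  w <- 0.05 * (1 + 0.2 * sin(2 * pi * cc$x * 4))
  phi <- vapply(seq_len(g$ny), function(j)
    equilibrium_profile(w - abs(cc$y[j] - 0.5), eps), numeric(g$nx))
  inx <- outer(cc$x > 0.02 & cc$x < 0.98, rep(TRUE, g$ny))
  phi[!inx] <- -1
  cv_sin <- channel_uniformity(extract_air_bodies(phi, g)[[1]])
  expect_equal(cv_sin, 0.2 / sqrt(2), tolerance = 0.10)
  # beads-on-string: higher CV than the uniform channel
  beads <- matrix(0, g$nx, g$ny)
  for (x0 in seq(0.15, 0.85, by = 0.14)) {
    r <- sqrt(outer((cc$x - x0)^2, (cc$y - 0.5)^2, "+"))
    beads[r < 0.07] <- 1
  }
  cv_beads <- channel_uniformity(extract_air_bodies(beads, g)[[1]])
  expect_gt(cv_beads, cv_flat + 0.05)
})

test_that("deformation ratio is bounded and behaves at the limits", {
  expect_equal(deformation_ratio(5e-4, 5e-4), 1)
  expect_equal(deformation_ratio(1e-6, 5e-4), 0.002)
  expect_error(deformation_ratio(0, 1), "> 0")
})

test_that("metrics are translation invariant and rotation tolerant", {
  g <- make_grid()
  cc <- grid_centers(g)
  shape <- function(x0, y0, th) {
    xr <- outer(cc$x - x0, rep(1, g$ny)); yr <- outer(rep(1, g$nx), cc$y - y0)
    xx <- cos(th) * xr + sin(th) * yr; yy <- -sin(th) * xr + cos(th) * yr
    ((xx / 0.25)^2 + (yy / 0.1)^2 < 1) * 1
  }
  ref <- extract_air_bodies(shape(0.5, 0.5, 0), g)[[1]]
  tr <- extract_air_bodies(shape(0.37, 0.61, 0), g)[[1]]
  expect_equal(tr$area, ref$area, tolerance = 0.01)
  expect_equal(circularity(tr), circularity(ref), tolerance = 0.01)
  expect_equal(tr$centroid, c(0.37, 0.61), tolerance = 1e-3)
  for (th in c(pi / 4, pi / 2)) {
    rot <- extract_air_bodies(shape(0.5, 0.5, th), g)[[1]]
    expect_equal(rot$area, ref$area, tolerance = 0.02)
    expect_equal(circularity(rot), circularity(ref), tolerance = 0.05)
    expect_equal(body_aspect_ratio(rot), body_aspect_ratio(ref), tolerance = 0.05)
  }
})

test_that("metrics on rasterized discs converge under refinement", {
  errs <- vapply(c(64, 128, 256), function(n) {
    g <- grid_spec(n, n, dx = 1 / n)
    cc <- grid_centers(g)
    m <- (sqrt(outer((cc$x - 0.5)^2, (cc$y - 0.5)^2, "+")) < 0.2) * 1
    b <- extract_air_bodies(m, g)[[1]]
    abs(b$area / (pi * 0.2^2) - 1) + abs(circularity(b) - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("body metrics export one deterministic row per body", {
  g <- make_grid(64)
  cc <- grid_centers(g)
  m <- (sqrt(outer((cc$x - 0.5)^2, (cc$y - 0.5)^2, "+")) < 0.2) * 1
  bodies <- extract_air_bodies(m, g)
  path <- tempfile(fileext = ".csv")
  df <- body_metrics(bodies, path, time = 1.5)
  expect_true(file.exists(path))
  expect_identical(nrow(df), 1L)
  expect_identical(readLines(path), readLines({
    p2 <- tempfile(fileext = ".csv"); body_metrics(bodies, p2, time = 1.5); p2
  }))
})
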