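test_that("polyline length respects anisotropic spacing", {
  expect_equal(polyline_length_mm(polyline_loi(rbind(c(0, 0), c(3, 4))),
                                  c(1, 1)), 5)
  expect_equal(polyline_length_mm(polyline_loi(rbind(c(0, 0), c(0, 10))),
                                  c(1.9, 1.9)), 19)
  expect_equal(polyline_length_mm(
    polyline_loi(rbind(c(0, 0), c(0, 2), c(0, 5))), c(2, 1)), 5)
})

test_that("the 10 mm minimum-length rule passes and fails as measured", {
  long_loi <- polyline_loi(rbind(c(0, 0), c(0, 10)))
  short_loi <- polyline_loi(rbind(c(0, 0), c(3, 4)))
  expect_true(validate_min_length(long_loi, c(1.9, 1.9))$pass)    # 19 mm
  expect_false(validate_min_length(short_loi, c(1, 1))$pass)      # 5 mm
  expect_true(validate_min_length(short_loi, c(1, 1), min_mm = 0)$pass)
  # ROI length is the longest vertex chord
  roi <- polygon_roi(rbind(c(0, 0), c(0, 6), c(2, 6), c(2, 0)))
  v <- validate_min_length(roi, c(1.9, 1.9))
  expect_equal(v$length_mm, 1.9 * sqrt(40))
  expect_true(v$pass)
})

test_that("supercover traversal matches the axis-aligned and corner cases", {
  g <- c(10, 10)
  expect_equal(
    pixel_set_sorted(trace_loi_pixels(
      polyline_loi(rbind(c(2.5, 0.2), c(2.5, 2.8))), g)),
    cbind(c(2, 2, 2), c(0, 1, 2)))
  # diagonal through pixel corners: corner-touched neighbors excluded
  expect_equal(
    pixel_set_sorted(trace_loi_pixels(
      polyline_loi(rbind(c(0.5, 0.5), c(2.5, 2.5))), g)),
    cbind(0:2, 0:2))
  # a segment running exactly along a grid line samples no interior
  expect_error(trace_loi_pixels(polyline_loi(rbind(c(2, 0.5), c(2, 3.5))), g),
               "no pixel interior")
  expect_error(trace_loi_pixels(polyline_loi(rbind(c(-5, -5), c(-1, -2))), g),
               "no pixel interior")
})

test_that("supercover traversal equals the dense point-sampling oracle", {
  g <- c(64, 64)
  for (k in 1:100) {
    v <- random_polyline(sample(2:5, 1), g, seed = 1000 + k)
    got <- pixel_set_sorted(trace_loi_pixels(polyline_loi(v), g))
    want <- oracle_trace(v, g)
    expect_equal(got, want, info = paste("polyline seed", 1000 + k))
  }
})

test_that("LOI statistics are unweighted over crossed pixels, NaN excluded", {
  m <- const_map(1000)
  loi <- polyline_loi(rbind(c(2.5, 0.2), c(2.5, 3.8)))
  s <- loi_stats(m, loi)
  expect_equal(s$mean_t1, 1000)
  expect_equal(s$sd_t1, 0)

  v <- matrix(500, 16, 16)
  v[3, 1:3] <- c(900, 1000, 1100)
  m2 <- t1_map(v)
  loi2 <- polyline_loi(rbind(c(2.5, 0.2), c(2.5, 2.8)))
  s2 <- loi_stats(m2, loi2)
  expect_equal(s2$mean_t1, 1000)
  expect_equal(s2$sd_t1, sqrt(mean((c(900, 1000, 1100) - 1000)^2)))  # 81.65

  v[3, 2] <- NaN
  s3 <- loi_stats(t1_map(v), loi2)
  expect_equal(s3$n, 2L)
  expect_equal(s3$n_nan_excluded, 1L)
  expect_equal(s3$mean_t1, 1000)

  v[3, 1:3] <- NaN
  expect_error(loi_stats(t1_map(v), loi2), "NaN")
})

test_that("LOI statistics are invariant under vertex subdivision", {
  set.seed(11)
  v <- matrix(runif(64 * 64, 800, 1600), 64, 64)
  m <- t1_map(v)
  for (k in 1:20) {
    pts <- random_polyline(3, c(64, 64), seed = 2000 + k)
    loi <- polyline_loi(pts)
    mid <- (pts[-nrow(pts), ] + pts[-1, ]) / 2
    sub <- matrix(rbind(t(pts[-nrow(pts), ]), t(mid)), ncol = 2, byrow = TRUE)
    loi_sub <- polyline_loi(rbind(sub, pts[nrow(pts), ]))
    a <- loi_stats(m, loi); b <- loi_stats(m, loi_sub)
    expect_equal(a$mean_t1, b$mean_t1)
    expect_equal(a$sd_t1, b$sd_t1)
    expect_equal(pixel_set_sorted(a$pixel_set), pixel_set_sorted(b$pixel_set))
  }
})

test_that("polygon rasterization takes pixels whose centers lie inside", {
  g <- c(16, 16)
  sq <- polygon_roi(rbind(c(0, 0), c(0, 3), c(3, 3), c(3, 0)))
  pix <- rasterize_polygon(sq, g)
  expect_equal(nrow(pix), 9L)
  expect_setequal(paste(pix[, 1], pix[, 2]),
                  paste(rep(0:2, each = 3), rep(0:2, 3)))
  # sub-pixel triangle: included iff it contains the center
  tri_on <- polygon_roi(rbind(c(5.3, 5.3), c(5.3, 5.9), c(5.9, 5.6)))
  expect_equal(unname(rasterize_polygon(tri_on, g)[1, ]), c(5, 5))
  tri_off <- polygon_roi(rbind(c(5.05, 5.05), c(5.05, 5.3), c(5.3, 5.15)))
  expect_error(rasterize_polygon(tri_off, g), "no pixel center")
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  g <- c(48, 48)
  for (k in 1:100) {
    v <- random_polygon(sample(3:9, 1), g, seed = 3000 + k)
    want <- oracle_rasterize(v, g)
    if (nrow(want) == 0) {
      expect_error(rasterize_polygon(polygon_roi(v), g), "no pixel center")
    } else {
      got <- pixel_set_sorted(suppressWarnings(
        rasterize_polygon(polygon_roi(v), g)))
      expect_equal(got, want, info = paste("polygon seed", 3000 + k))
    }
  }
})

test_that("rasterized pixel count approaches polygon area for large polygons", {
  for (r in c(8, 14, 20)) {
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    v <- cbind(24 + r * sin(th), 24 + r * cos(th))
    n <- nrow(rasterize_polygon(polygon_roi(v), c(48, 48)))
    area <- abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                    c(v[-1, 1], v[1, 1]) * v[, 2]) / 2)
    # error is perimeter-order
    expect_lt(abs(n - area), 2 * pi * r)
  }
})

test_that("an ROI covering exactly an LOI's crossed pixels gives identical stats", {
  set.seed(5)
  m <- t1_map(matrix(runif(256, 900, 1300), 16, 16))
  loi <- polyline_loi(rbind(c(4.5, 1.3), c(4.5, 6.7)))
  ls <- loi_stats(m, loi)
  # the crossed pixels are row 4, cols 1..6: an exact covering rectangle
  roi <- polygon_roi(rbind(c(4, 1), c(4, 7), c(5, 7), c(5, 1)))
  rs <- roi_stats(m, roi)
  expect_equal(pixel_set_sorted(rs$pixel_set), pixel_set_sorted(ls$pixel_set))
  expect_equal(rs$mean_t1, ls$mean_t1)
  expect_equal(rs$sd_t1, ls$sd_t1)
})

test_that("checkerboard ROI with even pixel count averages the two values", {
  v <- matrix(800, 16, 16)
  v[(row(v) + col(v)) %% 2 == 0] <- 1200
  m <- t1_map(v)
  roi <- polygon_roi(rbind(c(2, 2), c(2, 8), c(6, 8), c(6, 2)))  # 24 px
  s <- roi_stats(m, roi)
  expect_equal(s$n %% 2, 0)
  expect_equal(s$mean_t1, 1000)
})

test_that("length-weighted LOI statistics weight by traversed chord", {
  v <- matrix(1000, 16, 16); v[3, 3] <- 2000   # zero-based pixel (2, 2)
  m <- t1_map(v)
  # crosses pixel (2,1) over 0.5 px, (2,2) fully, (2,3) over 0.1 px
  loi <- polyline_loi(rbind(c(2.5, 1.5), c(2.5, 3.1)))
  su <- loi_stats(m, loi)
  sw <- loi_stats(m, loi, length_weighted = TRUE)
  expect_equal(su$mean_t1, (1000 + 2000 + 1000) / 3)
  expect_equal(sw$mean_t1, (0.5 * 1000 + 1 * 2000 + 0.1 * 1000) / 1.6)
})

test_that("wall thickness from the distance transform matches band geometry", {
  f <- 8L
  mk_band <- function(width_px, n = 24) {
    # horizontal band [a, a + width) in map-pixel units, odd subpixel count
    sub <- round(width_px * f)
    a <- 5L * f
    m <- matrix(0, n * f, n * f)
    m[(a + 1):(a + sub), ] <- 1
    m
  }
  region <- as.matrix(expand.grid(row = 0:23, col = 0:23))
  g15 <- max_wall_thickness_px(mk_band(1.5), region, f)
  expect_lte(abs(g15$max_thickness_px - 1.5), 1 / f)
  expect_equal(g15$grade, 2L)
  g25 <- max_wall_thickness_px(mk_band(2.5), region, f)
  expect_equal(g25$grade, 1L)
  g06 <- max_wall_thickness_px(mk_band(0.625), region, f)  # 5 subpixels
  expect_lte(abs(g06$max_thickness_px - 0.625), 1 / f)
  expect_equal(g06$grade, 3L)
  empty <- max_wall_thickness_px(mk_band(1.5) * 0, region, f)
  expect_equal(empty$max_thickness_px, 0)
  expect_equal(empty$grade, 3L)
})

test_that("grade boundaries: 1.0 and 2.0 px are grade 2, above 2 is grade 1", {
  expect_equal(wall_grade(1.0), 2L)
  expect_equal(wall_grade(2.0), 2L)
  expect_equal(wall_grade(2.0 + 1e-9), 1L)
  expect_equal(wall_grade(1.0 - 1e-9), 3L)
  expect_equal(wall_grade(3.5), 1L)
  expect_equal(wall_grade(0), 3L)
})
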