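test_that("distance, bearing and side behave on a straight highway", {
  hw <- straight_highway()
  r <- distance_bearing_side(0, 100, hw)
  expect_equal(r$distance, 100)
  expect_equal(r$bearing, -pi / 2)
  expect_equal(r$side, 1L)
  # mirrored point
  r2 <- distance_bearing_side(500, -40, hw)
  expect_equal(r2$bearing, pi / 2)
  expect_equal(r2$side, -1L)
  # on the line
  r0 <- distance_bearing_side(3000, 0, hw)
  expect_equal(r0$distance, 0)
  expect_equal(r0$side, 0L)
})

test_that("chainage clamps beyond endpoints and tracks vertices", {
  hw <- straight_highway()
  expect_equal(chainage_of_point(3000, 50, hw), 3000)
  expect_equal(chainage_of_point(-50, 10, hw), 0)
  expect_equal(chainage_of_point(10800, -3, hw), 10000)
  bent <- highway(c(0, 100, 100), c(0, 0, 100))
  expect_equal(bent$cum_len, c(0, 100, 200))
})

test_that("bent-polyline locations match the dense-sampling oracle", {
  bent <- highway(c(0, 100, 100), c(0, 0, 100))
  o <- dense_nearest(130, 40, bent)
  r <- distance_bearing_side(130, 40, bent)
  expect_equal(r$distance, o$distance, tolerance = 1e-4)
  expect_lt(abs(wrap_angle(r$bearing - o$bearing)), 1e-3)
  expect_lt(abs(chainage_of_point(130, 40, bent) - o$chainage), 0.01)
})

test_that("random polylines agree with the dense oracle within 1 cm", {
  set.seed(42)
  for (i in 1:20) {
    hwy <- random_polyline(sample(3:6, 1))
    px <- runif(5, -100, max(hwy$x) + 100)
    py <- runif(5, min(hwy$y) - 300, max(hwy$y) + 300)
    for (j in 1:5) {
      o <- dense_nearest(px[j], py[j], hwy)
      expect_lt(abs(distance_bearing_side(px[j], py[j], hwy)$distance - o$distance), 0.01)
      expect_lt(abs(chainage_of_point(px[j], py[j], hwy) - o$chainage), 0.02)
    }
  }
})

test_that("side flips exactly when a segment crosses the polyline", {
  set.seed(7)
  hwy <- highway(c(0, 400, 800), c(0, 60, -40))
  for (i in 1:50) {
    p0 <- c(runif(1, 0, 800), runif(1, -300, 300))
    p1 <- c(runif(1, 0, 800), runif(1, -300, 300))
    s0 <- distance_bearing_side(p0[1], p0[2], hwy)$side
    s1 <- distance_bearing_side(p1[1], p1[2], hwy)$side
    ints <- roadresponse:::hw_segment_intersections(p0[1], p0[2], p1[1], p1[2], hwy)
    if (s0 * s1 == -1) expect_gte(nrow(ints), 1)
    if (s0 == s1 && s0 != 0) expect_true(nrow(ints) %% 2 == 0)
  }
})

test_that("polygon containment honors the boundary-inside convention", {
  sq <- unit_square()
  expect_true(contains(sq, 0.5, 0.5))
  expect_false(contains(sq, 2, 2))
  expect_true(contains(sq, 1, 0.5))   # on an edge
  expect_true(contains(sq, 0, 0))     # on a vertex
  expect_equal(sq$area, 1)
  # holes via even-odd
  holey <- hr_polygon(list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                           cbind(c(4, 6, 6, 4), c(4, 4, 6, 6))))
  expect_false(contains(holey, 5, 5))
  expect_true(contains(holey, 1, 1))
  expect_equal(holey$area, 100 + 4)   # even-odd collects both ring areas
})

test_that("degenerate geometry errors are raised", {
  expect_error(highway(c(0, 0), c(0, 0)), "distinct")
  expect_error(hr_polygon(cbind(c(0, 1), c(0, 1))), "3 distinct")
  expect_error(passages(12000, "culvert", straight_highway()), "extent")
})

test_that("highway and polygon WKT round-trip", {
  hwy <- highway(c(0, 120.5, 700), c(0, 33.25, -12))
  f <- tempfile(fileext = ".wkt")
  write_highway(hwy, f)
  back <- read_highway(f)
  expect_equal(back$x, hwy$x, tolerance = 1e-3)
  expect_equal(back$y, hwy$y, tolerance = 1e-3)
  poly <- hr_polygon(list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                          cbind(c(2, 4, 4, 2), c(2, 2, 4, 4))))
  g <- tempfile(fileext = ".wkt")
  write_polygon(poly, g)
  back2 <- read_polygon(g)
  expect_equal(length(back2$rings), 2)
  expect_equal(back2$area, poly$area, tolerance = 1e-6)
})

test_that("GeoJSON LineString input is accepted", {
  f <- tempfile(fileext = ".json")
  writeLines('{"type": "LineString", "coordinates": [[0, 0], [100, 50]]}', f)
  hwy <- read_highway(f)
  expect_equal(hwy$length, sqrt(100^2 + 50^2))
})
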