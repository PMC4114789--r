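test_that("crossings are consecutive same-session opposite-side pairs", {
  hw <- straight_highway()
  ev <- detect_crossings(toy_track(c(100, 120), c(50, -30)), hw)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$chainage, 100); expect_lt(ev$chainage, 120)

  expect_equal(nrow(detect_crossings(toy_track(c(0, 50), c(40, 80)), hw)), 0)

  # opposite sides but different sessions: no crossing
  fx <- data.frame(animal_id = "a", session_id = c(1, 2),
                   timestamp = c(0, 1440), x = c(100, 120), y = c(50, -30),
                   active = TRUE)
  expect_equal(nrow(detect_crossings(animal_track(fx), hw)), 0)

  # a fix exactly on the line is not a side change
  on_line <- toy_track(c(0, 10, 20), c(30, 0, 40))
  expect_equal(nrow(detect_crossings(on_line, hw)), 0)
})

test_that("crossing chainage picks the intersection nearest the start", {
  # chord crossing a bent highway twice
  bent <- highway(c(0, 200, 400), c(0, 200, 0))
  ev <- detect_crossings(toy_track(c(0, 400), c(50, -50)), bent)
  expect_equal(nrow(ev), 1)
  ints <- roadresponse:::hw_segment_intersections(0, 50, 400, -50, bent)
  expect_equal(ev$chainage, ints$chainage[1])
})

test_that("crossing parity matches side changes over a session", {
  set.seed(12)
  hw <- straight_highway()
  for (i in 1:10) {
    y <- cumsum(rnorm(15, 0, 60))
    tr <- toy_track(seq(100, by = 40, length.out = 15), y)
    ev <- detect_crossings(tr, hw)
    sides <- sign(y)
    expect_equal(nrow(ev) %% 2, (sides[1] != sides[15]) * 1L %% 2)
  }
})

test_that("UD_cross concentrates at crossing locations and normalizes", {
  hw <- straight_highway()
  pars <- brb_params(tau = 5, h_min = 30, D = 10)
  # single symmetric crossing at x = 3000
  tr <- toy_track(c(3000, 3000), c(80, -80))
  uc <- ud_cross(detect_crossings(tr, hw), pars, hw, band = 200,
                 bin_width = 250)
  expect_false(uc$zero_crossings)
  expect_equal(sum(uc$profile$density), 1)
  mode_bin <- which.max(uc$profile$density)
  expect_equal(findInterval(3000, uc$profile$edges), mode_bin)
  expect_lt(abs(sum(uc$ud$z) - 1), 1e-6)
  # mask: all mass within the band
  cc <- roadresponse:::ud_cell_centers(uc$ud)
  gx <- rep(cc$x, times = length(cc$y)); gy <- rep(cc$y, each = length(cc$x))
  far <- distance_bearing_side(gx, gy, hw)$distance > 200
  expect_equal(sum(uc$ud$z[matrix(far, nrow(uc$ud$z))]), 0)
})

test_that("two separated crossings give a bimodal profile", {
  hw <- straight_highway()
  fx <- rbind(
    data.frame(animal_id = "a", session_id = 1, timestamp = c(0, 30),
               x = 2000, y = c(60, -60), active = TRUE),
    data.frame(animal_id = "a", session_id = 2, timestamp = 1440 + c(0, 30),
               x = 7000, y = c(-60, 60), active = TRUE))
  uc <- ud_cross(detect_crossings(animal_track(fx), hw),
                 brb_params(tau = 5, h_min = 30, D = 10), hw)
  d <- uc$profile$density
  b1 <- findInterval(2000, uc$profile$edges)
  b2 <- findInterval(7000, uc$profile$edges)
  top2 <- order(d, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(b1, b2))
})

test_that("profile equals a direct kernel recomputation on highway samples", {
  hw <- straight_highway()
  pars <- brb_params(tau = 5, h_min = 40, D = 20)
  tr <- toy_track(c(4000, 4100), c(90, -110))
  ev <- detect_crossings(tr, hw)
  uc <- ud_cross(ev, pars, hw, band = 200, bin_width = 500)
  # oracle: rebuild the masked UD by brute force, then bin highway samples
  st <- build_steps(tr)
  pts <- interpolate_steps(st, pars)
  ud <- uc$ud
  cc <- roadresponse:::ud_cell_centers(ud)
  z <- matrix(0, length(cc$x), length(cc$y))
  for (k in seq_len(nrow(pts)))
    for (j in seq_along(cc$y))
      z[, j] <- z[, j] + pts$w[k] * dnorm(cc$x, pts$x[k], pts$h[k]) *
        dnorm(cc$y[j], pts$y[k], pts$h[k])
  z <- z / sum(z)
  gx <- rep(cc$x, times = length(cc$y)); gy <- rep(cc$y, each = length(cc$x))
  z[matrix(distance_bearing_side(gx, gy, hw)$distance > 200, nrow(z))] <- 0
  z <- z / sum(z)
  ch <- seq(0, hw$length, by = ud$cell / 2)
  vals <- roadresponse:::ud_value_at(ud_raster(ud$x0, ud$y0, ud$cell, z),
                                     ch, rep(0, length(ch)))
  bin <- findInterval(ch, uc$profile$edges, rightmost.closed = TRUE)
  dens <- vapply(seq_along(uc$profile$density), function(b)
    if (any(bin == b)) mean(vals[bin == b]) else 0, 1)
  dens <- dens / sum(dens)
  expect_equal(uc$profile$density, dens, tolerance = 1e-9)
})

test_that("zero crossings yield an explicit empty profile", {
  hw <- straight_highway()
  uc <- ud_cross(detect_crossings(toy_track(c(0, 50), c(40, 90)), hw),
                 brb_params(D = 10), hw)
  expect_true(uc$zero_crossings)
  expect_null(uc$ud)
  expect_equal(sum(uc$profile$density), 0)
})
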