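test_that("bridge bandwidth collapses at endpoints and peaks mid-step", {
  h <- roadresponse:::brb_bandwidth
  expect_equal(h(0, 40, 10, 50), 10)
  expect_equal(h(1, 40, 10, 50), 10)
  # h_max^2 = h_min^2 + D*T/2 = 100 + 1000
  expect_equal(h(0.5, 40, 10, 50)^2, 1100)
  expect_true(all(diff(h(seq(0, 0.5, 0.05), 40, 10, 50)) > 0))
})

test_that("interpolated weights sum to step shares of total duration", {
  tr <- toy_track(c(0, 100, 150), c(0, 50, 0), t = c(0, 30, 70))
  pts <- interpolate_steps(tr, brb_params(tau = 5, h_min = 10, D = 20))
  expect_equal(sum(pts$w), 1)
  # per-step share: group points by x-position membership on each chord
  st <- build_steps(tr)
  total <- sum(st$duration)
  # first step contributes points with x in (0, 100)
  w1 <- sum(pts$w[pts$x < 100 - 1e-9])
  expect_equal(w1, st$duration[1] / total, tolerance = 1e-12)
})

test_that("UD equals the naive kernel-sum oracle and conserves mass", {
  tr <- toy_track(c(0, 100, 150), c(0, 50, 0))
  pars <- brb_params(tau = 5, h_min = 20, D = 10)
  g <- grid_spec(c(-150, 300), c(-150, 200), cell = 10)
  ud <- estimate_ud(tr, pars, g)
  expect_lt(abs(sum(ud$z) - 1), 1e-6)
  pts <- interpolate_steps(tr, pars)
  xs <- seq(-145, 300, by = 10); ys <- seq(-145, 200, by = 10)
  z <- matrix(0, length(xs), length(ys))
  for (k in seq_len(nrow(pts)))
    for (j in seq_along(ys))
      z[, j] <- z[, j] + pts$w[k] * dnorm(xs, pts$x[k], pts$h[k]) *
        dnorm(ys[j], pts$y[k], pts$h[k])
  z <- z / sum(z)
  expect_lt(max(abs(z - ud$z)), 1e-9)
})

test_that("degenerate tracks give a stationary Gaussian kernel", {
  tr <- toy_track(c(500, 500, 500), c(500, 500, 500))
  pars <- brb_params(tau = 5, h_min = 25, D = 0, L_min = 5)
  g <- grid_spec(c(300, 700), c(300, 700), cell = 10)
  ud <- estimate_ud(tr, pars, g)
  expect_lt(abs(sum(ud$z) - 1), 1e-6)
  cc <- roadresponse:::ud_cell_centers(ud)
  ref <- outer(dnorm(cc$x, 500, 25), dnorm(cc$y, 500, 25))
  expect_lt(max(abs(ud$z - ref / sum(ref))), 1e-9)
})

test_that("the UD ridge follows the movement chord", {
  tr <- toy_track(c(0, 100), c(0, 0))
  ud <- estimate_ud(tr, brb_params(tau = 2, h_min = 15, D = 10),
                    grid_spec(c(-100, 200), c(-100, 100), cell = 5))
  expect_gt(roadresponse:::ud_value_at(ud, 50, 0),
            roadresponse:::ud_value_at(ud, 50, 60))
})

test_that("diffusion MLE matches a grid-search oracle and recovers truth", {
  set.seed(5)
  D <- 30; dt <- 30; n <- 500
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt))))
  tr <- toy_track(x, y, t = (0:(n - 1)) * dt)
  Dhat <- estimate_diffusion(tr)
  expect_gt(Dhat, 20); expect_lt(Dhat, 40)
  grid <- seq(max(0.5, Dhat - 10), Dhat + 10, by = 0.01)
  ll <- vapply(grid, function(d) roadresponse:::diffusion_loglik(tr, d), 1)
  expect_lt(abs(grid[which.max(ll)] - Dhat), 0.02)
  # perfectly linear uniform-speed track: bridges predict exactly, D -> 0
  lin <- toy_track(seq(0, 900, by = 100), seq(0, 450, by = 50))
  expect_lt(estimate_diffusion(lin), 1e-10)
  expect_error(estimate_diffusion(toy_track(c(0, 1), c(0, 0))), ">= 3 fixes")
})

test_that("isopleths select cells in descending mass order", {
  # single cell holding all mass
  z <- matrix(0, 5, 5); z[3, 3] <- 1
  ud <- ud_raster(0, 0, 10, z)
  iso <- isopleth(ud, 0.95)
  expect_equal(sum(attr(iso, "cells")), 1)
  expect_equal(iso$area, 100)
  expect_true(contains(iso, 25, 25))

  # uniform UD over 100 cells, level 0.95 -> 95 cells
  u <- ud_raster(0, 0, 1, matrix(1 / 100, 10, 10))
  expect_equal(sum(attr(isopleth(u, 0.95), "cells")), 95)

  # random UD: selection equals the sort-and-accumulate oracle
  set.seed(8)
  z <- matrix(rexp(400), 20, 20); z <- z / sum(z)
  ud2 <- ud_raster(0, 0, 30, z)
  iso2 <- isopleth(ud2, 0.95)
  o <- order(z, decreasing = TRUE)
  k <- which(cumsum(z[o]) >= 0.95)[1]
  oracle <- matrix(FALSE, 20, 20); oracle[o[1:k]] <- TRUE
  expect_identical(attr(iso2, "cells"), oracle)
  m <- attr(iso2, "mass")
  expect_gte(m, 0.95)
  expect_lte(m, 0.95 + max(z))
})

test_that("isopleth area is monotone in level and traces clean boundaries", {
  set.seed(9)
  tr <- toy_track(cumsum(rnorm(12, 0, 80)), cumsum(rnorm(12, 0, 80)))
  ud <- estimate_ud(tr, brb_params(tau = 5, h_min = 30, D = 20))
  areas <- vapply(c(0.5, 0.7, 0.9, 0.95), function(l) isopleth(ud, l)$area, 1)
  expect_true(all(diff(areas) >= 0))
  iso <- isopleth(ud, 0.95)
  # boundary tracing: every selected cell center is inside the polygon
  sel <- attr(iso, "cells")
  cc <- roadresponse:::ud_cell_centers(ud)
  idx <- which(sel, arr.ind = TRUE)
  expect_true(all(contains(iso, cc$x[idx[, 1]], cc$y[idx[, 2]])))
  out <- which(!sel, arr.ind = TRUE)
  some <- out[seq(1, nrow(out), length.out = 50), , drop = FALSE]
  expect_false(any(contains(iso, cc$x[some[, 1]], cc$y[some[, 2]])))
})

test_that("halving tau barely changes the converged UD", {
  tr <- toy_track(c(0, 120, 300), c(0, 80, 20), t = c(0, 40, 80))
  g <- grid_spec(c(-200, 500), c(-200, 300), cell = 20)
  u1 <- estimate_ud(tr, brb_params(tau = 4, h_min = 30, D = 20), g)
  u2 <- estimate_ud(tr, brb_params(tau = 2, h_min = 30, D = 20), g)
  expect_lt(max(abs(u1$z - u2$z)), 0.01 * max(u1$z))
})

test_that("UD rasters survive the ASCII grid round trip", {
  set.seed(3)
  z <- matrix(rexp(64), 8, 8); z <- z / sum(z)
  ud <- ud_raster(100, -50, 25, z)
  f <- tempfile(fileext = ".asc")
  write_ud(ud, f)
  back <- read_ud(f)
  expect_equal(back$z, ud$z, tolerance = 1e-8)
  expect_equal(back$cell, 25)
  expect_equal(back$x0, 100)
})
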