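# Shared fixture builders; everything is generated in code, no data files.

straight_highway <- function(len = 10000) highway(c(0, len), c(0, 0))

unit_square <- function() hr_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))

big_square <- function(half = 5000) {
  hr_polygon(cbind(c(-half, half, half, -half), c(-half, -half, half, half)))
}

# track from bare coordinate/time vectors, one session
toy_track <- function(x, y, t = seq_along(x) * 30 - 30, session = 1,
                      active = TRUE, id = "toy") {
  animal_track(data.frame(animal_id = id, session_id = session,
                          timestamp = t, x = x, y = y, active = active))
}

# random jagged polyline for geometry oracle tests
random_polyline <- function(n = 5) {
  highway(cumsum(runif(n, 50, 500)), cumsum(runif(n, -300, 300)))
}

# brute-force point-to-polyline by dense sampling at `by` meters
dense_nearest <- function(px, py, hwy, by = 0.01) {
  ch <- seq(0, hwy$length, by = by)
  pt <- roadresponse:::hw_point_at(ch, hwy)
  d2 <- (pt$x - px)^2 + (pt$y - py)^2
  k <- which.min(d2)
  list(distance = sqrt(d2[k]), chainage = ch[k],
       bearing = atan2(pt$y[k] - py, pt$x[k] - px))
}
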