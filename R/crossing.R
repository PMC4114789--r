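#' Detect highway crossings in a track
#'
#' A crossing is a pair of consecutive fixes in the same tracking session
#' recorded on strictly opposite sides of the highway (side signs -1/+1;
#' a fix exactly on the line is no side change). The crossing chainage is
#' where the straight chord between the two fixes intersects the polyline
#' (the intersection nearest the start fix if the chord cuts several
#' times).
#'
#' @param track an [animal_track()] or [build_steps()] table.
#' @param hwy a [highway()].
#' @param max_gap step gap rule (min) when building steps from a track.
#' @return data.frame of class `crossing_events`: session_id, t0, t1,
#'   x0, y0, x1, y1, chainage.
#' @export
detect_crossings <- function(track, hwy, max_gap = 90) {
  steps <- if (inherits(track, "steps")) track else build_steps(track, max_gap)
  empty <- structure(data.frame(session_id = character(0), t0 = numeric(0),
                                t1 = numeric(0), x0 = numeric(0),
                                y0 = numeric(0), x1 = numeric(0),
                                y1 = numeric(0), chainage = numeric(0)),
                     class = c("crossing_events", "data.frame"))
  if (nrow(steps) == 0) return(empty)
  s0 <- hw_locate(steps$x0, steps$y0, hwy)$side
  s1 <- hw_locate(steps$x1, steps$y1, hwy)$side
  idx <- which(s0 * s1 == -1L)
  if (length(idx) == 0) return(empty)
  ch <- vapply(idx, function(k) {
    xi <- hw_segment_intersections(steps$x0[k], steps$y0[k],
                                   steps$x1[k], steps$y1[k], hwy)
    if (nrow(xi) == 0) {
      # opposite side signs but the finite polyline missed the chord
      # (crossing beyond the mapped section); clamp to nearest chainage
      chainage_of_point((steps$x0[k] + steps$x1[k]) / 2,
                        (steps$y0[k] + steps$y1[k]) / 2, hwy)
    } else xi$chainage[1]
  }, numeric(1))
  structure(data.frame(session_id = steps$session_id[idx],
                       t0 = steps$t0[idx], t1 = steps$t1[idx],
                       x0 = steps$x0[idx], y0 = steps$y0[idx],
                       x1 = steps$x1[idx], y1 = steps$y1[idx],
                       chainage = ch),
            class = c("crossing_events", "data.frame"))
}

#' Along-highway chainage profile
#'
#' @param edges bin edges (m) along the highway chainage.
#' @param density per-bin values, >= 0 (normalized to sum 1 where stated).
#' @return list of class `chainage_profile`.
#' @export
chainage_profile <- function(edges, density) {
  stopifnot(length(edges) == length(density) + 1, all(diff(edges) > 0),
            all(density >= 0))
  structure(list(edges = edges, density = density),
            class = "chainage_profile")
}

#' @export
print.chainage_profile <- function(x, ...) {
  cat(sprintf("Chainage profile: %d bins over [%.0f, %.0f] m\n",
              length(x$density), min(x$edges), max(x$edges)))
  invisible(x)
}

#' Crossing-location utilization distribution (UD_cross)
#'
#' Each crossing fix pair is treated as a two-point track and smoothed
#' with the same biased-random-bridge estimator as the full UD. The
#' resulting surface is masked to cells within `band` of the highway and
#' renormalized, then projected onto the highway: the polyline is sampled
#' densely, each sample reads the UD cell it falls in, and samples are
#' averaged within chainage bins; the bin values are normalized to sum 1.
#'
#' @param events a [detect_crossings()] result with >= 1 row (0 rows give
#'   an all-zero profile flagged `zero_crossings`).
#' @param params [brb_params()] with `D` set.
#' @param hwy a [highway()].
#' @param band mask half-width around the highway (m); 200 m focuses the
#'   surface on the immediate crossing zone.
#' @param bin_width chainage bin width (m).
#' @param grid optional [grid_spec()].
#' @return list of class `ud_cross`: `ud` (masked [ud_raster()] or NULL),
#'   `profile` (a [chainage_profile()]), `n_events`, `zero_crossings`.
#' @export
ud_cross <- function(events, params, hwy, band = 200, bin_width = 250,
                     grid = NULL) {
  edges <- seq(0, hwy$length + bin_width, by = bin_width)
  if (nrow(events) == 0)
    return(structure(list(ud = NULL,
                          profile = chainage_profile(edges, rep(0, length(edges) - 1)),
                          n_events = 0L, zero_crossings = TRUE),
                     class = "ud_cross"))
  steps <- structure(data.frame(session_id = events$session_id,
                                x0 = events$x0, y0 = events$y0,
                                x1 = events$x1, y1 = events$y1,
                                t0 = events$t0, t1 = events$t1,
                                length = sqrt((events$x1 - events$x0)^2 +
                                              (events$y1 - events$y0)^2),
                                duration = events$t1 - events$t0,
                                heading = atan2(events$y1 - events$y0,
                                                events$x1 - events$x0),
                                active0 = TRUE, active1 = TRUE),
                     class = c("steps", "data.frame"))
  # keep crossing steps regardless of the general gap rule
  params$T_max <- max(params$T_max, max(steps$duration))
  full <- estimate_ud(steps, params, grid)
  cc <- ud_cell_centers(full)
  gx <- rep(cc$x, times = length(cc$y))
  gy <- rep(cc$y, each = length(cc$x))
  near <- hw_locate(gx, gy, hwy)$distance <= band
  z <- full$z
  z[!matrix(near, nrow(z), ncol(z))] <- 0
  if (sum(z) <= 0) stop("no UD mass within the highway band")
  masked <- ud_raster(full$x0, full$y0, full$cell, z / sum(z))
  # sample the polyline at half-cell spacing and bin by chainage
  ch <- seq(0, hwy$length, by = masked$cell / 2)
  pt <- hw_point_at(ch, hwy)
  vals <- ud_value_at(masked, pt$x, pt$y)
  bin <- findInterval(ch, edges, rightmost.closed = TRUE)
  dens <- vapply(seq_len(length(edges) - 1),
                 function(b) if (any(bin == b)) mean(vals[bin == b]) else 0,
                 numeric(1))
  if (sum(dens) > 0) dens <- dens / sum(dens)
  structure(list(ud = masked, profile = chainage_profile(edges, dens),
                 n_events = nrow(events), zero_crossings = FALSE),
            class = "ud_cross")
}

#' @export
print.ud_cross <- function(x, ...) {
  if (x$zero_crossings) cat("UD_cross: no crossings observed\n")
  else cat(sprintf("UD_cross: %d crossing events, %d profile bins\n",
                   x$n_events, length(x$profile$density)))
  invisible(x)
}
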