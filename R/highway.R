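#' Highway (linear barrier) geometry
#'
#' A highway is an ordered planar polyline in projected meter coordinates.
#' Chainage is the arc-length coordinate along it: 0 at the first vertex,
#' the total length at the last.
#'
#' @param x,y numeric vectors of vertex coordinates (m), length >= 2.
#' @return an object of class `highway`: vertices plus cached segment
#'   lengths and cumulative chainage.
#' @export
#' @examples
#' hw <- highway(c(0, 10000), c(0, 0))
#' hw$length
highway <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  dx <- diff(x); dy <- diff(y)
  seg_len <- sqrt(dx^2 + dy^2)
  if (any(seg_len == 0)) stop("consecutive highway vertices must be distinct")
  structure(list(x = x, y = y,
                 seg_len = seg_len,
                 cum_len = c(0, cumsum(seg_len)),
                 length = sum(seg_len)),
            class = "highway")
}

#' @export
print.highway <- function(x, ...) {
  cat(sprintf("Highway polyline: %d vertices, %.1f m total length\n",
              length(x$x), x$length))
  invisible(x)
}

#' Passages (crossing structures) along a highway
#'
#' @param chainage numeric vector of positions along the highway (m).
#' @param kind character vector, one of `"culvert"`, `"underpass"`,
#'   `"overpass"` per passage.
#' @param hwy the [highway()] the passages belong to (used for validation).
#' @return data.frame of class `passages` with columns chainage, kind.
#' @export
passages <- function(chainage, kind = "culvert", hwy = NULL) {
  kind <- rep_len(kind, length(chainage))
  stopifnot(all(kind %in% c("culvert", "underpass", "overpass")))
  if (!is.null(hwy)) {
    if (any(chainage < 0 | chainage > hwy$length))
      stop("passage chainage outside the highway extent")
  }
  structure(data.frame(chainage = chainage, kind = kind),
            class = c("passages", "data.frame"))
}

# Vectorized point-to-polyline location. For each point returns the nearest
# point on the polyline, the distance, the bearing of the point->nearest
# vector, the chainage of the nearest point, and the side sign.
#
# Side is the sign of the 2-D cross product of the local segment direction
# with the vector segment-start -> point: +1 left of the traversal
# direction, -1 right, 0 exactly on the line.
hw_locate <- function(px, py, hwy) {
  stopifnot(inherits(hwy, "highway"))
  if (hwy$length <= 0) stop("degenerate highway (zero length)")
  n <- length(px)
  nseg <- length(hwy$seg_len)
  x0 <- hwy$x[-length(hwy$x)]; y0 <- hwy$y[-length(hwy$y)]
  dx <- diff(hwy$x); dy <- diff(hwy$y)
  L2 <- hwy$seg_len^2

  best_d2 <- rep(Inf, n)
  best_t <- best_seg <- numeric(n)
  best_nx <- best_ny <- numeric(n)
  for (s in seq_len(nseg)) {
    t <- ((px - x0[s]) * dx[s] + (py - y0[s]) * dy[s]) / L2[s]
    t <- pmin(1, pmax(0, t))
    nx <- x0[s] + t * dx[s]; ny <- y0[s] + t * dy[s]
    d2 <- (px - nx)^2 + (py - ny)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_t[upd] <- t[upd]; best_seg[upd] <- s
    best_nx[upd] <- nx[upd]; best_ny[upd] <- ny[upd]
  }
  dist <- sqrt(best_d2)
  cross <- dx[best_seg] * (py - y0[best_seg]) - dy[best_seg] * (px - x0[best_seg])
  side <- sign(cross)
  side[dist == 0] <- 0
  bearing <- ifelse(dist == 0, 0, atan2(best_ny - py, best_nx - px))
  list(distance = dist,
       bearing = wrap_angle(bearing),
       side = as.integer(side),
       chainage = hwy$cum_len[best_seg] + best_t * hwy$seg_len[best_seg],
       nx = best_nx, ny = best_ny)
}

#' Distance, bearing and side of a point relative to the highway
#'
#' The bearing is the direction of the vector from the point to the nearest
#' point on the polyline (the animal-to-highway angle), counter-clockwise
#' from +x, wrapped to (-pi, pi]. The side is +1 to the left of the
#' traversal direction, -1 to the right, and 0 only for points exactly on
#' the line (for which the bearing is reported as 0 by convention).
#'
#' @param px,py point coordinates (m); vectorized.
#' @param hwy a [highway()].
#' @return data.frame with columns `distance`, `bearing`, `side`.
#' @export
#' @examples
#' hw <- highway(c(0, 10000), c(0, 0))
#' distance_bearing_side(0, 100, hw) # 100 m, bearing -pi/2, side +1
distance_bearing_side <- function(px, py, hwy) {
  stopifnot(all(is.finite(px)), all(is.finite(py)))
  loc <- hw_locate(px, py, hwy)
  data.frame(distance = loc$distance, bearing = loc$bearing, side = loc$side)
}

#' Chainage of the nearest highway point
#'
#' Arc-length position (m) along the highway of the point on the polyline
#' nearest to the query point, in [0, total length]. Points beyond the
#' polyline ends clamp to the terminal vertices.
#'
#' @inheritParams distance_bearing_side
#' @return numeric vector of chainages (m).
#' @export
chainage_of_point <- function(px, py, hwy) {
  stopifnot(all(is.finite(px)), all(is.finite(py)))
  hw_locate(px, py, hwy)$chainage
}

# Point at a given chainage, plus the local unit tangent. Used by the
# synthetic generator (passage-faithful crossings) and profile sampling.
hw_point_at <- function(chainage, hwy) {
  chainage <- pmin(hwy$length, pmax(0, chainage))
  seg <- findInterval(chainage, hwy$cum_len, rightmost.closed = TRUE)
  seg <- pmin(seg, length(hwy$seg_len))
  t <- (chainage - hwy$cum_len[seg]) / hwy$seg_len[seg]
  dx <- diff(hwy$x); dy <- diff(hwy$y)
  list(x = hwy$x[seg] + t * dx[seg],
       y = hwy$y[seg] + t * dy[seg],
       tx = dx[seg] / hwy$seg_len[seg],
       ty = dy[seg] / hwy$seg_len[seg])
}

# Intersections of the segment (x0,y0)-(x1,y1) with the polyline.
# Returns a data.frame (possibly 0-row) with the chord parameter t in [0,1],
# the chainage at each intersection, sorted by t.
hw_segment_intersections <- function(x0, y0, x1, y1, hwy) {
  dx <- x1 - x0; dy <- y1 - y0
  hx0 <- hwy$x[-length(hwy$x)]; hy0 <- hwy$y[-length(hwy$y)]
  hdx <- diff(hwy$x); hdy <- diff(hwy$y)
  denom <- dx * hdy - dy * hdx
  ok <- abs(denom) > 1e-12
  t <- (((hx0 - x0) * hdy - (hy0 - y0) * hdx) / denom)[ok]
  u <- ((hx0 - x0) * dy - (hy0 - y0) * dx)[ok] / denom[ok]
  seg <- which(ok)
  keep <- t >= 0 & t <= 1 & u >= 0 & u <= 1
  res <- data.frame(t = t[keep],
                    chainage = hwy$cum_len[seg[keep]] + u[keep] * hwy$seg_len[seg[keep]])
  res[order(res$t), , drop = FALSE]
}

#' Read a highway polyline from WKT or GeoJSON
#'
#' Accepts a file containing either a WKT `LINESTRING (...)` or a GeoJSON
#' geometry/feature with a LineString. Coordinates must already be in a
#' projected meter CRS.
#'
#' @param path file path.
#' @return a [highway()].
#' @export
read_highway <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^[[:space:]]*LINESTRING", txt, ignore.case = TRUE)) {
    body <- sub(".*LINESTRING[[:space:]]*\\(", "", txt, ignore.case = TRUE)
    body <- sub("\\).*", "", body)
    pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "[[:space:]]+")
    xy <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  } else {
    gj <- yaml::yaml.load(txt)  # JSON is a YAML subset
    geom <- if (!is.null(gj$geometry)) gj$geometry else gj
    if (!identical(geom$type, "LineString"))
      stop("expected a LineString geometry")
    xy <- do.call(rbind, lapply(geom$coordinates, function(p) as.numeric(p[1:2])))
  }
  highway(xy[, 1], xy[, 2])
}

#' Write a highway polyline as WKT
#'
#' @param hwy a [highway()].
#' @param path output file path.
#' @export
write_highway <- function(hwy, path) {
  coords <- paste(sprintf("%.3f %.3f", hwy$x, hwy$y), collapse = ", ")
  writeLines(sprintf("LINESTRING (%s)", coords), path)
}
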