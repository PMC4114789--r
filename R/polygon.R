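#' Home-range polygon
#'
#' One or more closed rings of planar points (m). Containment uses the
#' even-odd rule across all rings, so interior rings act as holes and
#' multi-part ranges are supported. Points on a ring edge count as inside.
#'
#' @param rings a single n x 2 matrix, or a list of such matrices. Rings
#'   need not repeat the first vertex; they are treated as closed.
#' @return object of class `hr_polygon` with elements `rings` and `area`
#'   (m^2, even-odd: hole areas subtract).
#' @export
#' @examples
#' sq <- hr_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' sq$area
hr_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, all(is.finite(r)))
    # drop an explicitly repeated closing vertex
    if (nrow(r) > 1 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) stop("polygon ring needs >= 3 distinct vertices")
    r
  })
  area <- sum(vapply(rings, ring_area, numeric(1)))
  if (area <= 0) stop("polygon area must be > 0")
  structure(list(rings = rings, area = area), class = "hr_polygon")
}

#' @export
print.hr_polygon <- function(x, ...) {
  cat(sprintf("Polygon: %d ring(s), area %.3f km^2\n",
              length(x$rings), x$area / 1e6))
  invisible(x)
}

# Shoelace |area| of one ring
ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Point-in-polygon test
#'
#' Even-odd (ray casting) rule over all rings; points on a ring edge are
#' inside by convention (the home-range boundary belongs to the range).
#'
#' @param poly an [hr_polygon()].
#' @param px,py point coordinates (vectorized).
#' @param tol edge tolerance (m) for the boundary-counts-as-inside rule.
#' @return logical vector.
#' @export
contains <- function(poly, px, py, tol = 1e-9) {
  stopifnot(inherits(poly, "hr_polygon"))
  n <- length(px)
  inside <- logical(n)
  on_edge <- logical(n)
  for (r in poly$rings) {
    x0 <- r[, 1]; y0 <- r[, 2]
    x1 <- c(x0[-1], x0[1]); y1 <- c(y0[-1], y0[1])
    ex <- x1 - x0; ey <- y1 - y0
    el2 <- ex^2 + ey^2
    for (i in seq_len(n)) {
      if (on_edge[i]) next
      # edge proximity
      t <- ((px[i] - x0) * ex + (py[i] - y0) * ey) / el2
      t <- pmin(1, pmax(0, t))
      d2 <- (px[i] - (x0 + t * ex))^2 + (py[i] - (y0 + t * ey))^2
      if (any(d2 <= tol^2)) { on_edge[i] <- TRUE; next }
      # even-odd crossings of the upward ray
      crosses <- ((y0 > py[i]) != (y1 > py[i])) &
        (px[i] < x0 + (py[i] - y0) / (y1 - y0) * ex)
      inside[i] <- xor(inside[i], sum(crosses) %% 2 == 1)
    }
  }
  inside | on_edge
}

# First exit of the ray p0 + s*dir (s in (0, len]) through any ring edge.
# Returns len if the whole segment stays inside-capable (no intersection).
# Used by the null model's boundary-truncation fallback.
ray_boundary_distance <- function(poly, x0, y0, dir, len) {
  x1 <- x0 + len * cos(dir); y1 <- y0 + len * sin(dir)
  smin <- Inf
  for (r in poly$rings) {
    rx0 <- r[, 1]; ry0 <- r[, 2]
    rdx <- c(rx0[-1], rx0[1]) - rx0; rdy <- c(ry0[-1], ry0[1]) - ry0
    dx <- x1 - x0; dy <- y1 - y0
    denom <- dx * rdy - dy * rdx
    ok <- abs(denom) > 1e-12
    t <- (((rx0 - x0) * rdy - (ry0 - y0) * rdx) / denom)[ok]
    u <- ((rx0 - x0) * dy - (ry0 - y0) * dx)[ok] / denom[ok]
    hit <- t > 1e-9 & t <= 1 & u >= 0 & u <= 1
    if (any(hit)) smin <- min(smin, min(t[hit]) * len)
  }
  if (is.finite(smin)) smin else len
}

#' Read a polygon from WKT
#'
#' Accepts `POLYGON ((...))` or `MULTIPOLYGON` WKT; all rings are collected
#' into one even-odd [hr_polygon()].
#'
#' @param path file path.
#' @return an [hr_polygon()].
#' @export
read_polygon <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  ring_strs <- regmatches(txt, gregexpr("\\(([^()]+)\\)", txt))[[1]]
  rings <- lapply(ring_strs, function(s) {
    s <- gsub("[()]", "", s)
    pairs <- strsplit(trimws(strsplit(s, ",")[[1]]), "[[:space:]]+")
    do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  })
  hr_polygon(rings)
}

#' Write a polygon as WKT
#'
#' @param poly an [hr_polygon()].
#' @param path output file path.
#' @export
write_polygon <- function(poly, path) {
  rs <- vapply(poly$rings, function(r) {
    r <- rbind(r, r[1, ])
    sprintf("(%s)", paste(sprintf("%.3f %.3f", r[, 1], r[, 2]), collapse = ", "))
  }, character(1))
  writeLines(sprintf("POLYGON (%s)", paste(rs, collapse = ", ")), path)
}
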