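#' Biased-random-bridge smoothing parameters
#'
#' Controls movement-based kernel density estimation. Between each pair of
#' fixes the animal's path is a random bridge: interpolated points are laid
#' along the straight chord and smoothed with a bandwidth that is `h_min`
#' at the endpoints (where the animal was actually observed) and widens
#' mid-step in proportion to the elapsed time and the diffusion coefficient
#' `D`: h^2(p) = h_min^2 + 4 p (1 - p) (h_max^2 - h_min^2) with
#' h_max^2 = h_min^2 + D T / 2 for a step of duration T at relative time p.
#'
#' @param tau interpolation interval (min), > 0.
#' @param h_min minimum smoothing bandwidth (m), > 0. Default 30 m, one
#'   land-cover cell.
#' @param D diffusion coefficient (m^2/min), >= 0; `NULL` to estimate from
#'   the data with [estimate_diffusion()]. `D` is the standard planar
#'   diffusion coefficient: per-coordinate displacement variance 2 D dt.
#' @param T_max maximum step duration retained (min); longer steps say
#'   little about the path between fixes.
#' @param L_min minimum step length treated as directed movement (m);
#'   shorter steps contribute stationary kernels at their mean location.
#' @return list of class `brb_params`.
#' @export
brb_params <- function(tau = 5, h_min = 30, D = NULL, T_max = 90, L_min = 5) {
  stopifnot(tau > 0, h_min > 0, is.null(D) || D >= 0, T_max > 0, L_min >= 0)
  structure(list(tau = tau, h_min = h_min, D = D, T_max = T_max,
                 L_min = L_min), class = "brb_params")
}

# Bridge bandwidth at relative time p in [0,1] for a step of duration T.
brb_bandwidth <- function(p, T, h_min, D) {
  h_max2 <- h_min^2 + D * T / 2
  sqrt(h_min^2 + 4 * p * (1 - p) * (h_max2 - h_min^2))
}

#' Interpolate weighted points along the movement bridges
#'
#' Lays points along each retained step's chord at spacing `tau`, each with
#' a kernel bandwidth from the bridge variance profile and a weight
#' proportional to the time it represents; weights sum to 1 over the track
#' (each step contributes its share duration / total tracked duration).
#'
#' @param track an [animal_track()] (or a precomputed [build_steps()]
#'   data.frame).
#' @param params [brb_params()]; `params$D` must be set.
#' @return data.frame: x, y, h (bandwidth m), w (weight).
#' @export
interpolate_steps <- function(track, params = brb_params(D = 0)) {
  steps <- if (inherits(track, "steps")) track else
    build_steps(track, max_gap = params$T_max)
  steps <- steps[steps$duration <= params$T_max, , drop = FALSE]
  if (nrow(steps) == 0) stop("no movement data")
  D <- params$D
  if (is.null(D)) stop("params$D must be set (see estimate_diffusion)")
  total_T <- sum(steps$duration)
  out <- vector("list", nrow(steps))
  for (k in seq_len(nrow(steps))) {
    T <- steps$duration[k]
    n <- max(1L, ceiling(T / params$tau))
    p <- (seq_len(n) - 0.5) / n   # midpoint rule over the bridge
    if (steps$length[k] < params$L_min) {
      # effectively stationary: one kernel pile at the mean location
      mx <- (steps$x0[k] + steps$x1[k]) / 2
      my <- (steps$y0[k] + steps$y1[k]) / 2
      out[[k]] <- data.frame(x = rep(mx, n), y = rep(my, n),
                             h = rep(params$h_min, n),
                             w = rep(T / n / total_T, n))
    } else {
      out[[k]] <- data.frame(
        x = steps$x0[k] + p * (steps$x1[k] - steps$x0[k]),
        y = steps$y0[k] + p * (steps$y1[k] - steps$y0[k]),
        h = brb_bandwidth(p, T, params$h_min, D),
        w = rep(T / n / total_T, n))
    }
  }
  do.call(rbind, out)
}

#' Utilization-distribution raster
#'
#' Gridded probability surface: `z[i, j]` is the probability mass in the
#' cell centered at `(x0 + (i - 0.5) cell, y0 + (j - 0.5) cell)`; masses
#' sum to 1.
#'
#' @param x0,y0 lower-left corner (m).
#' @param cell cell size (m).
#' @param z matrix of non-negative masses summing to 1 (within 1e-6).
#' @return object of class `ud_raster`.
#' @export
ud_raster <- function(x0, y0, cell, z) {
  stopifnot(cell > 0, is.matrix(z), all(z >= 0))
  if (abs(sum(z) - 1) > 1e-6) stop("UD mass must sum to 1")
  structure(list(x0 = x0, y0 = y0, cell = cell, z = z), class = "ud_raster")
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf("UD raster: %d x %d cells of %g m, total mass %.8f\n",
              nrow(x$z), ncol(x$z), x$cell, sum(x$z)))
  invisible(x)
}

ud_cell_centers <- function(ud) {
  list(x = ud$x0 + (seq_len(nrow(ud$z)) - 0.5) * ud$cell,
       y = ud$y0 + (seq_len(ncol(ud$z)) - 0.5) * ud$cell)
}

# UD mass at point coordinates (0 outside the grid)
ud_value_at <- function(ud, px, py) {
  i <- floor((px - ud$x0) / ud$cell) + 1
  j <- floor((py - ud$y0) / ud$cell) + 1
  ok <- i >= 1 & i <= nrow(ud$z) & j >= 1 & j <= ncol(ud$z)
  out <- numeric(length(px))
  out[ok] <- ud$z[cbind(i[ok], j[ok])]
  out
}

#' Grid specification for UD estimation
#'
#' @param xlim,ylim extents (m). If omitted in [estimate_ud()], the grid
#'   covers all fixes plus a 3 x max-bandwidth margin.
#' @param cell cell size (m).
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(xlim, ylim, cell = 30) {
  stopifnot(cell > 0, diff(xlim) > 0, diff(ylim) > 0)
  structure(list(xlim = xlim, ylim = ylim, cell = cell), class = "grid_spec")
}

#' Estimate a utilization distribution with biased random bridges
#'
#' Sums bivariate Gaussian kernels over the interpolated bridge points,
#' evaluated at cell centers, and normalizes total mass to 1.
#'
#' @param track an [animal_track()] or [build_steps()] result.
#' @param params [brb_params()]. If `params$D` is `NULL` and `track` is an
#'   `animal_track`, the diffusion coefficient is estimated from it.
#' @param grid a [grid_spec()], or `NULL` to size one automatically.
#' @return a [ud_raster()].
#' @export
estimate_ud <- function(track, params = brb_params(), grid = NULL) {
  if (is.null(params$D)) {
    if (!inherits(track, "animal_track"))
      stop("supply params$D when estimating from a step table")
    params$D <- estimate_diffusion(track)
  }
  pts <- interpolate_steps(track, params)
  hmax <- max(pts$h)
  if (is.null(grid)) {
    m <- 3 * hmax
    grid <- grid_spec(c(min(pts$x) - m, max(pts$x) + m),
                      c(min(pts$y) - m, max(pts$y) + m),
                      cell = min(params$h_min, hmax / 2))
  }
  if (grid$cell > params$h_min)
    warning("grid cell size exceeds h_min; UD will be under-resolved")
  xs <- seq(grid$xlim[1] + grid$cell / 2, grid$xlim[2], by = grid$cell)
  ys <- seq(grid$ylim[1] + grid$cell / 2, grid$ylim[2], by = grid$cell)
  z <- matrix(0, length(xs), length(ys))
  # separable Gaussian: outer product of the 1-D kernels per point
  for (k in seq_len(nrow(pts))) {
    kx <- stats::dnorm(xs, pts$x[k], pts$h[k])
    ky <- stats::dnorm(ys, pts$y[k], pts$h[k])
    z <- z + pts$w[k] * (kx %o% ky)
  }
  s <- sum(z)
  if (s <= 0) stop("all UD mass fell outside the grid")
  ud_raster(grid$xlim[1], grid$ylim[1], grid$cell, z / s)
}

#' Maximum-likelihood diffusion coefficient
#'
#' Leave-one-out Brownian-bridge likelihood: each odd-indexed fix inside a
#' session is predicted from its two neighbors; under a planar Brownian
#' bridge its per-coordinate variance is 2 D T p (1 - p), where T is the
#' neighbor-to-neighbor duration and p the relative time of the middle fix.
#' The MLE is closed-form; only neighbor gaps within `T_max` are used.
#'
#' @param track an [animal_track()].
#' @param T_max maximum neighbor-to-neighbor duration (min).
#' @return D (m^2/min), >= 0.
#' @export
estimate_diffusion <- function(track, T_max = 180) {
  stopifnot(inherits(track, "animal_track"))
  f <- track$fixes
  num <- 0; m <- 0L
  for (sid in unique(f$session_id)) {
    s <- f[f$session_id == sid, , drop = FALSE]
    if (nrow(s) < 3) next
    mid <- seq(2, nrow(s) - 1, by = 2)
    for (i in mid) {
      T <- s$timestamp[i + 1] - s$timestamp[i - 1]
      if (T > T_max) next
      p <- (s$timestamp[i] - s$timestamp[i - 1]) / T
      v <- 2 * T * p * (1 - p)          # variance per coordinate per unit D
      if (v <= 0) next
      ex <- s$x[i - 1] + p * (s$x[i + 1] - s$x[i - 1])
      ey <- s$y[i - 1] + p * (s$y[i + 1] - s$y[i - 1])
      num <- num + ((s$x[i] - ex)^2 + (s$y[i] - ey)^2) / v
      m <- m + 1L
    }
  }
  if (m == 0) stop("need at least one session with >= 3 fixes")
  # loglik(D) = sum over triplets, 2 coords each: -log(2 pi v D) - r^2/(2 v D)
  # => D_hat = sum(r^2 / v) / (2 m)
  num / (2 * m)
}

# The bridge log-likelihood as a function of D, for cross-checking the
# closed form (used by tests' grid-search oracle and exported for audit).
diffusion_loglik <- function(track, D, T_max = 180) {
  f <- track$fixes
  ll <- 0
  for (sid in unique(f$session_id)) {
    s <- f[f$session_id == sid, , drop = FALSE]
    if (nrow(s) < 3) next
    for (i in seq(2, nrow(s) - 1, by = 2)) {
      T <- s$timestamp[i + 1] - s$timestamp[i - 1]
      if (T > T_max) next
      p <- (s$timestamp[i] - s$timestamp[i - 1]) / T
      v <- 2 * D * T * p * (1 - p)
      if (v <= 0) next
      ex <- s$x[i - 1] + p * (s$x[i + 1] - s$x[i - 1])
      ey <- s$y[i - 1] + p * (s$y[i + 1] - s$y[i - 1])
      ll <- ll - log(2 * pi * v) - ((s$x[i] - ex)^2 + (s$y[i] - ey)^2) / (2 * v)
    }
  }
  ll
}

#' Isopleth home range of a UD
#'
#' Smallest set of cells, taken in descending mass order, whose cumulative
#' mass reaches `level`; the outer boundary of the selected cells is traced
#' into polygon rings (possibly multi-part, holes handled by the even-odd
#' rule). Ties are broken by grid scan order (column-major).
#'
#' @param ud a [ud_raster()].
#' @param level mass fraction in (0, 1); 0.95 is the conventional
#'   home-range isopleth.
#' @return an [hr_polygon()] whose attribute `"cells"` holds the logical
#'   selection mask and `"mass"` the mass actually enclosed.
#' @export
isopleth <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "ud_raster"), level > 0, level < 1)
  o <- order(ud$z, decreasing = TRUE)     # ties: ascending linear index
  cum <- cumsum(ud$z[o])
  ncell <- which(cum >= level)[1]
  if (is.na(ncell)) ncell <- length(o)
  sel <- matrix(FALSE, nrow(ud$z), ncol(ud$z))
  sel[o[seq_len(ncell)]] <- TRUE
  rings <- trace_cell_boundary(sel, ud$x0, ud$y0, ud$cell)
  poly <- hr_polygon(rings)
  attr(poly, "cells") <- sel
  attr(poly, "mass") <- cum[ncell]
  poly
}

# Trace the boundary of a union of grid cells into closed rings.
# Collects every cell edge not shared with another selected cell, then
# chains edges into rings by walking corner-to-corner.
trace_cell_boundary <- function(sel, x0, y0, cell) {
  nx <- nrow(sel); ny <- ncol(sel)
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty cell selection")
  segs <- list()
  at <- function(i, j) i >= 1 && i <= nx && j >= 1 && j <= ny && sel[i, j]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    xl <- x0 + (i - 1) * cell; xr <- xl + cell
    yb <- y0 + (j - 1) * cell; yt <- yb + cell
    if (!at(i, j - 1)) segs[[length(segs) + 1]] <- c(xl, yb, xr, yb)
    if (!at(i, j + 1)) segs[[length(segs) + 1]] <- c(xr, yt, xl, yt)
    if (!at(i - 1, j)) segs[[length(segs) + 1]] <- c(xl, yt, xl, yb)
    if (!at(i + 1, j)) segs[[length(segs) + 1]] <- c(xr, yb, xr, yt)
  }
  segs <- do.call(rbind, segs)
  # chain segments: map each start corner to its segment (corners are exact
  # multiples of cell, so keys are exact strings)
  key <- function(x, y) paste(round(x / cell * 2), round(y / cell * 2))
  from <- key(segs[, 1], segs[, 2])
  lookup <- split(seq_len(nrow(segs)), from)
  used <- logical(nrow(segs))
  rings <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    ring <- list(segs[s0, 1:2])
    cur <- s0
    repeat {
      used[cur] <- TRUE
      nxt_key <- key(segs[cur, 3], segs[cur, 4])
      cand <- lookup[[nxt_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      cur <- cand[1]
      ring[[length(ring) + 1]] <- segs[cur, 1:2]
    }
    rings[[length(rings) + 1]] <- do.call(rbind, ring)
  }
  # drop collinear intermediate corners to keep rings small
  lapply(rings, simplify_ring)
}

simplify_ring <- function(r) {
  n <- nrow(r)
  if (n < 4) return(r)
  keep <- logical(n)
  for (k in seq_len(n)) {
    p <- r[if (k == 1) n else k - 1, ]
    q <- r[k, ]
    s <- r[if (k == n) 1 else k + 1, ]
    keep[k] <- abs((q[1] - p[1]) * (s[2] - p[2]) - (q[2] - p[2]) * (s[1] - p[1])) > 1e-9
  }
  r[keep, , drop = FALSE]
}

#' Read/write a UD raster as an ESRI ASCII grid
#'
#' @param ud a [ud_raster()].
#' @param path file path.
#' @export
write_ud <- function(ud, path) {
  write_ascii_grid(ud$z, ud$x0, ud$y0, ud$cell, path)
  invisible(path)
}

#' @rdname write_ud
#' @export
read_ud <- function(path) {
  g <- read_ascii_grid(path)
  z <- g$mat
  z[z < 0] <- 0
  ud_raster(g$x0, g$y0, g$cell, z / sum(z))
}
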