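#' Ground-truth behavior of a synthetic animal
#'
#' Encodes everything the generator needs to produce one animal's
#' telemetry, and everything a recovery test needs to check against:
#' the qualitative response class with its von Mises parameters
#' (mean response angle `mu_true`, concentration at the highway
#' `theta1_true`, exponential decay `theta2_true` per m), the crossing
#' policy, the home-range center, the session plan, and the step-length
#' law.
#'
#' Session-plan defaults reproduce the study regime this package was
#' built around: 5-28 nightly sessions of about 10 +/- 5 fixes at
#' 39 +/- 22 min intervals, home ranges of 2-3 km^2.
#'
#' @param response `"attraction"`, `"avoidance"`, `"parallel"` or
#'   `"indifference"`.
#' @param mu_true mean response angle (rad); defaults to the pole of the
#'   chosen response (0, pi, pi/2, or NA for indifference).
#' @param theta1_true concentration at distance 0 (0 for indifference).
#' @param theta2_true decay rate (per m).
#' @param crossing_policy `"naive"`, `"passage_faithful"`, or
#'   `"non_crosser"`.
#' @param cross_prob naive policy: probability a highway encounter becomes
#'   a crossing.
#' @param passage_tolerance passage-faithful policy: maximum chainage
#'   shift (m) to reach the nearest allowed passage.
#' @param home_center length-2 numeric, home-range center (m).
#' @param n_sessions number of tracking sessions (nights).
#' @param fixes_mean,fixes_sd per-session fix count law (rounded normal,
#'   min 2).
#' @param interval_mean,interval_sd inter-fix interval law (min, truncated
#'   normal, min 5).
#' @param step_meanlog,step_sdlog log-normal step-length parameters;
#'   defaults give a median step of about 100 m, a realistic nightly
#'   foraging displacement at 39-min intervals.
#' @param kappa_home concentration of the home-attraction pull.
#' @param n_rest,rest_sd number of resting sites and their spread (m)
#'   around the home center; sessions start at one of them. Together with
#'   `kappa_home` these set the realized range size; the defaults were
#'   calibrated once so 95% isopleth ranges land near 2-3 km^2 under the
#'   default step law.
#' @param response_range distance (m) within which the highway-response
#'   rotation is applied.
#' @return list of class `behavior_truth`.
#' @export
behavior_truth <- function(response = c("indifference", "attraction",
                                        "avoidance", "parallel"),
                           mu_true = NULL, theta1_true = NULL,
                           theta2_true = 0.005,
                           crossing_policy = c("naive", "passage_faithful",
                                               "non_crosser"),
                           cross_prob = 0.5, passage_tolerance = 1500,
                           home_center = c(0, 0),
                           n_sessions = 20, fixes_mean = 10, fixes_sd = 5,
                           interval_mean = 39, interval_sd = 22,
                           step_meanlog = log(100), step_sdlog = 0.7,
                           kappa_home = 0.5, response_range = 1000,
                           n_rest = 6, rest_sd = 600) {
  response <- match.arg(response)
  crossing_policy <- match.arg(crossing_policy)
  if (is.null(mu_true))
    mu_true <- switch(response, attraction = 0, avoidance = pi,
                      parallel = pi / 2, indifference = NA_real_)
  if (is.null(theta1_true))
    theta1_true <- if (response == "indifference") 0 else 8
  stopifnot(theta1_true >= 0, theta2_true >= 0, n_sessions >= 1)
  structure(list(response = response, mu_true = mu_true,
                 theta1_true = theta1_true, theta2_true = theta2_true,
                 crossing_policy = crossing_policy, cross_prob = cross_prob,
                 passage_tolerance = passage_tolerance,
                 home_center = home_center, n_sessions = n_sessions,
                 fixes_mean = fixes_mean, fixes_sd = fixes_sd,
                 interval_mean = interval_mean, interval_sd = interval_sd,
                 step_meanlog = step_meanlog, step_sdlog = step_sdlog,
                 kappa_home = kappa_home, response_range = response_range,
                 n_rest = n_rest, rest_sd = rest_sd),
            class = "behavior_truth")
}

#' Generate a synthetic landscape
#'
#' A gently curved highway polyline, passages at requested chainages, and
#' a blobby categorical land-cover raster whose class proportions match
#' the requested mix: an i.i.d. Gaussian field is smoothed with a
#' separable kernel and thresholded at the proportion quantiles, giving
#' spatially coherent patches with (up to ties) exact class shares.
#'
#' @param highway_length highway length (m).
#' @param passage_chainages numeric vector of passage positions (m).
#' @param passage_kinds kinds per passage (recycled).
#' @param extent length-4 numeric (xmin, xmax, ymin, ymax) of the raster.
#' @param cell raster cell size (m); 30 m matches typical land-cover
#'   products.
#' @param proportions named class proportions, summing to 1. Default:
#'   forest 0.67, agricultural 0.27, urban 0.02, water 0.01, other 0.03.
#' @param curve_amp amplitude (m) of the highway's gentle curvature.
#' @param smooth smoothing radius in cells for the land-cover field.
#' @param seed RNG seed; the landscape is reproducible from (config,
#'   seed).
#' @return list of class `landscape`: `highway`, `passages`, `landcover`.
#' @export
generate_landscape <- function(highway_length = 10000,
                               passage_chainages = seq(500, 9500, by = 450),
                               passage_kinds = "culvert",
                               extent = c(0, 10000, -3000, 3000),
                               cell = 30,
                               proportions = c(forest = 0.67,
                                               agricultural = 0.27,
                                               urban = 0.02, water = 0.01,
                                               other = 0.03),
                               curve_amp = 150, smooth = 6, seed = 1) {
  set.seed(seed)
  stopifnot(abs(sum(proportions) - 1) < 1e-6)
  if (any(passage_chainages < 0 | passage_chainages > highway_length))
    stop("passages beyond highway length")
  vx <- seq(0, highway_length, length.out = 41)
  vy <- curve_amp * sin(vx / highway_length * 2 * pi)
  # re-parameterize so requested chainages are honored on the curved line
  hwy <- highway(vx, vy)
  ps <- passages(passage_chainages * hwy$length / highway_length,
                 passage_kinds, hwy)
  nx <- ceiling((extent[2] - extent[1]) / cell)
  ny <- ceiling((extent[4] - extent[3]) / cell)
  field <- matrix(stats::rnorm(nx * ny), nx, ny)
  k <- stats::dnorm(seq(-2, 2, length.out = 2 * smooth + 1))
  k <- k / sum(k)
  field <- apply(field, 2, function(col) stats::filter(col, k, circular = TRUE))
  field <- t(apply(field, 1, function(row) stats::filter(row, k, circular = TRUE)))
  cuts <- stats::quantile(field, cumsum(proportions)[-length(proportions)])
  grid <- matrix(findInterval(field, cuts) + 1L, nx, ny)
  lc <- landcover(extent[1], extent[3], cell, grid, names(proportions))
  structure(list(highway = hwy, passages = ps, landcover = lc),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  print(x$highway)
  cat(sprintf("%d passages\n", nrow(x$passages)))
  print(x$landcover)
  invisible(x)
}

#' Generate one animal's synthetic telemetry
#'
#' Movement mechanism: sessions start at a resting site near the home
#' center (flagged inactive); each step draws its length from the
#' log-normal law and its heading from the circular convolution of a
#' home-attraction draw (von Mises around the bearing to the home center,
#' concentration `kappa_home`) and — when within `response_range` of the
#' highway — a highway-response draw: a response angle from
#' vonMises(mu_true, theta1_true * exp(-theta2_true * T)) applied around
#' the animal-to-highway bearing C, so the generated response angles
#' follow exactly the model the fitting stage estimates. The two draws
#' are composed as the direction of the sum of their unit vectors.
#'
#' Steps that would cross the highway are resolved by the crossing
#' policy: `non_crosser` reflects the endpoint back across the highway
#' tangent; `naive` crosses in place with probability `cross_prob` (else
#' reflects); `passage_faithful` shifts the endpoint along the highway so
#' the chord passes through the nearest allowed passage within
#' `passage_tolerance` (else reflects).
#'
#' @param landscape a [generate_landscape()] result (or a list with a
#'   `highway` and optionally `passages`).
#' @param truth a [behavior_truth()].
#' @param seed RNG seed.
#' @param animal_id id string for the emitted fixes.
#' @param allowed_passages optional chainages usable by the
#'   passage-faithful policy (default: all landscape passages).
#' @return list: `track` (an [animal_track()]) and `truth` (the input
#'   truth, echoed verbatim for recovery tests).
#' @export
generate_track <- function(landscape, truth, seed = 1, animal_id = "A1",
                           allowed_passages = NULL) {
  set.seed(seed)
  hwy <- landscape$highway
  if (truth$crossing_policy == "passage_faithful") {
    if (is.null(allowed_passages)) allowed_passages <- landscape$passages$chainage
    if (length(allowed_passages) == 0)
      stop("passage_faithful policy needs at least one passage")
  }
  home <- truth$home_center
  rest_sites <- cbind(home[1] + stats::rnorm(truth$n_rest, 0, truth$rest_sd),
                      home[2] + stats::rnorm(truth$n_rest, 0, truth$rest_sd))
  rows <- list()
  t_base <- 0
  pos <- NULL
  for (s in seq_len(truth$n_sessions)) {
    n_fix <- max(2L, round(stats::rnorm(1, truth$fixes_mean, truth$fixes_sd)))
    rs <- rest_sites[sample.int(nrow(rest_sites), 1), ]
    pos <- rs
    ts <- t_base
    srows <- data.frame(t = ts, x = pos[1], y = pos[2], active = FALSE)
    for (i in seq_len(n_fix - 1)) {
      dt <- max(5, stats::rnorm(1, truth$interval_mean, truth$interval_sd))
      L <- stats::rlnorm(1, truth$step_meanlog, truth$step_sdlog)
      head_home <- atan2(home[2] - pos[2], home[1] - pos[1])
      u_home <- rvonmises(1, head_home, truth$kappa_home)
      loc <- hw_locate(pos[1], pos[2], hwy)
      if (truth$response != "indifference" &&
          loc$distance <= truth$response_range) {
        kapT <- truth$theta1_true * exp(-truth$theta2_true * loc$distance)
        a_resp <- rvonmises(1, truth$mu_true, kapT)
        u_resp <- wrap_angle(loc$bearing + a_resp)
        # circular convolution: direction of the summed unit vectors
        heading <- atan2(sin(u_home) + sin(u_resp),
                         cos(u_home) + cos(u_resp))
      } else heading <- u_home
      cand <- pos + L * c(cos(heading), sin(heading))
      cand <- resolve_crossing(pos, cand, hwy, truth, allowed_passages)
      pos <- cand
      ts <- ts + dt
      srows <- rbind(srows, data.frame(t = ts, x = pos[1], y = pos[2],
                                       active = TRUE))
    }
    rows[[s]] <- data.frame(animal_id = animal_id,
                            session_id = sprintf("s%02d", s),
                            timestamp = srows$t, x = srows$x, y = srows$y,
                            active = srows$active)
    t_base <- t_base + 24 * 60          # one session per night
  }
  track <- animal_track(do.call(rbind, rows))
  list(track = track, truth = truth)
}

# Apply the crossing policy to a proposed step from p0 to p1.
resolve_crossing <- function(p0, p1, hwy, truth, allowed_passages) {
  s0 <- hw_locate(p0[1], p0[2], hwy)$side
  s1 <- hw_locate(p1[1], p1[2], hwy)$side
  if (s0 == 0L || s1 == 0L || s0 == s1) return(p1)
  xi <- hw_segment_intersections(p0[1], p0[2], p1[1], p1[2], hwy)
  if (nrow(xi) == 0) return(p1)         # side flip beyond the mapped section
  ch <- xi$chainage[1]
  if (truth$crossing_policy == "naive") {
    if (stats::runif(1) < truth$cross_prob) return(p1)
    return(reflect_across(p1, ch, hwy))
  }
  if (truth$crossing_policy == "non_crosser")
    return(reflect_across(p1, ch, hwy))
  # passage_faithful: detour the step through the nearest allowed passage,
  # so the chord crosses the highway exactly at the passage point
  q <- allowed_passages[which.min(abs(allowed_passages - ch))]
  if (abs(q - ch) > truth$passage_tolerance)
    return(reflect_across(p1, ch, hwy))
  X <- hw_point_at(ch, hwy)
  at <- hw_point_at(q, hwy)
  over <- sqrt((p1[1] - X$x)^2 + (p1[2] - X$y)^2)  # travel beyond the highway
  u <- c(at$x - p0[1], at$y - p0[2])
  u <- u / sqrt(sum(u^2))
  c(at$x, at$y) + u * max(over, 1)
}

# Mirror a point across the highway tangent line at the given chainage:
# the endpoint lands at the same distance on the origin side.
reflect_across <- function(p, chainage, hwy) {
  at <- hw_point_at(chainage, hwy)
  vx <- p[1] - at$x; vy <- p[2] - at$y
  # reflection across the tangent direction (tx, ty)
  dot <- vx * at$tx + vy * at$ty
  rx <- 2 * dot * at$tx - vx
  ry <- 2 * dot * at$ty - vy
  c(at$x + rx, at$y + ry)
}

#' Generate a full scenario: landscape plus a set of animals
#'
#' @param animals named list of [behavior_truth()]s.
#' @param landscape_config list of arguments for [generate_landscape()].
#' @param seed base seed; each animal gets an independent derived stream.
#' @return list of class `scenario`: `landscape`, `tracks` (named list of
#'   [animal_track()]), `truths`, `seed`.
#' @export
generate_scenario <- function(animals, landscape_config = list(), seed = 1) {
  landscape <- do.call(generate_landscape,
                       c(landscape_config, list(seed = derive_seed(seed, 0))))
  tracks <- list(); truths <- list()
  for (i in seq_along(animals)) {
    id <- names(animals)[i]
    g <- generate_track(landscape, animals[[i]],
                        seed = derive_seed(seed, i), animal_id = id)
    tracks[[id]] <- g$track
    truths[[id]] <- g$truth
  }
  structure(list(landscape = landscape, tracks = tracks, truths = truths,
                 seed = seed), class = "scenario")
}

#' Write a scenario's telemetry, landscape and ground truth to disk
#'
#' Emits the fix CSV, highway WKT, land-cover ASCII grid, passage CSV and
#' a machine-readable truth YAML, so recovery analyses can read the truth
#' back instead of re-specifying it.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if missing).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fixes(scenario$tracks, file.path(dir, "fixes.csv"))
  write_highway(scenario$landscape$highway, file.path(dir, "highway.wkt"))
  write_landcover(scenario$landscape$landcover, file.path(dir, "landcover.asc"))
  utils::write.csv(scenario$landscape$passages,
                   file.path(dir, "passages.csv"), row.names = FALSE)
  truths <- lapply(scenario$truths, function(tr) {
    tr <- unclass(tr)
    tr$home_center <- as.numeric(tr$home_center)
    tr
  })
  yaml::write_yaml(list(seed = scenario$seed, animals = truths),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
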