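#' Null-model configuration
#'
#' Settings for the barrier-naive constrained random walk: the number of
#' replicate simulations per animal (1000 at full fidelity; smaller values
#' give faster, noisier envelopes), the redraw budget per step, and the
#' base seed from which per-replicate RNG streams are derived.
#'
#' @param n_replicates number of replicates, >= 1.
#' @param max_direction_draws maximum uniform direction draws per step
#'   before the boundary-truncation fallback.
#' @param seed integer base seed, recorded in the output.
#' @return list of class `null_config`.
#' @export
null_config <- function(n_replicates = 1000, max_direction_draws = 1000,
                        seed = 1L) {
  stopifnot(n_replicates >= 1, max_direction_draws >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 max_direction_draws = as.integer(max_direction_draws),
                 seed = as.integer(seed)),
            class = "null_config")
}

# Derived per-replicate seed, kept within 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1299709) %% 2147483647)
}

#' Simulate one tracking session of a barrier-naive walker
#'
#' The agent starts at a resting site chosen uniformly from `rest_sites`,
#' then replays the observed step lengths in their original order; each
#' step's direction is drawn uniformly on (-pi, pi] and redrawn until the
#' endpoint lies inside the home-range polygon. The agent knows nothing of
#' the highway: any barrier effect present in the observed track is absent
#' here by construction. If no admissible direction is found within the
#' redraw budget (degenerate geometry), the step is truncated at the
#' polygon boundary along the last drawn direction and the event is
#' counted in the `truncated` attribute.
#'
#' @param rest_sites matrix (k x 2) of candidate start locations, all
#'   inside `poly`.
#' @param step_lengths observed step lengths (m), replayed exactly and in
#'   order — never resampled.
#' @param poly the home-range [hr_polygon()].
#' @param max_draws redraw budget per step.
#' @return matrix ((length(step_lengths) + 1) x 2) of simulated fix
#'   coordinates; attribute `truncated` counts fallback events.
#' @export
simulate_session <- function(rest_sites, step_lengths, poly,
                             max_draws = 1000) {
  rest_sites <- matrix(rest_sites, ncol = 2)
  stopifnot(nrow(rest_sites) >= 1)
  if (!all(contains(poly, rest_sites[, 1], rest_sites[, 2])))
    stop("all rest sites must lie inside the polygon")
  n <- length(step_lengths)
  out <- matrix(NA_real_, n + 1, 2)
  start <- rest_sites[sample.int(nrow(rest_sites), 1), ]
  out[1, ] <- start
  truncated <- 0L
  batch <- 16L
  for (k in seq_len(n)) {
    L <- step_lengths[k]
    cur <- out[k, ]
    if (L == 0) { out[k + 1, ] <- cur; next }
    placed <- FALSE
    drawn <- 0L
    last_dir <- NA_real_
    while (drawn < max_draws) {
      m <- min(batch, max_draws - drawn)
      dirs <- stats::runif(m, -pi, pi)
      drawn <- drawn + m
      last_dir <- dirs[m]
      px <- cur[1] + L * cos(dirs); py <- cur[2] + L * sin(dirs)
      ok <- contains(poly, px, py)
      if (any(ok)) {
        j <- which(ok)[1]
        out[k + 1, ] <- c(px[j], py[j])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      s <- ray_boundary_distance(poly, cur[1], cur[2], last_dir, L)
      cand <- c(cur[1] + s * cos(last_dir), cur[2] + s * sin(last_dir))
      # starting on the boundary pointing outward can miss every edge;
      # staying put is the only containing fallback then
      if (!contains(poly, cand[1], cand[2], tol = 1e-6)) cand <- cur
      out[k + 1, ] <- cand
      truncated <- truncated + 1L
    }
  }
  attr(out, "truncated") <- truncated
  out
}

#' Run the full replicate set for one animal
#'
#' Replays every observed tracking session `n_replicates` times inside the
#' home-range polygon. Each replicate runs on its own RNG stream derived
#' from `(seed, replicate index)`, so any replicate can be reproduced
#' independently.
#'
#' @param track the observed [animal_track()].
#' @param poly the animal's home-range [hr_polygon()] (95% UD isopleth).
#' @param config a [null_config()].
#' @param max_gap step gap rule (min), matching the observed-step build.
#' @return object of class `replicate_set`: list with `replicates` (each a
#'   list of per-session fix matrices), `session_ids`, `step_lengths`
#'   (observed, per session), `config`, and `n_truncated`.
#' @export
run_replicates <- function(track, poly, config = null_config(), max_gap = 90) {
  stopifnot(inherits(track, "animal_track"))
  steps <- build_steps(track, max_gap)
  if (nrow(steps) == 0) stop("track has no usable steps")
  sess_ids <- unique(steps$session_id)
  step_lengths <- lapply(sess_ids, function(s) steps$length[steps$session_id == s])
  names(step_lengths) <- as.character(sess_ids)
  f <- track$fixes
  # rest sites: first fix of each session plus any inactive fixes
  firsts <- do.call(rbind, lapply(split(f, f$session_id),
                                  function(s) c(s$x[1], s$y[1])))
  inact <- cbind(f$x[!f$active], f$y[!f$active])
  rest <- unique(rbind(firsts, inact))
  rest <- rest[contains(poly, rest[, 1], rest[, 2]), , drop = FALSE]
  if (nrow(rest) == 0) stop("no rest site lies inside the polygon")
  n_trunc <- 0L
  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(derive_seed(config$seed, r))
    sims <- lapply(step_lengths, function(sl)
      simulate_session(rest, sl, poly, config$max_direction_draws))
    n_trunc <- n_trunc + sum(vapply(sims, function(m) attr(m, "truncated"), 0L))
    reps[[r]] <- sims
  }
  structure(list(replicates = reps, session_ids = sess_ids,
                 step_lengths = step_lengths, config = config,
                 n_truncated = n_trunc),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Null-model replicate set: %d replicates x %d sessions (seed %d)\n",
              length(x$replicates), length(x$session_ids), x$config$seed))
  if (x$n_truncated > 0)
    cat(sprintf("  %d boundary-truncated steps\n", x$n_truncated))
  invisible(x)
}

# Convert one replicate to an animal_track, reusing the observed session
# timestamps so downstream stages (steps, BRB, crossings) see the same
# temporal structure.
replicate_as_track <- function(repset, r, track, max_gap = 90) {
  f <- track$fixes
  sims <- repset$replicates[[r]]
  rows <- list()
  for (sid in repset$session_ids) {
    s <- f[f$session_id == sid, , drop = FALSE]
    # timestamps of the fixes that participate in steps (gap rule kept)
    m <- sims[[as.character(sid)]]
    st <- build_steps(animal_track(s), max_gap)
    # contiguous times preserving each observed step's duration (gap-split
    # sessions are replayed as one contiguous walk)
    ts <- st$t0[1] + cumsum(c(0, st$duration))
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = track$animal_id, session_id = sid, timestamp = ts,
      x = m[, 1], y = m[, 2], active = TRUE)
  }
  animal_track(do.call(rbind, rows))
}

#' Write a replicate set as an indexed fix CSV
#'
#' One CSV with a leading `replicate` column; sessions and fix order
#' mirror the observed track.
#'
#' @param repset a [run_replicates()] result.
#' @param track the observed track (for ids/timestamps).
#' @param path output CSV path.
#' @export
write_replicates <- function(repset, track, path) {
  rows <- list()
  for (r in seq_along(repset$replicates)) {
    tr <- replicate_as_track(repset, r, track)
    df <- tr$fixes
    df <- cbind(replicate = r, df)
    rows[[r]] <- df
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
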