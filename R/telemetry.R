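#' Construct an animal track from a fix table
#'
#' A track is one animal's telemetry: fixes grouped into tracking sessions
#' (one intensive tracking night each), sorted by time within session. The
#' first fix of each session is taken as that session's resting site.
#'
#' @param fixes data.frame with columns `animal_id`, `session_id`,
#'   `timestamp` (numeric minutes or anything coercible via
#'   [as_minutes()]), `x`, `y` (projected m), `active` (logical).
#' @return object of class `animal_track`.
#' @export
animal_track <- function(fixes) {
  need <- c("animal_id", "session_id", "timestamp", "x", "y", "active")
  miss <- setdiff(need, names(fixes))
  if (length(miss)) stop("fixes missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(fixes$animal_id)) != 1)
    stop("animal_track expects a single animal_id")
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y)))
    stop("non-finite coordinates")
  fixes$timestamp <- as_minutes(fixes$timestamp)
  fixes$active <- as.logical(fixes$active)
  fixes <- fixes[order(fixes$session_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  for (sid in unique(fixes$session_id)) {
    ts <- fixes$timestamp[fixes$session_id == sid]
    if (anyDuplicated(ts))
      stop(sprintf("duplicate timestamps in session '%s'", sid))
  }
  structure(list(animal_id = fixes$animal_id[1], fixes = fixes),
            class = "animal_track")
}

#' @export
print.animal_track <- function(x, ...) {
  s <- summarize_track(x)
  cat(sprintf("Animal '%s': %d sessions, %d fixes, %.1f tracked hours\n",
              x$animal_id, s$n_sessions, s$n_fixes, s$tracked_hours))
  if (is.finite(s$interval_mean))
    cat(sprintf("  inter-fix interval %.0f +/- %.0f min\n",
                s$interval_mean, s$interval_sd))
  invisible(x)
}

# Timestamps: numeric minutes pass through; ISO-8601 strings are converted
# to minutes since the epoch.
as_minutes <- function(ts) {
  if (is.numeric(ts)) return(as.numeric(ts))
  t <- as.POSIXct(ts, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                 "%Y-%m-%d %H:%M:%S"))
  if (anyNA(t)) stop("unparseable timestamps")
  as.numeric(t) / 60
}

#' Read telemetry fixes from CSV
#'
#' Expects a header `animal_id,session_id,timestamp,x,y,active`. Rows are
#' grouped by animal and session and sorted by time. Malformed rows
#' (non-numeric coordinates) raise an error citing the offending data rows;
#' duplicate (animal, session, timestamp) triples and non-monotone session
#' timestamps are errors naming the session.
#'
#' @param path CSV file path.
#' @return named list of [animal_track()] objects, one per animal.
#' @export
read_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "session_id", "timestamp", "x", "y", "active")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix CSV missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("no fixes in ", path)
    return(structure(list(), names = character(0)))
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at data row(s) %s of %s",
                   col, paste(bad, collapse = ", "), path))
    df[[col]] <- v
  }
  df$active <- parse_flag(df$active)
  out <- lapply(split(df, df$animal_id), animal_track)
  out[order(names(out))]
}

parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  lv <- tolower(trimws(as.character(v)))
  out <- lv %in% c("true", "t", "1", "yes")
  bad <- !lv %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad)) stop("unparseable active flag at data row(s) ",
                     paste(which(bad), collapse = ", "))
  out
}

#' Write tracks back to the fix CSV schema
#'
#' @param tracks a single [animal_track()] or a list of them.
#' @param path output CSV path.
#' @export
write_fixes <- function(tracks, path) {
  if (inherits(tracks, "animal_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, `[[`, "fixes"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build movement steps from a track
#'
#' One step per pair of consecutive fixes in the same session whose time
#' gap does not exceed `max_gap` (longer gaps — typically loss of contact —
#' yield no step; steps never span sessions). A zero-displacement pair
#' keeps length 0 and inherits the previous step's heading; if there is no
#' previous step its heading is NA and angle analyses drop it.
#'
#' @param track an [animal_track()].
#' @param max_gap maximum step duration (min); default 90, about twice the
#'   typical 39-min inter-fix interval, so overnight gaps are not treated
#'   as movement.
#' @return data.frame of class `steps`: session_id, x0, y0, x1, y1, t0, t1,
#'   length (m), duration (min), heading (rad), active0, active1.
#' @export
#' @examples
#' fx <- data.frame(animal_id = "a", session_id = 1,
#'                  timestamp = c(0, 30), x = c(0, 30), y = c(0, 40),
#'                  active = TRUE)
#' build_steps(animal_track(fx)) # one 50 m step, heading atan2(40, 30)
build_steps <- function(track, max_gap = 90) {
  stopifnot(inherits(track, "animal_track"), max_gap > 0)
  f <- track$fixes
  out <- list()
  for (sid in unique(f$session_id)) {
    s <- f[f$session_id == sid, , drop = FALSE]
    if (nrow(s) < 2) next
    i <- seq_len(nrow(s) - 1)
    dur <- diff(s$timestamp)
    keep <- dur <= max_gap
    if (!any(keep)) next
    dx <- diff(s$x); dy <- diff(s$y)
    len <- sqrt(dx^2 + dy^2)
    heading <- wrap_angle(atan2(dy, dx))
    # zero-length steps inherit the previous step's heading
    for (k in which(len == 0)) heading[k] <- if (k > 1) heading[k - 1] else NA
    out[[length(out) + 1]] <- data.frame(
      session_id = sid,
      x0 = s$x[i][keep], y0 = s$y[i][keep],
      x1 = s$x[i + 1][keep], y1 = s$y[i + 1][keep],
      t0 = s$timestamp[i][keep], t1 = s$timestamp[i + 1][keep],
      length = len[keep], duration = dur[keep], heading = heading[keep],
      active0 = s$active[i][keep], active1 = s$active[i + 1][keep])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(session_id = character(0), x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), t0 = numeric(0),
               t1 = numeric(0), length = numeric(0), duration = numeric(0),
               heading = numeric(0), active0 = logical(0), active1 = logical(0))
  rownames(res) <- NULL
  class(res) <- c("steps", "data.frame")
  res
}

#' Summary statistics of a track
#'
#' Counts all sessions and fixes, but computes tracked hours and the
#' inter-fix interval moments only over sessions with at least two fixes
#' (single-fix sessions carry no interval information).
#'
#' @param track an [animal_track()].
#' @return one-row data.frame: animal_id, n_sessions, n_fixes,
#'   tracked_hours, interval_mean, interval_sd (min).
#' @export
summarize_track <- function(track) {
  stopifnot(inherits(track, "animal_track"))
  f <- track$fixes
  by_sess <- split(f$timestamp, f$session_id)
  multi <- by_sess[vapply(by_sess, length, 1L) >= 2]
  ivals <- unlist(lapply(multi, diff), use.names = FALSE)
  data.frame(animal_id = track$animal_id,
             n_sessions = length(by_sess),
             n_fixes = nrow(f),
             tracked_hours = sum(vapply(multi, function(t) diff(range(t)), 1)) / 60,
             interval_mean = if (length(ivals)) mean(ivals) else NA_real_,
             interval_sd = if (length(ivals) > 1) stats::sd(ivals) else
               if (length(ivals) == 1) 0 else NA_real_)
}
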