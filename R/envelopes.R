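#' Percentile envelope of a scalar statistic
#'
#' Classifies an observed value against the empirical 5th-95th percentile
#' band of its null-model replicate distribution: values below the 5th
#' percentile are `"below"` (less than expected by chance), above the 95th
#' `"above"`, otherwise `"within"`. Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7), the convention
#' fixed for the whole package so small replicate sets are reproducible.
#'
#' @param observed the observed statistic (e.g. crossing count).
#' @param replicates numeric vector of the statistic across null
#'   replicates.
#' @param probs lower/upper percentile pair.
#' @return list of class `envelope_result`: observed, lower, upper,
#'   classification.
#' @export
count_envelope <- function(observed, replicates, probs = c(0.05, 0.95)) {
  if (length(replicates) == 0) stop("no replicate values")
  if (length(replicates) < 100)
    warning("fewer than 100 replicates; envelope percentiles are noisy")
  q <- stats::quantile(replicates, probs, names = FALSE, type = 7)
  structure(list(observed = observed, lower = q[1], upper = q[2],
                 classification = classify_band(observed, q[1], q[2])),
            class = "envelope_result")
}

classify_band <- function(x, lo, hi) {
  ifelse(x < lo, "below", ifelse(x > hi, "above", "within"))
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("observed %.3g vs null [%.3g, %.3g] (5-95%%): %s\n",
              x$observed, x$lower, x$upper, x$classification))
  invisible(x)
}

#' Cell-wise UD envelope
#'
#' Classifies each cell of the observed utilization distribution against
#' the per-cell 5th-95th percentile band of the replicate UDs. Cells
#' outside the mask (conventionally the home range) are `NA`.
#'
#' @param observed a [ud_raster()].
#' @param replicates list of [ud_raster()]s on the same grid.
#' @param mask logical matrix of cells to classify, or `NULL` for all.
#' @param probs percentile pair.
#' @return character matrix of `"below"`/`"within"`/`"above"`/`NA` with
#'   attributes `lower` and `upper` (the per-cell bounds).
#' @export
cellwise_envelope <- function(observed, replicates, mask = NULL,
                              probs = c(0.05, 0.95)) {
  stopifnot(inherits(observed, "ud_raster"), length(replicates) >= 1)
  for (r in replicates)
    if (!identical(dim(r$z), dim(observed$z)) ||
        r$cell != observed$cell || r$x0 != observed$x0 || r$y0 != observed$y0)
      stop("replicate UD grid does not match the observed grid")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(observed$z), ncol(observed$z))
  stopifnot(identical(dim(mask), dim(observed$z)))
  arr <- vapply(replicates, function(r) r$z,
                matrix(0, nrow(observed$z), ncol(observed$z)))
  dim(arr) <- c(length(observed$z), length(replicates))
  qs <- apply(arr, 1, stats::quantile, probs = probs, names = FALSE, type = 7)
  lower <- matrix(qs[1, ], nrow(observed$z))
  upper <- matrix(qs[2, ], nrow(observed$z))
  cls <- matrix(classify_band(observed$z, lower, upper), nrow(observed$z))
  cls[!mask] <- NA
  attr(cls, "lower") <- lower
  attr(cls, "upper") <- upper
  cls
}

#' Chainage-profile envelope
#'
#' Per-bin classification of an observed along-highway crossing profile
#' against replicate profiles; `"above"` bins are highway segments crossed
#' more often than the barrier-naive null expects.
#'
#' @param observed a [chainage_profile()].
#' @param replicates list of [chainage_profile()]s on the same bin edges.
#' @param probs percentile pair.
#' @return data.frame: bin_start, bin_end, observed, lower, upper,
#'   classification.
#' @export
profile_envelope <- function(observed, replicates, probs = c(0.05, 0.95)) {
  stopifnot(inherits(observed, "chainage_profile"), length(replicates) >= 1)
  for (r in replicates)
    if (!isTRUE(all.equal(r$edges, observed$edges)))
      stop("replicate profile bins do not match the observed profile")
  arr <- vapply(replicates, `[[`, observed$density, "density")
  dim(arr) <- c(length(observed$density), length(replicates))
  qs <- apply(arr, 1, stats::quantile, probs = probs, names = FALSE, type = 7)
  data.frame(bin_start = observed$edges[-length(observed$edges)],
             bin_end = observed$edges[-1],
             observed = observed$density,
             lower = qs[1, ], upper = qs[2, ],
             classification = classify_band(observed$density, qs[1, ], qs[2, ]))
}
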