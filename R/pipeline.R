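#' Run the full per-animal analysis pipeline
#'
#' Orchestrates, per animal: habitat screen inputs, UD estimation and 95%
#' isopleth home range, response-angle model fits with LR test and
#' qualitative classification, crossing detection and UD_cross profile,
#' the barrier-naive null-model replicates, and the three envelope
#' analyses (crossing count, cell-wise UD, chainage profile); then the
#' weighted compositional habitat screen across animals. Outputs are
#' written under `out_dir` with a YAML manifest recording the seed and a
#' config hash; stages already on disk are reused unless
#' `overwrite = TRUE`.
#'
#' @param tracks named list of [animal_track()]s (e.g. [read_fixes()] or a
#'   [generate_scenario()]'s `$tracks`).
#' @param hwy the [highway()].
#' @param landcover optional [landcover()] for the habitat screen.
#' @param config list of settings; see [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list of class `pipeline_result`: per-animal result lists plus
#'   `habitat` (a [compositional_test()] result or NULL) and `manifest`.
#' @export
run_pipeline <- function(tracks, hwy, landcover = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(tracks) >= 1)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  animals <- names(tracks)
  if (is.null(animals)) animals <- paste0("animal", seq_along(tracks))
  results <- list()
  for (id in animals) {
    idx <- match(id, animals)
    res <- tryCatch(
      analyze_animal(tracks[[id]], hwy, config, out_dir, id,
                     seed = derive_seed(config$seed, 1000 + idx)),
      error = function(e) stop(sprintf("stage failure for animal '%s': %s",
                                       id, conditionMessage(e)), call. = FALSE))
    results[[id]] <- res
  }
  habitat <- NULL
  if (!is.null(landcover) && length(animals) >= 2) {
    used <- t(vapply(animals, function(id)
      use_from_fixes(tracks[[id]], landcover, config$habitat_classes),
      numeric(2)))
    avail <- t(vapply(animals, function(id)
      availability_from_ud(results[[id]]$ud, landcover, config$habitat_classes),
      numeric(2)))
    colnames(used) <- colnames(avail) <- config$habitat_classes
    w <- vapply(animals, function(id) nrow(tracks[[id]]$fixes), numeric(1))
    habitat <- compositional_test(composition_table(used, avail, w),
                                  n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, 777))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("roadresponse")),
                   seed = config$seed,
                   n_replicates = config$n_replicates,
                   config_hash = config_hash(config),
                   animals = animals,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(list(animals = results, habitat = habitat, manifest = manifest),
            class = "pipeline_result")
}

#' Pipeline configuration
#'
#' @param seed base seed for every random stage.
#' @param n_replicates null-model replicates per animal (1000 for full
#'   fidelity; 200 is the fast demo profile).
#' @param isopleth_level home-range isopleth mass fraction.
#' @param band UD_cross mask half-width (m).
#' @param bin_width chainage bin width (m).
#' @param max_gap step gap rule (min).
#' @param brb a [brb_params()].
#' @param habitat_classes two land-cover classes for the habitat screen.
#' @param n_perm permutations for the compositional test.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_replicates = 1000,
                            isopleth_level = 0.95, band = 200,
                            bin_width = 250, max_gap = 90,
                            brb = brb_params(),
                            habitat_classes = c("forest", "agricultural"),
                            n_perm = 1000) {
  stopifnot(isopleth_level > 0, isopleth_level < 1)
  structure(list(seed = as.integer(seed), n_replicates = n_replicates,
                 isopleth_level = isopleth_level, band = band,
                 bin_width = bin_width, max_gap = max_gap, brb = brb,
                 habitat_classes = habitat_classes, n_perm = n_perm),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(lapply(unclass(config), unclass), tf)
  unname(tools::md5sum(tf))
}

analyze_animal <- function(track, hwy, config, out_dir, id, seed = config$seed) {
  cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(id, "_stage.rds"))
  if (!is.null(cache) && file.exists(cache)) return(readRDS(cache))
  params <- config$brb
  if (is.null(params$D)) params$D <- estimate_diffusion(track)
  ud <- estimate_ud(track, params)
  hr <- isopleth(ud, config$isopleth_level)
  obs_angles <- response_angles(track, hwy, max_gap = config$max_gap)
  fits <- NULL
  if (nrow(obs_angles) >= 10 && length(unique(obs_angles$T)) > 1) {
    f0 <- vm_response(A ~ 1, obs_angles)
    f1 <- vm_response(A ~ T, obs_angles)
    lt <- lr_test(f0, f1)
    fits <- list(no_response = f0, responsive = f1, lr = lt,
                 classification = classify_response(f1, lt))
  }
  events <- detect_crossings(track, hwy, config$max_gap)
  udc <- ud_cross(events, params, hwy, band = config$band,
                  bin_width = config$bin_width)
  reps <- run_replicates(track, hr,
                         null_config(config$n_replicates, seed = seed),
                         max_gap = config$max_gap)
  # replicate statistics
  rep_counts <- integer(length(reps$replicates))
  rep_uds <- vector("list", length(reps$replicates))
  rep_profiles <- vector("list", length(reps$replicates))
  gspec <- grid_spec(c(ud$x0, ud$x0 + nrow(ud$z) * ud$cell),
                     c(ud$y0, ud$y0 + ncol(ud$z) * ud$cell), ud$cell)
  for (r in seq_along(reps$replicates)) {
    tr <- replicate_as_track(reps, r, track, config$max_gap)
    ev <- detect_crossings(tr, hwy, config$max_gap)
    rep_counts[r] <- nrow(ev)
    rep_uds[[r]] <- estimate_ud(tr, params, gspec)
    if (!udc$zero_crossings && nrow(ev) > 0) {
      rp <- ud_cross(ev, params, hwy, band = config$band,
                     bin_width = config$bin_width, grid = gspec)
      rep_profiles[[r]] <- rp$profile
    }
  }
  envelopes <- list(
    crossings = count_envelope(nrow(events), rep_counts),
    cells = cellwise_envelope(ud, rep_uds, mask = attr(hr, "cells")))
  if (!udc$zero_crossings) {
    keep <- !vapply(rep_profiles, is.null, TRUE)
    if (any(keep))
      envelopes$profile <- profile_envelope(udc$profile, rep_profiles[keep])
  } else {
    envelopes$profile <- NULL
    message(sprintf("animal '%s': no crossings; chainage envelope skipped", id))
  }
  res <- list(id = id, summary = summarize_track(track), ud = ud,
              home_range = hr, angles = obs_angles, fits = fits,
              crossings = events, ud_cross = udc,
              replicate_counts = rep_counts, envelopes = envelopes)
  if (!is.null(out_dir)) {
    write_ud(ud, file.path(out_dir, paste0(id, "_ud.asc")))
    write_polygon(hr, file.path(out_dir, paste0(id, "_homerange.wkt")))
    utils::write.csv(events, file.path(out_dir, paste0(id, "_crossings.csv")),
                     row.names = FALSE)
    if (!is.null(fits))
      utils::write.csv(table2_row(id, fits),
                       file.path(out_dir, paste0(id, "_response.csv")),
                       row.names = FALSE)
    saveRDS(res, cache)
  }
  res
}

# One row of the response-model summary table: animal, |mu|, theta1,
# theta2, chi2, p — the conventional reporting shape for these fits.
table2_row <- function(id, fits) {
  cf <- fits$responsive$coefficients
  data.frame(animal = id, abs_mu = abs(cf[["mu"]]),
             theta1 = cf[["theta1"]], theta2 = cf[["theta2"]],
             chi2 = fits$lr$statistic, p = fits$lr$p_value,
             classification = fits$classification)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d animals\n", length(x$animals)))
  for (a in x$animals) {
    cls <- if (!is.null(a$fits)) a$fits$classification else "(no angle fit)"
    cat(sprintf("  %s: %d crossings (%s vs null), response: %s\n",
                a$id, nrow(a$crossings),
                a$envelopes$crossings$classification, cls))
  }
  if (!is.null(x$habitat)) print(x$habitat)
  invisible(x)
}
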