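test_that("landscapes are reproducible and honor their config", {
  a <- generate_landscape(seed = 5)
  b <- generate_landscape(seed = 5)
  expect_identical(a$landcover$grid, b$landcover$grid)
  expect_identical(a$highway$x, b$highway$x)

  ls <- generate_landscape(passage_chainages = c(2500, 7000), seed = 6)
  expect_equal(nrow(ls$passages), 2)
  pt <- roadresponse:::hw_point_at(ls$passages$chainage[1], ls$highway)
  # requested chainage honored on the (curved) line within 1% of length scale
  expect_lt(abs(ls$passages$chainage[1] / ls$highway$length - 2500 / 10000), 0.001)
  expect_true(is.finite(pt$x))

  # class proportions realized within 5 points
  tab <- table(factor(ls$landcover$grid, levels = 1:5)) / length(ls$landcover$grid)
  expect_lt(abs(tab[[1]] - 0.67), 0.05)
  expect_lt(abs(tab[[2]] - 0.27), 0.05)
  expect_error(generate_landscape(passage_chainages = 12000), "beyond")
})

test_that("tracks are reproducible and carry their truth record", {
  ls <- generate_landscape(seed = 2)
  tru <- behavior_truth("attraction", home_center = c(5000, 400), n_sessions = 6)
  g1 <- generate_track(ls, tru, seed = 9)
  g2 <- generate_track(ls, tru, seed = 9)
  expect_identical(g1$track$fixes, g2$track$fixes)
  expect_identical(g1$truth, tru)
  # session structure: first fix inactive (resting site), others active
  f <- g1$track$fixes
  firsts <- !duplicated(f$session_id)
  expect_true(all(!f$active[firsts]))
  expect_true(all(f$active[!firsts]))
  expect_equal(length(unique(f$session_id)), 6)
})

test_that("generated intervals reproduce the configured cadence", {
  ls <- generate_landscape(seed = 2)
  tru <- behavior_truth(n_sessions = 30, fixes_mean = 12, fixes_sd = 3,
                        interval_mean = 39, interval_sd = 22)
  g <- generate_track(ls, tru, seed = 10)
  s <- summarize_track(g$track)
  expect_gt(s$n_fixes, 200)
  expect_lt(abs(s$interval_mean - 39) / 39, 0.1)
  expect_lt(abs(s$interval_sd - 22) / 22, 0.35)  # sd truncated at 5-min floor
})

test_that("non-crossing agents never cross; naive agents do", {
  ls <- generate_landscape(seed = 2)
  nc <- generate_track(ls, behavior_truth("indifference",
                                          crossing_policy = "non_crosser",
                                          home_center = c(5000, 120),
                                          n_sessions = 15), seed = 11)
  expect_equal(nrow(detect_crossings(nc$track, ls$highway, max_gap = 1e9)), 0)
  na <- generate_track(ls, behavior_truth("indifference",
                                          crossing_policy = "naive",
                                          home_center = c(5000, 0),
                                          n_sessions = 15), seed = 11)
  expect_gt(nrow(detect_crossings(na$track, ls$highway, max_gap = 1e9)), 0)
})

test_that("passage-faithful crossings happen at the allowed passage", {
  ls <- generate_landscape(seed = 2)
  tru <- behavior_truth("indifference", crossing_policy = "passage_faithful",
                        home_center = c(5000, 0), n_sessions = 20)
  g <- generate_track(ls, tru, seed = 12, allowed_passages = 4550)
  ev <- detect_crossings(g$track, ls$highway, max_gap = 1e9)
  expect_gt(nrow(ev), 0)
  expect_true(all(abs(ev$chainage - 4550) < 300))
  expect_error(generate_track(ls, tru, seed = 1, allowed_passages = numeric(0)),
               "at least one passage")
})

test_that("generated response angles follow the configured model", {
  # near the highway an avoider's angles concentrate around pi
  ls <- generate_landscape(seed = 2)
  tru <- behavior_truth("avoidance", home_center = c(5000, 400),
                        n_sessions = 30, fixes_mean = 12)
  g <- generate_track(ls, tru, seed = 13)
  ra <- response_angles(g$track, ls$highway)
  near <- ra$A[ra$T < 300]
  expect_gt(length(near), 10)
  expect_gt(mean(cos(near - pi)), 0.3)  # resultant toward pi
})

test_that("scenarios round-trip through disk including the truth file", {
  sc <- generate_scenario(
    list(a1 = behavior_truth(n_sessions = 3),
         a2 = behavior_truth("avoidance", home_center = c(3000, 500),
                             n_sessions = 3)),
    seed = 4)
  dir <- tempfile()
  write_scenario(sc, dir)
  tracks <- read_fixes(file.path(dir, "fixes.csv"))
  expect_setequal(names(tracks), c("a1", "a2"))
  expect_equal(tracks$a1$fixes$x, sc$tracks$a1$fixes$x)
  hwy <- read_highway(file.path(dir, "highway.wkt"))
  expect_equal(hwy$length, sc$landscape$highway$length, tolerance = 1e-6)
  lc <- read_landcover(file.path(dir, "landcover.asc"))
  expect_identical(lc$grid, sc$landscape$landcover$grid)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$animals$a2$response, "avoidance")
  expect_equal(truth$animals$a2$theta1_true, sc$truths$a2$theta1_true)
  expect_equal(truth$seed, 4)
})
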