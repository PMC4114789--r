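test_that("response angles hit the attraction/avoidance/parallel poles", {
  hw <- straight_highway()
  toward <- build_steps(toy_track(c(0, 0), c(100, 50)))
  away <- build_steps(toy_track(c(0, 0), c(100, 150)))
  parallel <- build_steps(toy_track(c(0, 50), c(100, 100)))
  expect_equal(response_angles(toward, hw)$A, 0)
  expect_equal(abs(response_angles(away, hw)$A), pi)
  expect_equal(abs(response_angles(parallel, hw)$A), pi / 2)
  # C is the bearing to the highway, T the start distance
  ra <- response_angles(toward, hw)
  expect_equal(ra$C, -pi / 2)
  expect_equal(ra$T, 100)
})

test_that("inactive endpoints are excluded when active_only", {
  fx <- data.frame(animal_id = "a", session_id = 1, timestamp = c(0, 30, 60),
                   x = c(0, 10, 20), y = 100, active = c(FALSE, TRUE, TRUE))
  tr <- animal_track(fx)
  expect_equal(nrow(response_angles(tr, straight_highway())), 1)
  expect_equal(nrow(response_angles(tr, straight_highway(), active_only = FALSE)), 2)
})

test_that("von Mises density is uniform at kappa 0, symmetric, and normalized", {
  expect_equal(dvonmises(0.3, 0, 0, log = FALSE), 1 / (2 * pi))
  expect_equal(dvonmises(-2, 1, 0, log = FALSE), 1 / (2 * pi))
  for (d in c(0.2, 1, 2.5))
    expect_equal(dvonmises(0.7 + d, 0.7, 3, log = FALSE),
                 dvonmises(0.7 - d, 0.7, 3, log = FALSE))
  for (k in c(0, 0.5, 5, 50)) {
    int <- integrate(function(a) dvonmises(a, 0.4, k, log = FALSE),
                     -pi, pi, rel.tol = 1e-12)$value
    expect_lt(abs(int - 1), 1e-8)
  }
  # stable at large kappa
  expect_true(is.finite(dvonmises(0.01, 0, 1e4)))
  expect_error(dvonmises(0, 0, -1), "kappa")
})

test_that("no-response MLE has the closed-form properties", {
  f <- fit_no_response(rep(0, 20))
  expect_equal(f$coefficients[["mu"]], 0)
  expect_equal(f$coefficients[["kappa"]], 1e4)   # capped
  f2 <- fit_no_response(c(0, pi / 2, pi, -pi / 2, 0, pi / 2, pi, -pi / 2))
  expect_equal(f2$coefficients[["kappa"]], 0)
  expect_error(fit_no_response(c(0, 1)), "insufficient")
  set.seed(21)
  f3 <- fit_no_response(rvonmises(1000, 0.5, 2))
  expect_lt(abs(f3$coefficients[["mu"]] - 0.5), 0.1)
  expect_lt(abs(f3$coefficients[["kappa"]] - 2), 0.3)
})

test_that("responsive fit nests the no-response model", {
  set.seed(31)
  # data generated with constant concentration (theta2 = 0)
  d <- data.frame(T = runif(400, 0, 500), A = rvonmises(400, 1, 2))
  f0 <- vm_response(A ~ 1, d)
  f1 <- vm_response(A ~ T, d)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  # and never does worse on arbitrary data
  for (s in 1:5) {
    set.seed(s)
    dd <- data.frame(T = runif(80, 0, 300),
                     A = wrap_angle(rnorm(80, 0, 2)))
    expect_gte(vm_response(A ~ T, dd)$loglik, vm_response(A ~ 1, dd)$loglik - 1e-6)
  }
})

test_that("responsive fit recovers generating parameters", {
  set.seed(17)
  T <- runif(2000, 0, 500)
  A <- rvonmises(2000, 0, 5 * exp(-0.005 * T))
  f <- fit_responsive(A, T)
  cf <- coef(f)
  expect_lt(abs(wrap_angle(cf[["mu"]])), 0.1)
  expect_gt(cf[["theta1"]], 3.5); expect_lt(cf[["theta1"]], 7)
  expect_gt(cf[["theta2"]], 0.003); expect_lt(cf[["theta2"]], 0.008)
  # fitted concentration vanishes far away: predicted density -> uniform
  k_far <- predict(f, data.frame(T = 5000, A = 0), type = "kappa")
  expect_lt(k_far, 0.05)
  expect_equal(predict(f, data.frame(T = 5e4, A = 1.2), type = "density"),
               1 / (2 * pi), tolerance = 1e-3)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_responsive(rep(0.1, 20), rep(100, 20)), "all equal")
  expect_error(fit_responsive(rep(0.1, 5), 1:5), "insufficient")
})

test_that("likelihood-ratio mapping matches chi-square(1) and guards input", {
  p_of <- function(stat) pchisq(stat, 1, lower.tail = FALSE)
  expect_equal(round(p_of(8.7), 2), 0.00)
  expect_equal(round(p_of(2.6), 2), 0.11)
  expect_equal(p_of(0), 1)
  set.seed(41)
  d <- data.frame(T = runif(300, 0, 400))
  d$A <- rvonmises(300, 0.5, 4 * exp(-0.01 * d$T))
  f0 <- vm_response(A ~ 1, d); f1 <- vm_response(A ~ T, d)
  lt <- lr_test(f0, f1)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$p_value, p_of(lt$statistic))
  a <- anova(f0, f1)
  expect_equal(a$Chisq[2], lt$statistic)
  f0b <- fit_no_response(d$A[1:100])
  expect_error(lr_test(f0b, f1), "different numbers")
})

test_that("qualitative classification follows |mu| and significance", {
  mk <- function(absmu) {
    f <- list(coefficients = c(mu = absmu, theta1 = 2, theta2 = 0.004),
              model = "responsive")
    class(f) <- c("vm_responsive", "vm_response")
    f
  }
  expect_equal(classify_response(mk(0.24), TRUE), "attraction")
  expect_equal(classify_response(mk(3.08), TRUE), "avoidance")
  expect_equal(classify_response(mk(1.61), TRUE), "parallel")
  expect_equal(classify_response(mk(0.24), FALSE), "indifference")
  lt <- structure(list(statistic = 2.3, df = 1L,
                       p_value = pchisq(2.3, 1, lower.tail = FALSE)),
                  class = "lr_test")
  expect_equal(classify_response(mk(2.30), lt), "indifference")
})

test_that("model methods (predict, simulate, residuals, summary) are coherent", {
  set.seed(19)
  d <- data.frame(T = runif(500, 0, 400))
  d$A <- rvonmises(500, 0.8, 6 * exp(-0.01 * d$T))
  f <- vm_response(A ~ T, d)
  k <- predict(f, data.frame(T = c(0, 100), A = c(0, 0)))
  expect_gt(k[1], k[2])   # concentration decays with distance
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(abs(unlist(sims)) <= pi))
  r <- residuals(f)
  expect_true(all(r > -pi & r <= pi))
  s <- summary(f)
  expect_equal(s$abs_mu, abs(coef(f)[["mu"]]))
  expect_equal(s$half_distance, log(2) / coef(f)[["theta2"]])
  expect_equal(as.numeric(logLik(f)), f$loglik)
})

test_that("simulated angles reproduce the fitted distribution", {
  set.seed(23)
  f <- fit_no_response(rvonmises(800, -1, 3))
  sim <- simulate(f, nsim = 1, seed = 5,
                  newdata = data.frame(A = numeric(2000), T = numeric(2000)))[[1]]
  refit <- fit_no_response(sim)
  expect_lt(abs(wrap_angle(refit$coefficients[["mu"]] - f$coefficients[["mu"]])), 0.1)
  expect_lt(abs(refit$coefficients[["kappa"]] - f$coefficients[["kappa"]]), 0.5)
})
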