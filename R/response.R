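#' Response angles of movement steps toward the highway
#'
#' For each step, the animal-to-highway angle `C` is the bearing from the
#' step's start to the nearest point of the highway, the move angle `B` is
#' the step heading, and the response angle is `A = wrap(B - C)`: 0 means
#' moving straight toward the highway, +/-pi straight away, +/-pi/2
#' parallel. The distance `T` is measured at the step's start (the response
#' is decided before moving).
#'
#' @param track an [animal_track()] or a [build_steps()] table.
#' @param hwy a [highway()].
#' @param active_only drop steps with an inactive endpoint (resting
#'   animals do not express a movement response).
#' @param max_gap passed to [build_steps()] when `track` is a track.
#' @return data.frame of class `response_angles`: columns A, B, C, T,
#'   session_id.
#' @export
response_angles <- function(track, hwy, active_only = TRUE, max_gap = 90) {
  steps <- if (inherits(track, "steps")) track else build_steps(track, max_gap)
  if (active_only && nrow(steps))
    steps <- steps[steps$active0 & steps$active1, , drop = FALSE]
  steps <- steps[is.finite(steps$heading), , drop = FALSE]
  if (nrow(steps) == 0)
    return(structure(data.frame(A = numeric(0), B = numeric(0),
                                C = numeric(0), T = numeric(0),
                                session_id = character(0)),
                     class = c("response_angles", "data.frame")))
  loc <- hw_locate(steps$x0, steps$y0, hwy)
  structure(data.frame(A = wrap_angle(steps$heading - loc$bearing),
                       B = steps$heading, C = loc$bearing,
                       T = loc$distance, session_id = steps$session_id),
            class = c("response_angles", "data.frame"))
}

# -- fitting -----------------------------------------------------------------

#' Fit von Mises response-angle models
#'
#' Fits, by maximum likelihood, either the *no-response* model — response
#' angles are von Mises with constant mean `mu` and constant concentration
#' `kappa` — or the *responsive* model, in which the concentration decays
#' exponentially with distance to the highway,
#' `kappa(T) = theta1 * exp(-theta2 * T)`, so the movement direction is
#' most constrained at the highway and approaches uniform far from it.
#' The two models are nested (`theta2 = 0` recovers constant
#' concentration) and are compared with [anova()] / [lr_test()] on 1 df.
#'
#' A formula interface mirrors other R modelling functions:
#' `vm_response(A ~ 1, data)` fits the no-response model and
#' `vm_response(A ~ T, data)` the responsive model, where the right-hand
#' variable is the distance to the highway (m).
#'
#' @param formula model formula; left side the response angle (rad), right
#'   side `1` or the distance variable.
#' @param data data.frame holding the variables (e.g. the output of
#'   [response_angles()]).
#' @param n_starts responsive model only: number of optimizer starts drawn
#'   from the grid mu in \{0, +/-pi/2, pi\} x theta1 in \{0.5, 5\}, with
#'   theta2 started at 1/median(T). The likelihood is multimodal in mu.
#' @return object of class `vm_response` (and `vm_no_response` or
#'   `vm_responsive`): list with `coefficients`, `loglik`, `n`, `model`,
#'   and the data used.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(T = runif(300, 0, 400))
#' d$A <- rvonmises(300, 0.5, 4 * exp(-0.01 * d$T))
#' f0 <- vm_response(A ~ 1, d)
#' f1 <- vm_response(A ~ T, d)
#' anova(f0, f1)
vm_response <- function(formula, data, n_starts = 8) {
  mf <- stats::model.frame(formula, data)
  a <- wrap_angle(stats::model.response(mf))
  rhs <- attr(stats::terms(formula), "term.labels")
  if (length(rhs) == 0) {
    fit_no_response(a)
  } else if (length(rhs) == 1) {
    fit_responsive(a, mf[[rhs]], n_starts = n_starts)
  } else stop("formula must be angle ~ 1 or angle ~ distance")
}

#' Fit the constant-concentration (no-response) model
#'
#' Closed-form von Mises MLE: the mean direction is the angle of the
#' vector resultant and the concentration solves A1(kappa) = mean
#' resultant length (capped at 1e4 for degenerate samples).
#'
#' @param a response angles (rad).
#' @return `vm_response` fit with coefficients `mu`, `kappa`.
#' @export
fit_no_response <- function(a) {
  a <- wrap_angle(a)
  n <- length(a)
  if (n < 5) stop("insufficient angles (need >= 5)")
  S <- sum(sin(a)); C <- sum(cos(a))
  mu <- atan2(S, C)
  rbar <- sqrt(S^2 + C^2) / n
  kappa <- A1inv(rbar)
  ll <- sum(dvonmises(a, mu, kappa))
  structure(list(coefficients = c(mu = mu, kappa = kappa),
                 loglik = ll, n = n, model = "no-response",
                 data = data.frame(A = a)),
            class = c("vm_no_response", "vm_response"))
}

# negative log-likelihood of the responsive model, vectorized over obs
nll_responsive <- function(par, a, T) {
  mu <- par[1]; th1 <- par[2]; th2 <- par[3]
  if (th1 < 0 || th2 < 0) return(Inf)
  kap <- th1 * exp(-th2 * T)
  -sum(dvonmises(a, mu, kap))
}

# analytic gradient (d log I0 / d kappa = A1(kappa))
nll_responsive_grad <- function(par, a, T) {
  mu <- par[1]; th1 <- max(par[2], 0); th2 <- max(par[3], 0)
  e <- exp(-th2 * T)
  kap <- th1 * e
  resid <- cos(a - mu) - A1(kap)
  c(-sum(kap * sin(a - mu)),
    -sum(resid * e),
    sum(resid * th1 * T * e))
}

#' Fit the distance-decaying (responsive) model
#'
#' Maximum likelihood over (mu, theta1, theta2) with theta1, theta2 >= 0,
#' by box-constrained quasi-Newton optimization from multiple starts. The
#' no-response MLE is always included as a start (with theta2 = 0), which
#' guarantees the fitted log-likelihood is at least the nested model's.
#'
#' @param a response angles (rad).
#' @param T distances to the highway (m), same length as `a`.
#' @param n_starts number of grid starts (see [vm_response()]).
#' @return `vm_response` fit with coefficients `mu`, `theta1`, `theta2`.
#' @export
fit_responsive <- function(a, T, n_starts = 8) {
  a <- wrap_angle(a)
  stopifnot(length(T) == length(a), all(T >= 0))
  n <- length(a)
  if (n < 10) stop("insufficient angles (need >= 10)")
  if (length(unique(T)) == 1) stop("distances are all equal; model unidentifiable")
  th2_0 <- 1 / max(stats::median(T), 1e-6)
  starts <- expand.grid(mu = c(0, pi / 2, -pi / 2, pi),
                        th1 = c(0.5, 5), th2 = th2_0)
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  f0 <- fit_no_response(a)
  starts <- rbind(starts,
                  data.frame(mu = f0$coefficients[["mu"]],
                             th1 = max(f0$coefficients[["kappa"]], 1e-4),
                             th2 = 0))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- try(stats::optim(unlist(starts[s, ]), nll_responsive,
                          gr = nll_responsive_grad, a = a, T = T,
                          method = "L-BFGS-B",
                          lower = c(-2 * pi, 0, 0),
                          upper = c(2 * pi, 1e4, 1)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("responsive fit failed to converge from any start")
  ll <- -best$value
  # numerical safety: never report below the nested model
  if (ll < f0$loglik) {
    best$par <- c(f0$coefficients[["mu"]], f0$coefficients[["kappa"]], 0)
    ll <- f0$loglik
  }
  structure(list(coefficients = c(mu = wrap_angle(unname(best$par[1])),
                                  theta1 = unname(best$par[2]),
                                  theta2 = unname(best$par[3])),
                 loglik = ll, n = n, model = "responsive",
                 data = data.frame(A = a, T = T)),
            class = c("vm_responsive", "vm_response"))
}

# -- methods -----------------------------------------------------------------

#' @export
print.vm_response <- function(x, digits = 3, ...) {
  cat(sprintf("von Mises %s model (n = %d)\n", x$model, x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.vm_response <- function(object, ...) object$coefficients

#' @export
logLik.vm_response <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
summary.vm_response <- function(object, ...) {
  cf <- object$coefficients
  out <- list(model = object$model, n = object$n, coefficients = cf,
              abs_mu = abs(cf[["mu"]]), loglik = object$loglik)
  if (object$model == "responsive") {
    # concentration half-distance: distance at which kappa halves
    out$half_distance <- if (cf[["theta2"]] > 0) log(2) / cf[["theta2"]] else Inf
  }
  class(out) <- "summary.vm_response"
  out
}

#' @export
print.summary.vm_response <- function(x, ...) {
  cat(sprintf("von Mises %s model, n = %d\n", x$model, x$n))
  cat(sprintf("  |mu| = %.2f rad (reported 0..pi)\n", x$abs_mu))
  if (!is.null(x$half_distance))
    cat(sprintf("  theta1 = %.2f, theta2 = %.4f /m (half-distance %.0f m)\n",
                x$coefficients[["theta1"]], x$coefficients[["theta2"]],
                x$half_distance))
  else
    cat(sprintf("  kappa = %.2f\n", x$coefficients[["kappa"]]))
  cat(sprintf("  log-likelihood %.2f\n", x$loglik))
  invisible(x)
}

#' Predicted concentration and density of a fitted response model
#'
#' @param object a `vm_response` fit.
#' @param newdata data.frame with a `T` column (ignored by the no-response
#'   model); defaults to the fitting data.
#' @param type `"kappa"` for the concentration at each distance, or
#'   `"density"` for the von Mises density evaluated at `newdata$A`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.vm_response <- function(object, newdata = NULL, type = c("kappa", "density"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  cf <- object$coefficients
  kap <- if (object$model == "responsive")
    cf[["theta1"]] * exp(-cf[["theta2"]] * newdata$T)
  else rep(cf[["kappa"]], nrow(newdata))
  if (type == "kappa") return(kap)
  dvonmises(newdata$A, cf[["mu"]], kap, log = FALSE)
}

#' Simulate response angles from a fitted model
#'
#' @param object a `vm_response` fit.
#' @param nsim number of replicate angle vectors.
#' @param seed optional RNG seed.
#' @param newdata distances to simulate at (data.frame with `T`); default
#'   the fitting data.
#' @param ... unused.
#' @return list of numeric vectors of length `nrow(newdata)`.
#' @export
simulate.vm_response <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data
  kap <- predict(object, newdata, type = "kappa")
  mu <- object$coefficients[["mu"]]
  lapply(seq_len(nsim), function(i) rvonmises(length(kap), mu, kap))
}

#' Residuals of a fitted response model
#'
#' Wrapped angular residuals `wrap(A - mu)`; under a good fit their
#' circular dispersion matches the fitted concentration at each distance.
#'
#' @param object a `vm_response` fit.
#' @param ... unused.
#' @export
residuals.vm_response <- function(object, ...) {
  wrap_angle(object$data$A - object$coefficients[["mu"]])
}

#' Plot a fitted response model
#'
#' Responsive fits show the response angles against distance with the
#' fitted concentration decay overlaid; no-response fits show a rose-style
#' histogram of the angles with the fitted density.
#'
#' @param x a `vm_response` fit.
#' @param ... passed to the underlying plot call.
#' @export
plot.vm_response <- function(x, ...) {
  if (x$model == "responsive") {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::plot(x$data$T, x$data$A, pch = 16, cex = 0.5,
                   xlab = "distance to highway (m)",
                   ylab = "response angle (rad)", ...)
    graphics::abline(h = x$coefficients[["mu"]], lty = 2)
    Ts <- seq(0, max(x$data$T), length.out = 200)
    graphics::plot(Ts, predict(x, data.frame(T = Ts, A = 0)), type = "l",
                   xlab = "distance to highway (m)",
                   ylab = "concentration kappa(T)")
  } else {
    h <- graphics::hist(x$data$A, breaks = seq(-pi, pi, length.out = 25),
                        freq = FALSE, xlab = "response angle (rad)",
                        main = "no-response fit", ...)
    as <- seq(-pi, pi, length.out = 400)
    graphics::lines(as, dvonmises(as, x$coefficients[["mu"]],
                                  x$coefficients[["kappa"]], log = FALSE))
    invisible(h)
  }
  invisible(x)
}

# -- model comparison --------------------------------------------------------

#' Likelihood-ratio test of responsive vs no-response model
#'
#' 2 * (loglik_responsive - loglik_no_response) against chi-square with
#' 1 df (the decay parameter); the statistic is clamped at 0 since the
#' models are nested.
#'
#' @param fit0 the no-response fit.
#' @param fit1 the responsive fit on the same observations.
#' @return list of class `lr_test`: statistic, df, p_value.
#' @export
lr_test <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "vm_no_response"), inherits(fit1, "vm_responsive"))
  if (fit0$n != fit1$n) stop("fits use different numbers of observations")
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test: chi^2(%d) = %.1f, p = %.2f\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' @export
anova.vm_response <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) != 2) stop("supply exactly two nested fits")
  is0 <- vapply(fits, inherits, TRUE, what = "vm_no_response")
  lt <- lr_test(fits[[which(is0)]], fits[[which(!is0)]])
  out <- data.frame(df = vapply(fits, function(f) length(f$coefficients), 1),
                    logLik = vapply(fits, `[[`, 1, "loglik"),
                    row.names = make.unique(vapply(fits, `[[`, "", "model")))
  out$Chisq <- c(NA, lt$statistic)
  out$`Pr(>Chisq)` <- c(NA, lt$p_value)
  structure(out, heading = "Likelihood-ratio comparison",
            class = c("anova", "data.frame"))
}

#' Classify the qualitative highway response
#'
#' If the LR test is not significant the animal is labelled indifferent.
#' Otherwise the absolute mean response angle decides: |mu| < pi/4 is
#' attraction (moving toward), |mu| > 3*pi/4 avoidance (moving away), and
#' intermediate values parallel movement along the highway.
#'
#' @param fit1 a responsive `vm_response` fit.
#' @param significant logical, or an `lr_test` result (compared at `alpha`).
#' @param alpha significance level when `significant` is an `lr_test`.
#' @return one of `"attraction"`, `"avoidance"`, `"parallel"`,
#'   `"indifference"`.
#' @export
classify_response <- function(fit1, significant, alpha = 0.05) {
  if (inherits(significant, "lr_test"))
    significant <- significant$p_value < alpha
  if (!isTRUE(significant)) return("indifference")
  am <- abs(fit1$coefficients[["mu"]])
  if (am < pi / 4) "attraction"
  else if (am > 3 * pi / 4) "avoidance"
  else "parallel"
}
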