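#' Wrap angles to (-pi, pi]
#'
#' All circular quantities in this package (step headings, animal-to-barrier
#' bearings, response angles) live on (-pi, pi], measured counter-clockwise
#' from the +x axis of the projected plane.
#'
#' @param a numeric vector of angles (radians).
#' @return numeric vector wrapped to (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(a) {
  w <- a %% (2 * pi)          # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  # %% can leave w == -pi for inputs like -pi - 2*pi*eps; fold onto +pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' von Mises log-density
#'
#' Log-density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`: log f(a) = kappa*cos(a - mu) - log(2*pi*I0(kappa)).
#' Uses the exponentially scaled Bessel function so it is stable up to
#' kappa = 1e4. `kappa = 0` gives the circular uniform, log(1/(2*pi)).
#'
#' @param a angles (radians); recycled against `kappa`.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter(s), >= 0.
#' @param log if `FALSE`, return the density instead.
#' @return numeric vector of log-densities (or densities).
#' @export
dvonmises <- function(a, mu, kappa, log = TRUE) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  # besselI(x, 0, expon.scaled) = I0(x) * exp(-x)
  ld <- kappa * cos(a - mu) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE)) - kappa
  if (log) ld else exp(ld)
}

#' von Mises random deviates
#'
#' Best-Fisher (1979) rejection sampler. Used by the synthetic-telemetry
#' generator and by `simulate()` on fitted response models.
#'
#' @param n number of deviates.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0 (0 gives uniform on (-pi, pi]).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (length(kappa) == 1L) kappa <- rep(kappa, n)
  if (length(mu) == 1L) mu <- rep(mu, n)
  stopifnot(length(kappa) == n, length(mu) == n)
  out <- numeric(n)
  unif <- kappa < 1e-9
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  idx <- which(!unif)
  for (i in idx) {
    k <- kappa[i]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    r <- (1 + rho^2) / (2 * rho)
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c0 <- k * (r - f)
      u2 <- stats::runif(1)
      if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
        u3 <- stats::runif(1)
        out[i] <- sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + mu)
}

# Mean resultant length of the von Mises: A1(kappa) = I1(kappa)/I0(kappa)
A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert A1 by root-finding; capped so degenerate (all-identical) samples
# return a finite concentration.
A1inv <- function(r, cap = 1e4) {
  if (r <= 1e-6) return(0)   # A1(k) ~ k/2 near 0: kappa indistinguishable from 0
  if (A1(cap) <= r) return(cap)
  stats::uniroot(function(k) A1(k) - r, lower = 1e-8, upper = cap,
                 tol = 1e-10)$root
}
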