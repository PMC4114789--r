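#' Available habitat proportions from a utilization distribution
#'
#' Availability is defined by the UD itself: for each land-cover class the
#' UD mass over cells of that class is summed, and the sums are
#' renormalized over the chosen classes (conventionally forest vs
#' agricultural). Each UD cell is assigned the land-cover class at its
#' center.
#'
#' @param ud a [ud_raster()].
#' @param lc a [landcover()].
#' @param classes character vector of class names to keep.
#' @return named numeric vector of proportions summing to 1.
#' @export
availability_from_ud <- function(ud, lc, classes = c("forest", "agricultural")) {
  cc <- ud_cell_centers(ud)
  gx <- rep(cc$x, times = length(cc$y))
  gy <- rep(cc$y, each = length(cc$x))
  cl <- landcover_class_at(lc, gx, gy)
  mass <- vapply(classes, function(k) {
    ki <- match(k, lc$classes)
    sum(ud$z[!is.na(cl) & cl == ki])
  }, numeric(1))
  if (sum(mass) <= 0) stop("UD has no mass over the requested classes")
  mass / sum(mass)
}

#' Used habitat proportions from fixes
#'
#' Proportion of an animal's fixes falling in each class, renormalized
#' over the chosen classes.
#'
#' @param track an [animal_track()].
#' @param lc a [landcover()].
#' @param classes classes to keep.
#' @return named numeric vector of proportions summing to 1.
#' @export
use_from_fixes <- function(track, lc, classes = c("forest", "agricultural")) {
  cl <- landcover_class_at(lc, track$fixes$x, track$fixes$y)
  counts <- vapply(classes, function(k)
    sum(cl == match(k, lc$classes), na.rm = TRUE), numeric(1))
  if (sum(counts) == 0) stop("no fixes fall in the requested classes")
  counts / sum(counts)
}

#' Assemble a composition table across animals
#'
#' @param used matrix (animals x classes) of used proportions, rows
#'   summing to 1.
#' @param available matrix of available proportions, same shape.
#' @param weights per-animal weights (fix counts); unequal tracking effort
#'   across animals is downweighted accordingly.
#' @return data.frame of class `composition_table`.
#' @export
composition_table <- function(used, available, weights) {
  used <- as.matrix(used); available <- as.matrix(available)
  stopifnot(identical(dim(used), dim(available)),
            length(weights) == nrow(used), all(weights > 0),
            all(used >= 0), all(available >= 0))
  if (any(abs(rowSums(used) - 1) > 1e-8) ||
      any(abs(rowSums(available) - 1) > 1e-8))
    stop("used and available proportions must sum to 1 per animal")
  out <- data.frame(used, available, weight = weights)
  names(out) <- c(paste0("used_", colnames(used)),
                  paste0("avail_", colnames(available)), "weight")
  structure(out, classes = colnames(used),
            class = c("composition_table", "data.frame"))
}

#' Weighted compositional test of habitat selection (two classes)
#'
#' For each animal the selection signal is the log-ratio difference
#' d = ln(used_1/used_2) - ln(avail_1/avail_2) (zero proportions replaced
#' by 0.01 and the pair renormalized, the standard compositional fix).
#' Wilks' Lambda for the weighted one-sample test of mean d = 0 is
#' Lambda = SS_resid / SS_total = sum w (d - dbar_w)^2 / sum w d^2,
#' which is 1 when the weighted mean is 0 and shrinks as selection
#' strengthens. Significance comes from a sign-randomization test: under
#' no selection each animal's d is symmetric about 0, so the observed
#' Lambda is compared with Lambdas after random sign flips;
#' p = (1 + #\{Lambda_perm <= Lambda_obs\}) / (n_perm + 1). With n
#' animals <= `exhaustive_n`, all 2^n sign patterns are enumerated and
#' the p-value is exact.
#'
#' @param table a [composition_table()] with exactly two classes.
#' @param n_perm number of random sign patterns (ignored when
#'   enumerating).
#' @param seed RNG seed for the randomization.
#' @param exhaustive_n enumerate all sign patterns when the number of
#'   animals is at most this.
#' @return list of class `composition_result`: lambda, p_value, d
#'   (per-animal log-ratio differences), ranking (classes ordered by
#'   weighted mean selection).
#' @export
compositional_test <- function(table, n_perm = 1000, seed = 1,
                               exhaustive_n = 10) {
  stopifnot(inherits(table, "composition_table"))
  classes <- attr(table, "classes")
  if (length(classes) != 2) stop("this test is for exactly two classes")
  n <- nrow(table)
  if (n < 2) stop("need >= 2 animals")
  zfix <- function(p) { p[p == 0] <- 0.01; p / sum(p) }
  d <- numeric(n)
  for (i in seq_len(n)) {
    u <- zfix(c(table[i, 1], table[i, 2]))
    a <- zfix(c(table[i, 3], table[i, 4]))
    d[i] <- log(u[1] / u[2]) - log(a[1] / a[2])
  }
  w <- table$weight / sum(table$weight)
  lambda_of <- function(dd) {
    sst <- sum(w * dd^2)
    if (sst == 0) return(1)
    dbar <- sum(w * dd)
    sum(w * (dd - dbar)^2) / sst
  }
  obs <- lambda_of(d)
  if (n <= exhaustive_n) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- apply(signs, 1, function(s) lambda_of(s * d))
    p <- mean(perm <= obs + 1e-12)
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, lambda_of(sample(c(-1, 1), n, replace = TRUE) * d))
    p <- (1 + sum(perm <= obs + 1e-12)) / (n_perm + 1)
  }
  ranking <- if (sum(w * d) >= 0) classes else rev(classes)
  structure(list(lambda = obs, p_value = p, d = d, ranking = ranking,
                 n = n), class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("Weighted compositional analysis (%d animals): Lambda = %.2f, p = %.2f\n",
              x$n, x$lambda, x$p_value))
  cat("  selection ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
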