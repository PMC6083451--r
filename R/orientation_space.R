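#' Circular coordinate conventions and summary statistics
#'
#' Orientation stimuli live on the half-circle \eqn{[-90^\circ, 90^\circ)};
#' all internal computation maps them onto the full circle
#' \eqn{[-\pi, \pi)} radians via \eqn{\theta_{rad} = \theta_{deg} \cdot
#' \pi / 90}, so that standard circular statistics apply. Conversion
#' happens only at the I/O boundary; every angle handled by the package
#' is in mapped radians.
#'
#' @param deg orientation(s) in degrees on \eqn{[-90, 90)}
#' @return mapped radians in \eqn{[-\pi, \pi)}
#' @export
deg_to_rad <- function(deg) wrap_angle(deg * pi / 90)

#' @rdname deg_to_rad
#' @param rad mapped radians
#' @return degrees on \eqn{[-90, 90)}
#' @export
rad_to_deg <- function(rad) wrap_angle(rad) * 90 / pi

#' Wrap angles into \eqn{[-\pi, \pi)}
#'
#' @param x numeric vector of angles (radians)
#' @return angles wrapped into \eqn{[-\pi, \pi)}
#' @export
wrap_angle <- function(x) {
  out <- ((x + pi) %% (2 * pi)) - pi
  # floating point can land exactly on pi (e.g. wrap of -pi - eps)
  out[out >= pi] <- out[out >= pi] - 2 * pi
  out
}

#' Circular difference a - b, wrapped
#'
#' Angular deviation between two orientations, e.g. between a reported
#' and a true target orientation (the recall error).
#'
#' @param a,b angles in mapped radians
#' @return wrapped difference in \eqn{[-\pi, \pi)}
#' @export
circ_diff <- function(a, b) wrap_angle(a - b)

#' Weighted circular summary statistics
#'
#' Computes the (weighted) circular mean, resultant length, circular
#' standard deviation and precision of a sample of angles. Precision is
#' defined as the reciprocal of the squared circular standard deviation,
#' \eqn{1/\sigma^2}. When the sample is perfectly concentrated
#' (\eqn{\sigma = 0}) precision is capped at \eqn{1/\epsilon^2} with
#' \eqn{\epsilon = 10^{-6}} rad and the result is flagged degenerate.
#'
#' @param x angles in radians
#' @param weights optional nonnegative weights, same length as `x`
#' @return an object of class `circ_summary`: a list with elements
#'   `mean`, `resultant_length`, `circ_sd`, `precision`, `n`,
#'   `degenerate`
#' @export
circ_summary <- function(x, weights = NULL) {
  if (length(x) == 0L) stop("circ_summary: empty input")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x)) {
    stop("circ_summary: weights must match x in length")
  }
  if (any(weights < 0)) stop("circ_summary: negative weights")
  wsum <- sum(weights)
  if (wsum <= 0) stop("circ_summary: all weights are zero")
  c_ <- sum(weights * cos(x)) / wsum
  s_ <- sum(weights * sin(x)) / wsum
  r <- min(1, sqrt(c_^2 + s_^2))
  mu <- atan2(s_, c_)
  eps <- 1e-6
  degenerate <- (r >= 1 - .Machine$double.eps * 8)
  sd_ <- if (degenerate) 0 else sqrt(-2 * log(r))
  prec <- if (sd_ < eps) 1 / eps^2 else 1 / sd_^2
  structure(
    list(
      mean = wrap_angle(mu), resultant_length = r, circ_sd = sd_,
      precision = prec, n = length(x), degenerate = degenerate
    ),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "circular summary (n = %d): mean %.4f rad, R %.4f, sd %.4f rad, precision %.4g%s\n",
    x$n, x$mean, x$resultant_length, x$circ_sd, x$precision,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Von Mises kernel concentration matched to a circular SD
#'
#' Solves \eqn{I_1(\kappa)/I_0(\kappa) = \exp(-h^2/2)} so that the von
#' Mises kernel has circular standard deviation exactly `h`.
#'
#' @param h circular SD of the kernel (radians, > 0)
#' @return concentration parameter \eqn{\kappa}
#' @export
vm_kappa_from_sd <- function(h) {
  stopifnot(is.numeric(h), length(h) == 1L, h > 0)
  target <- exp(-h^2 / 2)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  # huge bandwidth: kernel indistinguishable from uniform (kappa = 0)
  if (target <= A(1e-8)) return(0)
  # tiny bandwidth: besselI underflows past ~1e5; use the large-kappa
  # asymptotic circular SD ~ 1/sqrt(kappa)
  if (target >= A(1e5)) return(1 / h^2)
  stats::uniroot(function(k) A(k) - target, lower = 1e-8, upper = 1e5, tol = 1e-12)$root
}

#' Von Mises density (numerically stable)
#'
#' @param x angle(s) relative to the mean (radians)
#' @param mu mean direction (radians)
#' @param kappa concentration (>= 0); `kappa = 0` gives the circular
#'   uniform density
#' @return density values (1/radians)
#' @export
dvonmises <- function(x, mu = 0, kappa = 1) {
  # exp(k cos d) / (2 pi I0(k)), computed on the exp-scaled bessel to
  # survive kappa of several hundred
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Von Mises random deviates
#'
#' Best--Fisher (1979) rejection sampler, vectorised over per-draw
#' concentrations. Consumes the current RNG stream.
#'
#' @param n number of draws
#' @param mu mean direction(s), recycled to length `n`
#' @param kappa concentration(s), recycled to length `n`
#' @return `n` angles in \eqn{[-\pi, \pi)}
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  tiny <- kappa < 1e-8
  if (any(tiny)) out[tiny] <- stats::runif(sum(tiny), -pi, pi)
  pending <- which(!tiny)
  if (length(pending)) {
    k <- kappa[pending]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    b <- (1 + rho^2) / (2 * rho)
    val <- numeric(length(pending))
    todo <- seq_along(pending)
    while (length(todo)) {
      m <- length(todo)
      u1 <- stats::runif(m)
      u2 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + b[todo] * z) / (b[todo] + z)
      c_ <- k[todo] * (b[todo] - f)
      ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
      if (any(ok)) {
        u3 <- stats::runif(sum(ok))
        val[todo[ok]] <- sign(u3 - 0.5) * acos(f[ok])
      }
      todo <- todo[!ok]
    }
    out[pending] <- val
  }
  wrap_angle(mu + out)
}

#' Kernel-smoothed bias and precision curves
#'
#' Estimates recall bias (circular mean of error) and precision
#' (1/circular SD squared) as smooth functions of target orientation,
#' at 50 evenly spaced evaluation points (bin centers) on
#' \eqn{[-\pi, \pi)}. Observations are weighted by a von Mises kernel
#' centered on each evaluation point, with kernel circular SD `h_bias`
#' for the bias curve and `h_precision` for the precision curve
#' (the broader bias bandwidth tames the noisier raw bias estimates).
#' Weights are renormalised at every evaluation point by the weighted
#' circular mean itself. Intended to be applied per observer.
#'
#' @param targets target orientations (mapped radians)
#' @param errors recall errors (radians), same length
#' @param h_bias kernel SD for the bias curve (default 0.61 rad)
#' @param h_precision kernel SD for the precision curve (default 0.23 rad)
#' @param n_points number of evaluation points (default 50)
#' @return list with elements `bias` and `precision`, each a
#'   `smoothed_curve`: a list with `eval_points`, `values`, `bandwidth`,
#'   `n_effective`
#' @export
smooth_curves <- function(targets, errors, h_bias = 0.61, h_precision = 0.23,
                          n_points = 50L) {
  if (length(targets) != length(errors)) {
    stop("smooth_curves: targets and errors must have equal length")
  }
  if (length(targets) < 2L) stop("smooth_curves: need at least 2 trials")
  pts <- curve_eval_points(n_points)
  one <- function(h, what) {
    kap <- vm_kappa_from_sd(h)
    vals <- numeric(n_points)
    neff <- numeric(n_points)
    for (i in seq_len(n_points)) {
      w <- exp(kap * (cos(targets - pts[i]) - 1))
      s <- circ_summary(errors, weights = w)
      vals[i] <- if (what == "bias") s$mean else s$precision
      neff[i] <- sum(w)^2 / sum(w^2)
    }
    structure(
      list(eval_points = pts, values = vals, bandwidth = h, n_effective = neff),
      class = "smoothed_curve"
    )
  }
  list(bias = one(h_bias, "bias"), precision = one(h_precision, "precision"))
}

#' Evaluation grid used by smoothed curves (bin centers)
#' @param n_points number of points
#' @return `n_points` bin centers evenly spaced on \eqn{[-\pi, \pi)}
#' @export
curve_eval_points <- function(n_points = 50L) {
  -pi + (seq_len(n_points) - 0.5) * 2 * pi / n_points
}
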