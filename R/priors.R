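#' Circular stimulus priors
#'
#' Constructs a normalized circular density on \eqn{[-\pi, \pi)} used
#' both as the environmental stimulus distribution (the prior of the
#' Bayesian decoder) and as the warping measure for the efficient
#' population code. Built-in kinds:
#'
#' * `uniform`: \eqn{p(\theta) = 1/(2\pi)}.
#' * `natural_cardinal`: \eqn{p(\theta) \propto 2 - |\sin\theta|},
#'   bimodal with peaks at the cardinal orientations (0 and \eqn{\pm\pi}
#'   in mapped space, i.e. 0 and 90 degrees), approximating the
#'   distribution of orientations in natural scenes.
#' * `adapt_cardinal`: identical density to `natural_cardinal`; the
#'   congruent nontarget distribution of the adaptation experiment.
#' * `adapt_oblique`: \eqn{p(\theta) \propto 2 - |\cos\theta|}, peaks at
#'   the obliques (\eqn{\pm\pi/2} mapped, i.e. \eqn{\pm 45} degrees);
#'   the incongruent nontarget distribution.
#' * `custom`: any user-supplied nonnegative density, given either as a
#'   function of mapped radians or as a two-column table
#'   (`theta_rad`, `density`); normalized by trapezoidal quadrature on a
#'   dense grid.
#'
#' Built-in kinds use closed-form density and CDF; `custom` uses dense
#' tabulation (default 4096 intervals) with monotone linear
#' interpolation for CDF and quantiles.
#'
#' @param kind one of `"uniform"`, `"natural_cardinal"`,
#'   `"adapt_cardinal"`, `"adapt_oblique"`, `"custom"`
#' @param density for `kind = "custom"`: a vectorized function of theta
#'   (mapped radians), or a data.frame with columns `theta_rad`,
#'   `density`
#' @param n_grid tabulation resolution for CDF/quantile interpolation
#' @return an object of class `wm_prior`
#' @export
make_prior <- function(kind = c("uniform", "natural_cardinal", "adapt_cardinal",
                                "adapt_oblique", "custom"),
                       density = NULL, n_grid = 4096L) {
  kind <- match.arg(kind)
  z <- 4 * pi - 4 # normalizer of 2 - |sin| and 2 - |cos| over [-pi, pi)
  obj <- switch(kind,
    uniform = list(
      dens = function(theta) rep_len(1 / (2 * pi), length(theta)),
      cdf = function(theta) (theta + pi) / (2 * pi)
    ),
    natural_cardinal = ,
    adapt_cardinal = list(
      dens = function(theta) (2 - abs(sin(theta))) / z,
      cdf = function(theta) {
        s <- ifelse(theta <= 0, cos(theta) + 1, 3 - cos(theta))
        (2 * (theta + pi) - s) / z
      }
    ),
    adapt_oblique = list(
      dens = function(theta) (2 - abs(cos(theta))) / z,
      cdf = function(theta) {
        s <- ifelse(theta <= -pi / 2, -sin(theta),
          ifelse(theta <= pi / 2, 2 + sin(theta), 4 - sin(theta))
        )
        (2 * (theta + pi) - s) / z
      }
    ),
    custom = NULL
  )
  grid <- seq(-pi, pi, length.out = n_grid + 1L)
  if (kind == "custom") {
    if (is.null(density)) stop("make_prior: custom prior needs a density")
    if (is.data.frame(density)) {
      if (!all(c("theta_rad", "density") %in% names(density))) {
        stop("make_prior: density table needs columns theta_rad, density")
      }
      ord <- order(density$theta_rad)
      dfun <- stats::approxfun(density$theta_rad[ord], density$density[ord],
        rule = 2
      )
    } else if (is.function(density)) {
      dfun <- density
    } else {
      stop("make_prior: density must be a function or a data.frame")
    }
    dv <- dfun(grid)
    if (any(!is.finite(dv)) || any(dv < 0)) {
      stop("make_prior: density must be finite and nonnegative")
    }
    # trapezoid normalization; cdf by cumulative trapezoid on same grid
    h <- grid[2] - grid[1]
    total <- h * (sum(dv) - (dv[1] + dv[length(dv)]) / 2)
    if (total <= 0) stop("make_prior: density integrates to zero")
    dv <- dv / total
    cdf_tab <- c(0, cumsum((dv[-1] + dv[-length(dv)]) / 2 * h))
    cdf_tab <- cdf_tab / cdf_tab[length(cdf_tab)]
    # keep the exact (normalized) closure when a function was supplied;
    # only the CDF needs tabulation
    dens_fun <- if (is.function(density)) {
      force(dfun)
      function(theta) dfun(theta) / total
    } else {
      stats::approxfun(grid, dv, rule = 2)
    }
    cdf_fun <- stats::approxfun(grid, cdf_tab, rule = 2)
    obj <- list(dens = dens_fun, cdf = cdf_fun)
    cdf_vals <- cdf_tab
  } else {
    cdf_vals <- obj$cdf(grid)
  }
  # quantile table for inverse-CDF sampling (strictly increasing knots)
  keep <- c(TRUE, diff(cdf_vals) > 0)
  qfun <- stats::approxfun(cdf_vals[keep], grid[keep], rule = 2)
  structure(
    list(
      kind = kind, dens = obj$dens, cdf = obj$cdf, quantile = qfun,
      n_grid = as.integer(n_grid), grid = grid
    ),
    class = "wm_prior"
  )
}

#' @export
print.wm_prior <- function(x, ...) {
  cat(sprintf("wm_prior: kind '%s' (tabulation %d points)\n", x$kind, x$n_grid))
  invisible(x)
}

#' Prior density
#' @param prior a `wm_prior`
#' @param theta angle(s) in mapped radians
#' @return density values (1/radians)
#' @export
prior_density <- function(prior, theta) {
  stopifnot(inherits(prior, "wm_prior"))
  prior$dens(wrap_angle(theta))
}

#' Prior cumulative distribution function
#' @param prior a `wm_prior`
#' @param theta angle(s) in \eqn{[-\pi, \pi]}
#' @return cumulative probability in \eqn{[0, 1]}
#' @export
prior_cdf <- function(prior, theta) {
  stopifnot(inherits(prior, "wm_prior"))
  pmin(1, pmax(0, prior$cdf(pmin(pi, pmax(-pi, theta)))))
}

#' Efficient-coding warp map
#'
#' The CDF remapping \eqn{F(\theta) = 2\pi D(\theta) - \pi} that
#' redistributes a homogeneous population so that cellular density is
#' proportional to the prior: regions of high prior probability receive
#' more, and narrower, tuning functions.
#'
#' @param prior a `wm_prior`
#' @param theta angle(s) in mapped radians
#' @return warped angle(s) in \eqn{[-\pi, \pi]}
#' @export
warp_map <- function(prior, theta) {
  stopifnot(inherits(prior, "wm_prior"))
  # identity warp, exact to the bit: the warped population must reduce
  # to the homogeneous code under a uniform prior
  if (prior$kind == "uniform") return(pmin(pi, pmax(-pi, theta)))
  2 * pi * prior_cdf(prior, theta) - pi
}

#' Sample from a prior by inverse-CDF
#'
#' @param prior a `wm_prior`
#' @param n number of draws (>= 1)
#' @param seed optional integer seed; when supplied, the draw is
#'   reproducible and does not perturb the caller's RNG use pattern
#' @return `n` angles in \eqn{[-\pi, \pi)}
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "wm_prior"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  wrap_angle(prior$quantile(stats::runif(n)))
}
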