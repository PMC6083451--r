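#' Population configuration for the neural resource model
#'
#' The encoder is a population of `M` orientation-selective neurons with
#' von Mises tuning of shared basis width `kappa`, warped through the
#' CDF of the stimulus prior (efficient coding). Divisive normalization
#' fixes the total expected spike count at `gamma / N` for set size `N`,
#' spiking is Poisson over a unit decoding interval, and recall
#' estimates are the posterior mean of a Bayesian decoder that uses the
#' same prior.
#'
#' @param kappa basis tuning width (von Mises concentration, > 0)
#' @param gamma total population gain: expected spikes per trial at
#'   set size 1 (> 0)
#' @param prior a [make_prior()] object (default uniform)
#' @param M number of neurons (default 100)
#' @param T_decode decoding interval; fixed to 1
#' @return an object of class `wm_popconfig`
#' @export
population_config <- function(kappa, gamma, prior = make_prior("uniform"),
                              M = 100L, T_decode = 1) {
  stopifnot(
    is.numeric(kappa), kappa > 0, is.numeric(gamma), gamma > 0,
    inherits(prior, "wm_prior"), M >= 2, T_decode == 1
  )
  structure(
    list(
      kappa = kappa, gamma = gamma, prior = prior, M = as.integer(M),
      T_decode = 1, phi = -pi + 2 * pi * (seq_len(M) - 1) / M
    ),
    class = "wm_popconfig"
  )
}

#' @export
print.wm_popconfig <- function(x, ...) {
  cat(sprintf(
    "wm_popconfig: M = %d, kappa = %.3g, gamma = %.3g, prior '%s'\n",
    x$M, x$kappa, x$gamma, x$prior$kind
  ))
  invisible(x)
}

#' Unnormalized tuning responses
#'
#' Row i gives the peak-one tuning profile
#' \eqn{f_j(\theta_i) = \exp(\kappa(\cos(F(\theta_i) - \phi_j) - 1))}
#' where `F` is the prior's warp map and the preferred phases
#' \eqn{\phi_j} are evenly spaced. The gain prefactor of the classical
#' tuning equation is absorbed by normalization (see
#' [normalized_rates()]), so tuning is implemented peak-one for
#' numerical stability. With a uniform prior this is exactly the
#' homogeneous population.
#'
#' @param config a `wm_popconfig`
#' @param theta stimulus value(s), mapped radians
#' @return a `length(theta) x M` matrix of unnormalized rates
#' @export
tuning_rates <- function(config, theta) {
  stopifnot(inherits(config, "wm_popconfig"))
  ft <- warp_map(config$prior, theta)
  exp(config$kappa * (cos(outer(ft, config$phi, "-")) - 1))
}

#' Divisively normalized mean firing rates
#'
#' \eqn{r_j(\theta) = (\gamma/N)\, f_j(\theta) / \sum_k f_k(\theta)}:
#' normalization divides by the instantaneous population sum, so the
#' summed expected rate equals \eqn{\gamma/N} exactly for every
#' stimulus, prior, and tuning width (not just in the large-M limit).
#'
#' @param config a `wm_popconfig`
#' @param theta stimulus value(s), mapped radians
#' @param N set size (integer >= 1)
#' @return a `length(theta) x M` matrix; each row sums to `gamma / N`
#' @export
normalized_rates <- function(config, theta, N) {
  if (!(is.numeric(N) && length(N) == 1L && N >= 1 && N == round(N))) {
    stop("normalized_rates: N must be a positive integer")
  }
  f <- tuning_rates(config, theta)
  (config$gamma / N) * f / rowSums(f)
}

#' Poisson spike generation
#'
#' Independent Poisson draws per neuron over the unit decoding interval.
#'
#' @param rates vector (one stimulus) or matrix (rows = trials) of mean
#'   rates
#' @param seed optional integer seed
#' @return integer spike counts, same shape as `rates`
#' @export
sample_spikes <- function(rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(length(rates), as.numeric(rates))
  if (is.matrix(rates)) dim(n) <- dim(rates)
  n
}

#' Log-likelihood of stimulus values given a spike pattern
#'
#' Poisson log-likelihood
#' \eqn{\sum_j [n_j \ln r_j(\theta) - r_j(\theta) - \ln n_j!]} evaluated
#' on a grid of candidate stimulus values. Because normalization fixes
#' \eqn{\sum_j r_j(\theta) = \gamma/N}, the non-spike terms are constant
#' in theta; they are retained so the value matches the exact Poisson
#' pmf product. Rates are floored at 1e-12 inside the log (large kappa
#' underflows tuning tails).
#'
#' @param config a `wm_popconfig`
#' @param spikes integer vector of length M
#' @param theta_grid candidate stimulus values (nonempty)
#' @param N set size
#' @return log-likelihood at each grid value
#' @export
spike_loglik <- function(config, spikes, theta_grid, N) {
  stopifnot(length(theta_grid) >= 1L, length(spikes) == config$M)
  r <- normalized_rates(config, theta_grid, N)
  as.numeric(log(pmax(r, 1e-12)) %*% spikes) - config$gamma / N -
    sum(lgamma(spikes + 1))
}

#' Posterior-mean decoding of a spike pattern
#'
#' Evaluates the posterior \eqn{p(\theta | n) \propto L(\theta|n)
#' p(\theta)} on `n_grid` evenly spaced points and returns the circular
#' (resultant) mean of the posterior -- the arithmetic posterior mean is
#' ill-defined on the circle. If the posterior resultant is numerically
#' zero (e.g. zero spikes under a uniform prior) the estimate carries no
#' direction; a uniform random angle is returned and flagged, matching
#' the guessing behaviour implied by an uninformative posterior.
#'
#' @param config a `wm_popconfig`
#' @param spikes integer vector of length M
#' @param N set size
#' @param n_grid number of posterior evaluation points (>= 8,
#'   default 100)
#' @return a list with `estimate` (mapped radians) and `degenerate`
#'   (logical)
#' @export
decode_spikes <- function(config, spikes, N = 1L, n_grid = 100L) {
  stopifnot(n_grid >= 8L)
  grid <- -pi + 2 * pi * (seq_len(n_grid) - 1) / n_grid
  ll <- spike_loglik(config, spikes, grid, N)
  if (all(!is.finite(ll))) stop("decode_spikes: degenerate posterior (all -Inf)")
  w <- exp(ll - max(ll)) * prior_density(config$prior, grid)
  zc <- sum(w * cos(grid))
  zs <- sum(w * sin(grid))
  if (sqrt(zc^2 + zs^2) / sum(w) < 1e-12) {
    return(list(estimate = stats::runif(1, -pi, pi), degenerate = TRUE))
  }
  list(estimate = atan2(zs, zc), degenerate = FALSE)
}

# Vectorized encode -> spike -> decode for many trials at one set size.
# Consumes the current RNG stream. Returns responses (mapped radians).
simulate_responses <- function(config, targets, N, n_grid = 100L) {
  n <- length(targets)
  ut <- unique(targets)
  rates <- if (length(ut) <= n / 2) {
    normalized_rates(config, ut, N)[match(targets, ut), , drop = FALSE]
  } else {
    normalized_rates(config, targets, N)
  }
  spikes <- matrix(stats::rpois(n * config$M, as.numeric(rates)), nrow = n)
  grid <- -pi + 2 * pi * (seq_len(n_grid) - 1) / n_grid
  logr <- log(pmax(normalized_rates(config, grid, N), 1e-12)) # n_grid x M
  ll <- spikes %*% t(logr) # n x n_grid (theta-constant terms dropped)
  ll <- ll - ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
  pw <- prior_density(config$prior, grid)
  post <- exp(ll)
  zc <- as.numeric(post %*% (pw * cos(grid)))
  zs <- as.numeric(post %*% (pw * sin(grid)))
  tot <- as.numeric(post %*% pw)
  resp <- atan2(zs, zc)
  degen <- sqrt(zc^2 + zs^2) / tot < 1e-12
  if (any(degen)) resp[degen] <- stats::runif(sum(degen), -pi, pi)
  wrap_angle(resp)
}

#' Simulate continuous-report trials from the neural resource model
#'
#' Runs the full encode -> Poisson spike -> posterior-mean decode
#' pipeline for each target and repetition. All randomness (spikes and
#' degenerate-decode guesses) flows from a single generator seeded once
#' per call.
#'
#' @param config a `wm_popconfig`
#' @param targets target orientations (mapped radians)
#' @param N set size
#' @param reps repetitions per target (default 1)
#' @param seed optional integer seed
#' @param n_grid posterior grid resolution (default 100)
#' @return data.frame with columns `target`, `response` (mapped radians)
#' @export
simulate_trials <- function(config, targets, N, reps = 1L, seed = NULL,
                            n_grid = 100L) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tg <- rep(targets, each = reps)
  data.frame(
    target = tg,
    response = simulate_responses(config, tg, N, n_grid = n_grid)
  )
}
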