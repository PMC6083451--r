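#' Contamination mixture parameters
#'
#' A purely statistical model used to denoise block-wise bias
#' estimates: recall errors are a mixture of a von Mises component
#' whose mean shifts with target orientation as \eqn{\mu(\theta) =
#' \eta\sin(2\theta)}, and a uniform contaminant. `lambda` weights the
#' von Mises (memory) component, `1 - lambda` the contaminant. Positive
#' `eta` means repulsion from the cardinal orientations, negative means
#' attraction; no psychological interpretation is attached to `lambda`
#' or `kappa`.
#'
#' @param kappa von Mises concentration (> 0)
#' @param eta bias amplitude (radians; sign = direction)
#' @param lambda mixture weight of the von Mises component, in
#'   \eqn{[0, 1]}
#' @return an object of class `mixture_params`
#' @export
mixture_params <- function(kappa, eta, lambda) {
  stopifnot(kappa > 0, lambda >= 0, lambda <= 1)
  structure(
    list(kappa = kappa, eta = eta, lambda = lambda),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "mixture_params: kappa = %.3g, eta = %.3g, lambda = %.3g\n",
    x$kappa, x$eta, x$lambda
  ))
  invisible(x)
}

#' Contamination-mixture error density
#'
#' \eqn{p(\Delta\hat\theta | \theta) = \lambda\,
#' \mathrm{VM}(\Delta\hat\theta;\ \eta\sin(2\theta), \kappa) +
#' (1 - \lambda)/(2\pi)}.
#'
#' @param params a `mixture_params`
#' @param theta_target target orientation(s), mapped radians
#' @param error recall error(s) \eqn{\Delta\hat\theta}, radians
#' @return probability density (1/radians)
#' @export
mixture_density <- function(params, theta_target, error) {
  params$lambda * dvonmises(error, params$eta * sin(2 * theta_target), params$kappa) +
    (1 - params$lambda) / (2 * pi)
}

# negative log-likelihood on unconstrained parameters
# par = (log kappa, eta, logit lambda)
mixture_nll <- function(par, theta_target, error) {
  kappa <- exp(par[1])
  lambda <- stats::plogis(par[3])
  d <- lambda * dvonmises(error, par[2] * sin(2 * theta_target), kappa) +
    (1 - lambda) / (2 * pi)
  -sum(log(d))
}

#' Fit the contamination mixture to one block of trials
#'
#' Maximizes the summed log-likelihood of the observed errors by
#' Nelder--Mead simplex on unconstrained transformed parameters
#' (\eqn{\log\kappa}, \eqn{\eta}, \eqn{\mathrm{logit}\,\lambda}),
#' restarted from `restarts` random starting points
#' (\eqn{\kappa \sim U(0.5, 20)}, \eqn{\eta \sim U(-0.5, 0.5)},
#' \eqn{\lambda \sim U(0.5, 1)}) and keeping the best optimum.
#'
#' @param trials data.frame with columns `target`, `response` (mapped
#'   radians); at least 20 rows
#' @param restarts number of random starting points (default 100)
#' @param seed optional integer seed for the starting points
#' @return list with `params` (a `mixture_params`), `logL`,
#'   `n_trials`, `restarts`
#' @export
fit_mixture_block <- function(trials, restarts = 100L, seed = NULL) {
  if (nrow(trials) < 20L) stop("fit_mixture_block: need at least 20 trials")
  if (!is.null(seed)) set.seed(seed)
  err <- circ_diff(trials$response, trials$target)
  tg <- wrap_angle(trials$target)
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- c(
      log(stats::runif(1, 0.5, 20)),
      stats::runif(1, -0.5, 0.5),
      stats::qlogis(stats::runif(1, 0.5, 1))
    )
    opt <- tryCatch(
      stats::optim(start, mixture_nll,
        theta_target = tg, error = err,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("fit_mixture_block: no finite likelihood at any start")
  list(
    params = mixture_params(
      kappa = exp(best$par[1]), eta = best$par[2],
      lambda = stats::plogis(best$par[3])
    ),
    logL = -best$value, n_trials = nrow(trials), restarts = restarts
  )
}

#' Per-block bias series for one subject
#'
#' Fits the contamination mixture separately to each block and returns
#' the per-block estimates together with two summaries: the pre/post
#' contrast \eqn{\hat\eta(\mathrm{block}\ 8) - \hat\eta(\mathrm{block}\
#' 1)} and the ordinary least-squares slope of \eqn{\hat\eta} on block
#' index over the adaptation blocks 2--7. (Group-level mixed-effects
#' inference is out of scope; these per-subject summaries are the
#' exported quantities.)
#'
#' @param trials trial table for one subject, with columns `block`,
#'   `target`, `response`
#' @param blocks block labels expected (default 1:8); missing blocks
#'   are dropped with a warning
#' @param adapt_blocks blocks entering the slope (default 2:7)
#' @param restarts,seed passed to [fit_mixture_block()] (block index is
#'   folded into the seed so blocks get distinct starts)
#' @return list with `table` (data.frame: block, eta_hat, kappa_hat,
#'   lambda_hat, loglik, n_trials), `contrast`, `slope`
#' @export
block_series <- function(trials, blocks = 1:8, adapt_blocks = 2:7,
                         restarts = 100L, seed = NULL) {
  if (!"block" %in% names(trials)) stop("block_series: trials need a block column")
  rows <- list()
  for (b in blocks) {
    sub <- trials[!is.na(trials$block) & trials$block == b, ]
    if (nrow(sub) == 0L) {
      warning(sprintf("block_series: block %d missing, omitted", b))
      next
    }
    fit <- fit_mixture_block(sub,
      restarts = restarts,
      seed = if (is.null(seed)) NULL else seed + b
    )
    rows[[length(rows) + 1L]] <- data.frame(
      block = b, eta_hat = fit$params$eta, kappa_hat = fit$params$kappa,
      lambda_hat = fit$params$lambda, loglik = fit$logL,
      n_trials = fit$n_trials
    )
  }
  tab <- do.call(rbind, rows)
  eta_of <- function(b) {
    if (b %in% tab$block) tab$eta_hat[tab$block == b] else NA_real_
  }
  contrast <- eta_of(max(blocks)) - eta_of(min(blocks))
  ad <- tab[tab$block %in% adapt_blocks, ]
  slope <- if (nrow(ad) >= 2L) {
    unname(stats::coef(stats::lm(eta_hat ~ block, data = ad))[2])
  } else {
    NA_real_
  }
  list(table = tab, contrast = contrast, slope = slope)
}
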