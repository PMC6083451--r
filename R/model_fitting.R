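#' Stimulus and response bin geometry
#'
#' The likelihood currency for fitting is a J x Q stimulus-by-response
#' probability matrix per set size: J evenly spaced target orientations
#' (bin centers on \eqn{[-\pi, \pi)}) by Q equally spaced response
#' histogram bins. Defaults J = Q = 25.
#'
#' @param J number of stimulus bins
#' @param Q number of response bins
#' @return list with `centers` (stimulus bin centers), `edges`
#'   (response bin edges), `rcenters` (response bin centers)
#' @export
bin_geometry <- function(J = 25L, Q = 25L) {
  list(
    J = as.integer(J), Q = as.integer(Q),
    centers = curve_eval_points(J),
    edges = seq(-pi, pi, length.out = Q + 1L),
    rcenters = curve_eval_points(Q)
  )
}

# map wrapped angles to response-bin indices 1..Q
response_bin_index <- function(x, Q) {
  idx <- findInterval(wrap_angle(x), seq(-pi, pi, length.out = Q + 1L),
    rightmost.closed = TRUE
  )
  pmin(pmax(idx, 1L), Q)
}

# map angles to nearest stimulus-bin center index 1..J (circular)
stimulus_bin_index <- function(x, J) {
  centers <- curve_eval_points(J)
  step <- 2 * pi / J
  idx <- round((wrap_angle(x) - centers[1]) / step) + 1L
  ((idx - 1L) %% J) + 1L
}

#' Build a stimulus-by-response probability matrix
#'
#' For a neural population configuration, simulates `reps` decoded
#' responses at each of the J stimulus bin centers and histograms them
#' into Q response bins; cells get a 0.5 pseudo-count before row
#' normalization so rare response bins never produce a -Inf
#' log-likelihood. For slots-plus-averaging parameters the default is
#' exact bin probabilities by quadrature of the analytic response
#' density over each response bin (`method = "analytic"`); a simulation
#' path is retained (`method = "simulate"`) for strict parity with the
#' Monte-Carlo procedure.
#'
#' @param model a `wm_popconfig` or an `spa_params`
#' @param N set size
#' @param J,Q stimulus / response bin counts (default 25 each)
#' @param reps Monte-Carlo responses per stimulus bin (default 1e4;
#'   simulation paths only)
#' @param seed optional integer seed (simulation paths only)
#' @param method for `spa_params`: `"analytic"` or `"simulate"`
#' @param n_quad quadrature points per response bin (analytic path)
#' @return an object of class `response_matrix`: list with `probs`
#'   (J x Q row-stochastic), `N`, `J`, `Q`, `centers`, `edges`
#' @export
build_response_matrix <- function(model, N, J = 25L, Q = 25L, reps = 1e4,
                                  seed = NULL, method = NULL, n_quad = 8L) {
  geom <- bin_geometry(J, Q)
  if (inherits(model, "wm_popconfig")) {
    stopifnot(reps >= 100)
    if (!is.null(seed)) set.seed(seed)
    tg <- rep(geom$centers, each = reps)
    resp <- simulate_responses(model, tg, N)
    probs <- response_histogram(tg, resp, geom, reps)
  } else if (inherits(model, "spa_params")) {
    if (is.null(method)) method <- "analytic"
    if (method == "analytic") {
      probs <- spa_bin_probs(model, N, geom, n_quad)
    } else {
      stopifnot(reps >= 100)
      if (!is.null(seed)) set.seed(seed)
      tg <- rep(geom$centers, each = reps)
      resp <- spa_sample(model, tg, N)$response
      probs <- response_histogram(tg, resp, geom, reps)
    }
  } else {
    stop("build_response_matrix: model must be wm_popconfig or spa_params")
  }
  structure(
    list(
      probs = probs, N = N, J = geom$J, Q = geom$Q,
      centers = geom$centers, edges = geom$edges
    ),
    class = "response_matrix"
  )
}

# histogram simulated (target, response) pairs into a row-stochastic
# J x Q matrix with a 0.5 pseudo-count smoothing floor
response_histogram <- function(targets, responses, geom, reps) {
  j <- stimulus_bin_index(targets, geom$J)
  q <- response_bin_index(responses, geom$Q)
  counts <- matrix(0, geom$J, geom$Q)
  tab <- table(factor(j, levels = seq_len(geom$J)), factor(q, levels = seq_len(geom$Q)))
  counts[] <- as.numeric(tab)
  counts <- counts + 0.5
  counts / rowSums(counts)
}

# quadrature cache shared across grid points: response-bin midpoint
# subdivisions and the (Q*n_quad) x Q aggregation matrix
spa_quad_cache <- function(geom, n_quad = 8L) {
  sub <- as.numeric(vapply(seq_len(geom$Q), function(q) {
    lo <- geom$edges[q]
    hi <- geom$edges[q + 1L]
    lo + (seq_len(n_quad) - 0.5) * (hi - lo) / n_quad
  }, numeric(n_quad)))
  w <- 2 * pi / (geom$Q * n_quad)
  list(sub = sub, agg = kronecker(diag(geom$Q), matrix(rep(w, n_quad), ncol = 1)))
}

# exact SPA bin probabilities: midpoint quadrature of the analytic
# density over each response bin, vectorized across all J x Q x n_quad
spa_bin_probs <- function(params, N, geom, n_quad = 8L, cache = NULL) {
  if (is.null(cache)) cache <- spa_quad_cache(geom, n_quad)
  g <- spa_allocate(params$K, N)$guess_rate
  mu <- geom$centers + params$eta * sin(2 * geom$centers)
  kap <- spa_kappa_n(params, geom$centers, N)
  # J x (Q*n_quad) von Mises density, stable in kappa
  d <- exp(kap * (cos(outer(-mu, cache$sub, "+")) - 1)) /
    (2 * pi * besselI(kap, 0, expon.scaled = TRUE))
  d <- (1 - g) * d + g / (2 * pi)
  probs <- d %*% cache$agg
  probs / rowSums(probs)
}

#' Binned log-likelihood of a trial table under response matrices
#'
#' Each trial's target is assigned to the nearest stimulus bin center
#' and its response to its histogram bin; the log-likelihood is the sum
#' of the log bin probabilities, across all set sizes present.
#'
#' @param matrices named list of `response_matrix` objects, names equal
#'   to set sizes (e.g. `list("1" = ..., "4" = ...)`)
#' @param trials data.frame with columns `set_size`, `target`,
#'   `response` (mapped radians)
#' @return total log-likelihood (0 for an empty table)
#' @export
bin_loglik <- function(matrices, trials) {
  if (nrow(trials) == 0L) return(0)
  total <- 0
  for (N in sort(unique(trials$set_size))) {
    m <- matrices[[as.character(N)]]
    if (is.null(m)) stop(sprintf("bin_loglik: no response matrix for set size %d", N))
    sub <- trials[trials$set_size == N, ]
    j <- stimulus_bin_index(sub$target, m$J)
    q <- response_bin_index(sub$response, m$Q)
    total <- total + sum(log(m$probs[cbind(j, q)]))
  }
  total
}

# J x Q count table per set size for fast repeated likelihood evaluation
trial_count_tables <- function(trials, J = 25L, Q = 25L) {
  out <- list()
  for (N in sort(unique(trials$set_size))) {
    sub <- trials[trials$set_size == N, ]
    j <- stimulus_bin_index(sub$target, J)
    q <- response_bin_index(sub$response, Q)
    counts <- matrix(0, J, Q)
    tab <- table(factor(j, levels = seq_len(J)), factor(q, levels = seq_len(Q)))
    counts[] <- as.numeric(tab)
    out[[as.character(N)]] <- counts
  }
  out
}

#' Parameter grids for maximum-likelihood fitting
#'
#' The reference grids: neural, 100 x 100 (`kappa` 0.1 to 10 in 0.1
#' steps by integer `gamma` 1 to 100); slots-plus-averaging, `K` 1 to
#' 10 by `kappa1` 0.1 to 10, `eta` -1 to 1 and `lambda` 0 to 1 in 0.1
#' steps. Coarser grids (for tests and quick fits) are permitted but
#' flagged `reduced = TRUE` in the result.
#'
#' @param family `"neural"` or `"spa"`
#' @param resolution `"full"` or `"coarse"`; the coarse neural grid is
#'   20 x 20 (`kappa` step 0.5, `gamma` step 5), the coarse SPA grid
#'   uses `kappa1` step 0.5, `eta` step 0.2, `lambda` step 0.2
#' @return named list of parameter value vectors
#' @export
grid_spec <- function(family = c("neural", "spa"),
                      resolution = c("full", "coarse")) {
  family <- match.arg(family)
  resolution <- match.arg(resolution)
  if (family == "neural") {
    if (resolution == "full") {
      list(kappa = seq(0.1, 10, by = 0.1), gamma = 1:100)
    } else {
      list(kappa = seq(0.5, 10, by = 0.5), gamma = seq(5, 100, by = 5))
    }
  } else {
    if (resolution == "full") {
      list(
        K = 1:10, kappa1 = seq(0.1, 10, by = 0.1),
        eta = seq(-1, 1, by = 0.1), lambda = seq(0, 1, by = 0.1)
      )
    } else {
      list(
        K = 1:10, kappa1 = seq(0.5, 10, by = 0.5),
        eta = seq(-1, 1, by = 0.2), lambda = seq(0, 1, by = 0.2)
      )
    }
  }
}

#' Grid-search maximum likelihood fit
#'
#' Evaluates the binned log-likelihood at every point of the parameter
#' grid and returns the argmax with its AIC (\eqn{-2\ln L + 2P}; P = 2
#' for the neural model, P = 4 for slots-plus-averaging). For the
#' neural family the stimulus-response matrices are rebuilt per grid
#' point by Monte Carlo; the same seed is reset before every grid point
#' (common random numbers), which smooths the stochastic likelihood
#' surface and makes the fit exactly reproducible. The SPA family uses
#' the analytic bin-probability path, so no simulation is involved.
#'
#' @param family `"neural"` or `"spa"`
#' @param trials trial table (columns `set_size`, `target`, `response`
#'   in mapped radians)
#' @param grid named list of parameter vectors from [grid_spec()] (or
#'   custom); defaults to the coarse grid
#' @param prior prior for the neural family (default natural cardinal)
#' @param M neural population size (default 100)
#' @param reps Monte-Carlo responses per stimulus bin per grid point
#'   (neural family; default 500, the paper-scale value is 1e4)
#' @param J,Q bin counts (default 25)
#' @param seed integer seed controlling the common random numbers
#' @param refine_top neural family only: when > 0, the `refine_top`
#'   best cells from the first pass are re-evaluated with
#'   `refine_reps` Monte-Carlo responses and the argmax is taken among
#'   those. A cheap two-stage approximation to running the whole grid
#'   at high fidelity
#' @param refine_reps Monte-Carlo reps for the refinement pass
#'   (default `10 * reps`)
#' @param verbose print progress every 50 grid points
#' @return an object of class `wm_fit`: list with `model`, `params`,
#'   `logL`, `AIC`, `logL_by_N`, `grid`, `reduced`, `reps`, `seed`
#' @export
fit_grid <- function(family = c("neural", "spa"), trials, grid = NULL,
                     prior = make_prior("natural_cardinal"), M = 100L,
                     reps = 500, J = 25L, Q = 25L, seed = 1L,
                     refine_top = 0L, refine_reps = 10 * reps,
                     verbose = FALSE) {
  family <- match.arg(family)
  if (nrow(trials) == 0L) stop("fit_grid: empty trial table")
  if (is.null(grid)) grid <- grid_spec(family, "coarse")
  if (family == "neural") {
    fit_neural_grid(trials, grid, prior, M, reps, J, Q, seed,
      refine_top, refine_reps, verbose
    )
  } else {
    fit_spa_grid(trials, grid, J, Q, seed, verbose)
  }
}

fit_neural_grid <- function(trials, grid, prior, M, reps, J, Q, seed,
                            refine_top, refine_reps, verbose) {
  stopifnot(all(c("kappa", "gamma") %in% names(grid)))
  Ns <- sort(unique(trials$set_size))
  counts <- trial_count_tables(trials, J, Q)
  combos <- expand.grid(kappa = grid$kappa, gamma = grid$gamma)
  eval_cell <- function(kappa, gamma, nrep) {
    cfg <- population_config(kappa, gamma, prior, M)
    set.seed(seed) # common random numbers across grid points
    ll_by_n <- vapply(Ns, function(N) {
      m <- build_response_matrix(cfg, N, J, Q, nrep)
      # delta-method debiasing of log(p-hat): the plug-in log of a
      # histogram estimate is biased by -(1-p)/(2 n p), which differs
      # across grid cells and tilts the stochastic likelihood surface
      sum(counts[[as.character(N)]] *
        (log(m$probs) + (1 - m$probs) / (2 * nrep * m$probs)))
    }, 0)
    list(logL = sum(ll_by_n), logL_by_N = stats::setNames(ll_by_n, Ns))
  }
  lls <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    lls[i] <- eval_cell(combos$kappa[i], combos$gamma[i], reps)$logL
    if (verbose && i %% 50 == 0) {
      message(sprintf("neural grid %d/%d (best logL %.2f)", i, nrow(combos), max(lls[1:i])))
    }
  }
  if (refine_top > 0L) {
    top <- order(lls, decreasing = TRUE)[seq_len(min(refine_top, nrow(combos)))]
    ref <- vapply(top, function(i) {
      eval_cell(combos$kappa[i], combos$gamma[i], refine_reps)$logL
    }, 0)
    ibest <- top[which.max(ref)]
    final <- eval_cell(combos$kappa[ibest], combos$gamma[ibest], refine_reps)
  } else {
    ibest <- which.max(lls)
    final <- eval_cell(combos$kappa[ibest], combos$gamma[ibest], reps)
  }
  full <- grid_spec("neural", "full")
  reduced <- !identical(lapply(grid, length), lapply(full, length))
  structure(
    list(
      model = "neural",
      params = list(kappa = combos$kappa[ibest], gamma = combos$gamma[ibest]),
      logL = final$logL, AIC = -2 * final$logL + 2 * 2,
      logL_by_N = final$logL_by_N,
      grid = grid, reduced = reduced, reps = reps,
      refine_top = refine_top, seed = seed,
      prior_kind = prior$kind, M = M, n_trials = nrow(trials)
    ),
    class = "wm_fit"
  )
}

fit_spa_grid <- function(trials, grid, J, Q, seed, verbose) {
  stopifnot(all(c("K", "kappa1", "eta", "lambda") %in% names(grid)))
  Ns <- sort(unique(trials$set_size))
  counts <- trial_count_tables(trials, J, Q)
  geom <- bin_geometry(J, Q)
  cache <- spa_quad_cache(geom)
  best <- list(logL = -Inf)
  combos <- expand.grid(
    K = grid$K, kappa1 = grid$kappa1, eta = grid$eta, lambda = grid$lambda
  )
  for (i in seq_len(nrow(combos))) {
    p <- spa_params(combos$K[i], combos$kappa1[i], combos$eta[i], combos$lambda[i])
    ll_by_n <- numeric(length(Ns))
    for (k in seq_along(Ns)) {
      probs <- spa_bin_probs(p, Ns[k], geom, cache = cache)
      ll_by_n[k] <- sum(counts[[as.character(Ns[k])]] * log(probs))
    }
    ll <- sum(ll_by_n)
    if (ll > best$logL) {
      best <- list(
        logL = ll,
        params = list(
          K = combos$K[i], kappa1 = combos$kappa1[i],
          eta = combos$eta[i], lambda = combos$lambda[i]
        ),
        logL_by_N = stats::setNames(ll_by_n, Ns)
      )
    }
    if (verbose && i %% 2000 == 0) {
      message(sprintf("spa grid %d/%d (best logL %.2f)", i, nrow(combos), best$logL))
    }
  }
  full <- grid_spec("spa", "full")
  reduced <- !identical(lapply(grid, length), lapply(full, length))
  structure(
    list(
      model = "spa", params = best$params, logL = best$logL,
      AIC = -2 * best$logL + 2 * 4, logL_by_N = best$logL_by_N,
      grid = grid, reduced = reduced, reps = NA_real_, seed = seed,
      n_trials = nrow(trials)
    ),
    class = "wm_fit"
  )
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf(
    "wm_fit [%s]: logL = %.3f, AIC = %.3f%s\n  params: %s\n",
    x$model, x$logL, x$AIC, if (x$reduced) " (reduced grid)" else "",
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  ))
  invisible(x)
}

#' Compare neural and slots-plus-averaging fits by AIC
#'
#' Convention: \eqn{\Delta AIC = AIC_{neural} - AIC_{spa}} per observer;
#' negative values favor the neural model.
#'
#' @param fits either a list of two `wm_fit` objects (one observer) or
#'   a list of such pairs (many observers); each pair must contain one
#'   neural and one spa fit
#' @param subjects optional observer labels
#' @return list with `table` (data.frame: subject, aic_neural, aic_spa,
#'   delta_aic), `summed_delta_aic`, `n_prefer_neural`, `n_prefer_spa`
#' @export
compare_fits <- function(fits, subjects = NULL) {
  if (length(fits) == 2L && all(vapply(fits, inherits, TRUE, "wm_fit"))) {
    fits <- list(fits)
  }
  rows <- lapply(seq_along(fits), function(i) {
    pair <- fits[[i]]
    models <- vapply(pair, `[[`, "", "model")
    if (!all(c("neural", "spa") %in% models)) {
      stop("compare_fits: each observer needs one neural and one spa fit")
    }
    data.frame(
      subject = if (is.null(subjects)) i else subjects[i],
      aic_neural = pair[[which(models == "neural")]]$AIC,
      aic_spa = pair[[which(models == "spa")]]$AIC
    )
  })
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic_neural - tab$aic_spa
  list(
    table = tab,
    summed_delta_aic = sum(tab$delta_aic),
    n_prefer_neural = sum(tab$delta_aic < 0),
    n_prefer_spa = sum(tab$delta_aic > 0)
  )
}

#' Resampled model-prediction bias and precision curves
#'
#' Simulates `reps` model responses at each of `n_points` evenly spaced
#' target values, then repeatedly subsamples each simulated response
#' distribution down to the average number of empirical responses per
#' binned target value (sample size affects precision estimates), and
#' averages the per-point circular mean (bias) and precision over
#' `resamples` repetitions.
#'
#' @param model a `wm_popconfig` or `spa_params` (typically at the
#'   maximum-likelihood parameters)
#' @param N set size
#' @param n_empirical number of empirical trials at this set size
#'   (determines the subsample size `max(2, round(n_empirical /
#'   n_points))`); pass `NULL` to skip subsampling
#' @param n_points number of target values (default 100)
#' @param reps simulated responses per target (default 1e4)
#' @param resamples number of subsampling repetitions (default 500)
#' @param seed optional integer seed
#' @return list with `eval_points`, `bias`, `precision`,
#'   `subsample_size`
#' @export
prediction_curves <- function(model, N, n_empirical = NULL, n_points = 100L,
                              reps = 1e4, resamples = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- curve_eval_points(n_points)
  tg <- rep(pts, each = reps)
  resp <- if (inherits(model, "wm_popconfig")) {
    simulate_responses(model, tg, N)
  } else {
    spa_sample(model, tg, N)$response
  }
  err <- matrix(circ_diff(resp, tg), nrow = reps) # reps x n_points
  m <- if (is.null(n_empirical)) reps else max(2L, round(n_empirical / n_points))
  m <- min(m, reps)
  bias_acc <- numeric(n_points)
  prec_acc <- numeric(n_points)
  for (r in seq_len(resamples)) {
    idx <- if (m == reps) seq_len(reps) else sample.int(reps, m)
    for (i in seq_len(n_points)) {
      s <- circ_summary(err[idx, i])
      bias_acc[i] <- bias_acc[i] + s$mean
      prec_acc[i] <- prec_acc[i] + s$precision
    }
  }
  list(
    eval_points = pts, bias = bias_acc / resamples,
    precision = prec_acc / resamples, subsample_size = m
  )
}
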