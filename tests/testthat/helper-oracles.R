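# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths wherever they
# are used to check one.

# direct trigonometric circular mean/SD (unweighted)
oracle_circ_stats <- function(x) {
  c_ <- mean(cos(x))
  s_ <- mean(sin(x))
  r <- sqrt(c_^2 + s_^2)
  list(mean = atan2(s_, c_), r = r, sd = sqrt(-2 * log(r)))
}

# brute-force Poisson log-likelihood: product of dpois over neurons
oracle_spike_loglik <- function(rates_matrix, spikes) {
  apply(rates_matrix, 1L, function(r) sum(stats::dpois(spikes, r, log = TRUE)))
}

# dense brute-force posterior-mean decode (trapezoid on n_dense points)
oracle_decode <- function(config, spikes, N, n_dense = 1e4) {
  g <- -pi + 2 * pi * (seq_len(n_dense) - 1) / n_dense
  ll <- spike_loglik(config, spikes, g, N)
  w <- exp(ll - max(ll)) * prior_density(config$prior, g)
  atan2(sum(w * sin(g)), sum(w * cos(g)))
}

# classic slots-plus-averaging response density (no stimulus-specific
# modulation), implemented from first principles: floor/mod allocation,
# slot-averaged concentration, uniform guessing
oracle_spa_classic <- function(K, kappa1, theta_target, N, theta_hat) {
  s_low <- floor(K / N)
  p_high <- (K %% N) / N
  g <- max(0, 1 - K / N)
  kn <- if (N > K) kappa1 else ((1 - p_high) * s_low + p_high * (s_low + 1)) * kappa1
  vm <- exp(kn * cos(theta_hat - theta_target)) /
    (2 * pi * besselI(kn, 0))
  (1 - g) * vm + g / (2 * pi)
}

# per-trial loop version of the binned likelihood
oracle_bin_loglik <- function(matrices, trials) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    m <- matrices[[as.character(trials$set_size[i])]]
    centers <- m$centers
    d <- abs(neuralwm::circ_diff(trials$target[i], centers))
    j <- which.min(d)
    edges <- m$edges
    q <- findInterval(neuralwm::wrap_angle(trials$response[i]), edges,
      rightmost.closed = TRUE
    )
    q <- min(max(q, 1L), m$Q)
    total <- total + log(m$probs[j, q])
  }
  total
}

# synthetic contamination-mixture block (target, response) table
make_mixture_block <- function(n, kappa, eta, lambda, seed) {
  set.seed(seed)
  tg <- stats::runif(n, -pi, pi)
  mem <- stats::runif(n) < lambda
  resp <- rvonmises(n, wrap_angle(tg + eta * sin(2 * tg)), kappa)
  resp[!mem] <- stats::runif(sum(!mem), -pi, pi)
  data.frame(target = tg, response = resp)
}

# smooth bimodal cardinal-peaked prior (analytic density, used where
# quadrature must converge spectrally)
smooth_cardinal_prior <- function(n_grid = 32768L) {
  make_prior("custom",
    density = function(th) {
      0.5 * dvonmises(th, 0, 1.5) + 0.5 * dvonmises(th, pi, 1.5)
    },
    n_grid = n_grid
  )
}

# quadrature of a density over [-pi, pi) by midpoint rule
quad_circle <- function(f, n = 4096L) {
  x <- -pi + (seq_len(n) - 0.5) * 2 * pi / n
  sum(f(x)) * 2 * pi / n
}
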