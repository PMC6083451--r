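test_that("response matrices are row-stochastic with a positive floor", {
  cfg <- population_config(2, 50, make_prior("uniform"))
  m <- build_response_matrix(cfg, 2, reps = 200, seed = 31)
  expect_equal(rowSums(m$probs), rep(1, 25), tolerance = 1e-12)
  expect_true(all(m$probs > 0))
  ms <- build_response_matrix(spa_params(3, 5, 0.2, 0.4), 4)
  expect_equal(rowSums(ms$probs), rep(1, 25), tolerance = 1e-12)
  expect_true(all(ms$probs > 0))
})

test_that("uniform-prior neural matrix is approximately circulant", {
  cfg <- population_config(2, 50, make_prior("uniform"))
  m <- build_response_matrix(cfg, 1, reps = 2000, seed = 32)
  shifted <- vapply(seq_len(25), function(i) {
    # row i should be row 1 rotated by i-1 response bins
    max(abs(m$probs[i, ] - m$probs[1, ((seq_len(25) - (i - 1) - 1) %% 25) + 1]))
  }, 0)
  expect_lt(max(shifted), 0.06) # Monte-Carlo tolerance at 2000 reps/row
})

test_that("heavy-guessing SPA rows approach uniform", {
  m <- build_response_matrix(spa_params(1, 8), 20) # g = 0.95
  expect_lt(max(abs(m$probs - 1 / 25)), 0.05)
})

test_that("analytic and simulated SPA matrices agree", {
  p <- spa_params(3, 5, 0.2, 0.4)
  ma <- build_response_matrix(p, 4, method = "analytic")
  ms <- build_response_matrix(p, 4, method = "simulate", reps = 5000, seed = 33)
  expect_lt(max(abs(ma$probs - ms$probs)), 0.03)
})

test_that("binned log-likelihood: closed forms, additivity, oracle", {
  geom_probs <- matrix(1 / 25, 25, 25)
  mk <- function(N) {
    structure(
      list(
        probs = geom_probs, N = N, J = 25L, Q = 25L,
        centers = curve_eval_points(25), edges = seq(-pi, pi, length.out = 26)
      ),
      class = "response_matrix"
    )
  }
  mats <- list("1" = mk(1), "4" = mk(4))
  set.seed(34)
  n <- 200
  trials <- data.frame(
    set_size = sample(c(1, 4), n, replace = TRUE),
    target = runif(n, -pi, pi), response = runif(n, -pi, pi)
  )
  expect_equal(bin_loglik(mats, trials), n * log(1 / 25), tolerance = 1e-12)
  expect_equal(bin_loglik(mats, trials[0, ]), 0)
  expect_equal(bin_loglik(mats, rbind(trials, trials)),
    2 * bin_loglik(mats, trials),
    tolerance = 1e-12
  )
  expect_error(
    bin_loglik(mats, data.frame(set_size = 2, target = 0, response = 0)),
    "set size 2"
  )
  # non-uniform matrices against the per-trial loop oracle
  cfg <- population_config(2, 40, make_prior("natural_cardinal"))
  mats2 <- list(
    "1" = build_response_matrix(cfg, 1, reps = 200, seed = 35),
    "4" = build_response_matrix(cfg, 4, reps = 200, seed = 36)
  )
  expect_equal(bin_loglik(mats2, trials), oracle_bin_loglik(mats2, trials),
    tolerance = 1e-12
  )
})

test_that("grid fitting is deterministic under a fixed seed", {
  cfg <- population_config(2, 50, make_prior("natural_cardinal"))
  trials <- gen_observer(cfg, c(1, 4), 100, seed = 37)
  grid <- list(kappa = c(1.5, 2.5), gamma = c(40, 60))
  f1 <- fit_grid("neural", trials, grid = grid, reps = 200, seed = 38)
  f2 <- fit_grid("neural", trials, grid = grid, reps = 200, seed = 38)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-12)
  expect_true(f1$reduced)
  expect_equal(f1$AIC, -2 * f1$logL + 4, tolerance = 1e-12)
})

test_that("likelihood at the truth dominates distant parameters", {
  # 20 synthetic observers, analytic SPA likelihood: the truth should
  # beat a point several grid steps away in >= 95% of observers
  truth <- spa_params(3, 5, 0.2, 0.4)
  far <- spa_params(3, 6.5, 0.6, 0.8)
  geom <- bin_geometry()
  wins <- 0L
  for (s in 1:20) {
    tt <- gen_observer(truth, c(2, 4), 250,
      seed = 600 + s,
      target_values = curve_eval_points(25)
    )
    counts <- neuralwm:::trial_count_tables(tt)
    ll <- function(p) {
      sum(vapply(c(2, 4), function(N) {
        sum(counts[[as.character(N)]] * log(neuralwm:::spa_bin_probs(p, N, geom)))
      }, 0))
    }
    if (ll(truth) > ll(far)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("AIC comparison table follows the sign convention", {
  fa <- structure(list(model = "neural", AIC = 100), class = "wm_fit")
  fb <- structure(list(model = "spa", AIC = 104), class = "wm_fit")
  cmp <- compare_fits(list(fa, fb))
  expect_equal(cmp$table$delta_aic, -4)
  expect_equal(cmp$summed_delta_aic, -4)
  expect_equal(cmp$n_prefer_neural, 1)
  # identical logL, P = 2 vs P = 4: delta AIC = -4 by the penalty alone
  ll <- -321.7
  expect_equal((-2 * ll + 2 * 2) - (-2 * ll + 2 * 4), -4)
  # multiple observers: permutation leaves the summary unchanged
  pairs <- list(list(fa, fb), list(fb, fa), list(fa, fb))
  c1 <- compare_fits(pairs)
  c2 <- compare_fits(rev(pairs))
  expect_equal(c1$summed_delta_aic, c2$summed_delta_aic)
  expect_equal(c1$n_prefer_neural, c2$n_prefer_neural)
})

test_that("prediction curves: subsampling and symmetry behave", {
  cfg <- population_config(2, 60, make_prior("uniform"))
  # subsample size = full simulation size: resampling is a no-op
  pc1 <- prediction_curves(cfg, 1,
    n_empirical = NULL, n_points = 12,
    reps = 300, resamples = 1, seed = 39
  )
  pc2 <- prediction_curves(cfg, 1,
    n_empirical = NULL, n_points = 12,
    reps = 300, resamples = 3, seed = 39
  )
  expect_equal(pc1$bias, pc2$bias, tolerance = 1e-12)
  expect_equal(pc1$subsample_size, 300)
  # uniform prior: flat bias within Monte-Carlo error
  pc3 <- prediction_curves(cfg, 1,
    n_empirical = 1200, n_points = 12,
    reps = 2000, resamples = 20, seed = 40
  )
  expect_lt(max(abs(pc3$bias)), 0.05)
  expect_equal(pc3$subsample_size, 100)
})
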