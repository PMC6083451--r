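test_that("degree/radian mapping round-trips and wraps", {
  deg <- c(-90, -45.5, 0, 30, 89.999)
  expect_equal(rad_to_deg(deg_to_rad(deg)), deg, tolerance = 1e-12)
  set.seed(1)
  x <- runif(200, -50, 50)
  expect_true(all(wrap_angle(x) >= -pi & wrap_angle(x) < pi))
  expect_equal(wrap_angle(x), wrap_angle(x + 2 * pi), tolerance = 1e-9)
})

test_that("circ_diff wraps and is antisymmetric", {
  expect_equal(circ_diff(0.3, 0.3), 0)
  expect_equal(circ_diff(-3.0, 3.0), -6 + 2 * pi, tolerance = 1e-12)
  expect_equal(circ_diff(pi / 2, 0), pi / 2)
  set.seed(2)
  a <- runif(100, -pi, pi)
  b <- runif(100, -pi, pi)
  expect_equal(wrap_angle(circ_diff(a, b) + circ_diff(b, a)), rep(0, 100),
    tolerance = 1e-12
  )
})

test_that("circ_summary matches the trigonometric oracle and handles edge cases", {
  set.seed(3)
  for (rep in 1:20) {
    x <- runif(50, -pi, pi)
    s <- circ_summary(x)
    o <- oracle_circ_stats(x)
    expect_equal(s$mean, o$mean, tolerance = 1e-12)
    expect_equal(s$resultant_length, o$r, tolerance = 1e-12)
    expect_equal(s$circ_sd, o$sd, tolerance = 1e-12)
    expect_equal(s$precision, 1 / o$sd^2, tolerance = 1e-12)
  }
  # symmetric pair: zero mean
  expect_equal(circ_summary(c(0.4, -0.4))$mean, 0, tolerance = 1e-12)
  # degenerate concentration: capped precision, flagged
  s <- circ_summary(rep(0.2, 3))
  expect_equal(s$circ_sd, 0)
  expect_equal(s$precision, 1e12)
  expect_true(s$degenerate)
  # uniform null: tiny resultant
  expect_lt(circ_summary(runif(1e5, -pi, pi))$resultant_length, 0.02)
  # errors
  expect_error(circ_summary(numeric(0)), "empty")
  expect_error(circ_summary(c(1, 2), weights = c(0, 0)), "zero")
  expect_error(circ_summary(c(1, 2), weights = c(-1, 2)), "negative")
})

test_that("rotating all angles shifts the mean and preserves dispersion", {
  set.seed(4)
  x <- rvonmises(500, 0.5, 3)
  delta <- 1.1
  s0 <- circ_summary(x)
  s1 <- circ_summary(wrap_angle(x + delta))
  expect_equal(wrap_angle(s1$mean - s0$mean), delta, tolerance = 1e-10)
  expect_equal(s1$circ_sd, s0$circ_sd, tolerance = 1e-10)
})

test_that("von Mises kernel concentration matches the requested circular SD", {
  for (h in c(0.23, 0.61, 1.2)) {
    k <- vm_kappa_from_sd(h)
    r <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    expect_equal(sqrt(-2 * log(r)), h, tolerance = 1e-8)
  }
})

test_that("rvonmises matches dvonmises moments and is seed-stable", {
  set.seed(5)
  x <- rvonmises(2e4, 0.7, 4)
  s <- circ_summary(x)
  expect_equal(s$mean, 0.7, tolerance = 0.02)
  # resultant length should match A(kappa) = I1/I0
  r_theory <- besselI(4, 1, expon.scaled = TRUE) / besselI(4, 0, expon.scaled = TRUE)
  expect_equal(s$resultant_length, r_theory, tolerance = 0.01)
  set.seed(9)
  a <- rvonmises(10, 0, 2)
  set.seed(9)
  expect_identical(a, rvonmises(10, 0, 2))
})

test_that("smoothed curves recover a generative bias profile", {
  set.seed(6)
  n <- 5e4
  tg <- runif(n, -pi, pi)
  err <- rvonmises(n, 0.1 * sin(2 * tg), 8)
  # narrow kernel: amplitude attenuation of the 2nd harmonic is < 8%,
  # so pointwise recovery within 0.02 is attainable at this n
  cur <- smooth_curves(tg, err, h_bias = 0.2)
  truth <- 0.1 * sin(2 * cur$bias$eval_points)
  expect_lt(max(abs(cur$bias$values - truth)), 0.02)
  expect_length(cur$bias$values, 50)
  expect_length(cur$precision$values, 50)
  # default (broad) bandwidth keeps the shape: sign of sin(2 theta)
  cur2 <- smooth_curves(tg, err)
  pts <- cur2$bias$eval_points
  away <- abs(sin(2 * pts)) > 0.3
  expect_true(all(sign(cur2$bias$values[away]) == sign(sin(2 * pts[away]))))
})

test_that("smoothed curves: degenerate and limiting cases", {
  set.seed(7)
  tg <- runif(500, -pi, pi)
  # all-zero errors: bias identically 0
  cur <- smooth_curves(tg, rep(0, 500))
  expect_equal(cur$bias$values, rep(0, 50))
  # huge bandwidth: bias curve collapses to the global circular mean
  err <- rvonmises(500, 0.3, 2)
  cur2 <- smooth_curves(tg, err, h_bias = 50)
  global <- circ_summary(err)$mean
  expect_lt(max(abs(cur2$bias$values - global)), 1e-6)
  # permutation invariance
  idx <- sample(500)
  cur3 <- smooth_curves(tg[idx], err[idx])
  cur4 <- smooth_curves(tg, err)
  expect_equal(cur3$bias$values, cur4$bias$values, tolerance = 1e-12)
  # guards
  expect_error(smooth_curves(1, 0.2), "at least 2")
  expect_error(smooth_curves(c(1, 2), 0.2), "equal length")
})
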