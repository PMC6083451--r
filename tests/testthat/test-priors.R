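test_that("built-in prior densities match closed forms", {
  pu <- make_prior("uniform")
  expect_equal(prior_density(pu, c(-2, 0, 1.5)), rep(1 / (2 * pi), 3))
  pn <- make_prior("natural_cardinal")
  expect_equal(prior_density(pn, 0), 2 / (4 * pi - 4), tolerance = 1e-12)
  # cardinal-peaked: denser at 0 than at the oblique pi/2
  expect_gt(prior_density(pn, 0), prior_density(pn, pi / 2))
  po <- make_prior("adapt_oblique")
  expect_lt(prior_density(po, 0), prior_density(po, pi / 2))
  # congruent adaptation distribution equals the natural prior
  pc <- make_prior("adapt_cardinal")
  th <- seq(-pi, pi - 1e-9, length.out = 101)
  expect_equal(prior_density(pc, th), prior_density(pn, th), tolerance = 1e-12)
})

test_that("all prior kinds are normalized and nonnegative", {
  kinds <- c("uniform", "natural_cardinal", "adapt_cardinal", "adapt_oblique")
  for (k in kinds) {
    p <- make_prior(k)
    # fine quadrature: the kinked |sin|/|cos| densities need it to
    # reach the 1e-8 normalization tolerance
    expect_equal(quad_circle(function(x) prior_density(p, x), n = 65536L), 1,
      tolerance = 1e-8
    )
    expect_true(all(prior_density(p, seq(-pi, pi, length.out = 997)) >= 0))
  }
  pcust <- make_prior("custom", density = function(th) 1 + 0.5 * cos(4 * th))
  expect_equal(quad_circle(function(x) prior_density(pcust, x)), 1, tolerance = 1e-8)
})

test_that("prior CDFs match quadrature and closed form", {
  pn <- make_prior("natural_cardinal")
  expect_equal(prior_cdf(pn, 0), 0.5, tolerance = 1e-12)
  expect_equal(prior_cdf(pn, pi / 2), (3 * pi - 3) / (4 * pi - 4), tolerance = 1e-12)
  expect_equal(prior_cdf(pn, -pi), 0)
  expect_equal(prior_cdf(pn, pi), 1)
  expect_equal(prior_cdf(make_prior("uniform"), 0), 0.5)
  # quadrature oracle at several interior points, every kind
  for (k in c("natural_cardinal", "adapt_oblique")) {
    p <- make_prior(k)
    for (th in c(-2.1, -0.4, 0.9, 2.8)) {
      num <- stats::integrate(function(x) prior_density(p, x), -pi, th,
        rel.tol = 1e-10, subdivisions = 400L
      )$value
      expect_equal(prior_cdf(p, th), num, tolerance = 1e-8)
    }
    expect_true(all(diff(prior_cdf(p, seq(-pi, pi, length.out = 513))) >= 0))
  }
})

test_that("warp map is the CDF remap with the right derivative", {
  pu <- make_prior("uniform")
  th <- seq(-pi, pi - 1e-6, length.out = 101)
  expect_identical(warp_map(pu, th), th) # exact identity warp
  pn <- make_prior("natural_cardinal")
  expect_equal(warp_map(pn, 0), 0, tolerance = 1e-12)
  expect_equal(warp_map(pn, -pi), -pi)
  # chain rule: F'(theta) = 2 pi p(theta), by central differences
  for (t0 in c(-1.8, -0.3, 0.6, 2.2)) {
    fd <- (warp_map(pn, t0 + 1e-6) - warp_map(pn, t0 - 1e-6)) / 2e-6
    expect_equal(fd, 2 * pi * prior_density(pn, t0), tolerance = 1e-5)
  }
})

test_that("inverse-CDF sampling is consistent and reproducible", {
  pn <- make_prior("natural_cardinal")
  x <- prior_sample(pn, 1e5, seed = 42)
  # KS-style max deviation between empirical and true CDF
  xs <- sort(x)
  emp <- seq_along(xs) / length(xs)
  expect_lt(max(abs(emp - prior_cdf(pn, xs))), 0.01)
  # density ratio at the peak (cardinal) vs trough (oblique) is 2
  at0 <- mean(abs(circ_diff(x, 0)) < 0.15) / 0.3
  at90 <- mean(abs(circ_diff(x, pi / 2)) < 0.15) / 0.3
  expect_equal(at0 / at90, 2, tolerance = 0.15)
  # determinism
  expect_identical(prior_sample(pn, 5, seed = 7), prior_sample(pn, 5, seed = 7))
})

test_that("samples pushed through the warp map are uniform", {
  for (k in c("natural_cardinal", "adapt_oblique")) {
    p <- make_prior(k)
    x <- prior_sample(p, 1e5, seed = 13)
    u <- warp_map(p, x)
    us <- sort(u)
    emp <- seq_along(us) / length(us)
    expect_lt(max(abs(emp - (us + pi) / (2 * pi))), 0.01)
  }
})

test_that("custom priors accept tabulated densities", {
  th <- seq(-pi, pi, length.out = 513)
  tab <- data.frame(theta_rad = th, density = 2 - abs(sin(th)))
  p <- make_prior("custom", density = tab)
  pn <- make_prior("natural_cardinal")
  probe <- seq(-3, 3, length.out = 41)
  expect_equal(prior_density(p, probe), prior_density(pn, probe), tolerance = 1e-4)
  expect_error(make_prior("custom"), "needs a density")
  expect_error(
    make_prior("custom", density = function(th) sin(th)), # negative lobes
    "nonnegative"
  )
})
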