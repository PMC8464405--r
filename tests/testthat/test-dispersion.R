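test_that("in-plane density has the stated values, symmetry and normalization", {
  # a = 0: uniform density
  expect_equal(rho_ip(runif(5, 0, 2 * pi), 0, 0.4), rep(1, 5))
  # peak value e^1 / I0(1), checked against a series evaluation of I0
  i0_series <- sum(sapply(0:30, function(k) (1 / 4)^k / factorial(k)^2))
  expect_equal(rho_ip(0.3, 1, 0.3), exp(1) / i0_series, tolerance = 1e-10)
  expect_equal(rho_ip(0.3, 1, 0.3), 2.1470, tolerance = 1e-4)
  # pi-periodicity for random parameters
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 0, 20); al <- runif(1, 0, pi / 2); phi <- runif(1, 0, 2 * pi)
    expect_equal(rho_ip(phi, a, al), rho_ip(phi + pi, a, al))
  }
  # circle-average normalization by quadrature
  for (a in c(0.1, 1, 10, 100)) {
    q <- integrate(function(p) rho_ip(p, a, 0.7), 0, 2 * pi,
                   rel.tol = 1e-12)$value / (2 * pi)
    expect_equal(q, 1, tolerance = 1e-8)
  }
  # mixture is the symmetric average of the +/- alpha families
  phi <- seq(0, pi, length.out = 7)
  expect_equal(rho_ip_mixture(phi, 3, 0.6),
               (rho_ip(phi, 3, 0.6) + rho_ip(phi, 3, -0.6)) / 2)
  expect_error(rho_ip(0, -1), "must be >= 0")
})

test_that("out-of-plane density is even, normalized over the sphere measure, and has the stated peak", {
  set.seed(12)
  for (i in 1:10) {
    b <- runif(1, 0, 30); th <- runif(1, 0, pi / 2)
    expect_equal(rho_op(th, b), rho_op(-th, b))
  }
  for (b in c(0.5, 2, 10)) {
    q <- integrate(function(t) rho_op(t, b) * cos(t), -pi / 2, pi / 2,
                   rel.tol = 1e-12)$value / 2
    expect_equal(q, 1, tolerance = 1e-8)
  }
  # direct special-function evaluation at b = 5
  expect_equal(rho_op(0, 5), 2 * sqrt(10 / pi) / (2 * pnorm(sqrt(20)) - 1),
               tolerance = 1e-12)
  expect_equal(rho_op(0, 5), 3.5683, tolerance = 1e-4)
  # limiting constant density at b = 0
  expect_equal(rho_op(c(-1, 0, 1), 0), rep(1, 3))
  expect_error(rho_op(2, 5), "must lie in")
  expect_error(rho_op(0, -0.1), "must be >= 0")
})

test_that("kappa_ip matches its Bessel-integral definition and limits", {
  expect_equal(kappa_ip(0), 0.5)
  # quadrature oracle from the integral definitions of I0 and I1
  kip_oracle <- function(a) {
    I0 <- integrate(function(x) exp(a * cos(x)), 0, pi)$value / pi
    I1 <- integrate(function(x) exp(a * cos(x)) * cos(x), 0, pi)$value / pi
    0.5 - I1 / (2 * I0)
  }
  for (a in c(0.3, 1, 4, 20)) {
    expect_equal(kappa_ip(a), kip_oracle(a), tolerance = 1e-8)
  }
  expect_equal(kappa_ip(1), 0.2768, tolerance = 1e-4)
  # perfect alignment limit
  expect_lt(kappa_ip(1e6), 1e-3)
  # monotone decreasing, bounded in [0, 1]
  grid <- kappa_ip(c(0, 10^seq(-2, 4, by = 0.25)))
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_error(kappa_ip(-2), "must be >= 0")
})

test_that("kappa_op matches its moment-integral definition and limits", {
  # oracle: kappa_op = 1/2 - (1/4) integral of rho_op sin^2 cos
  kop_oracle <- function(b) {
    0.5 - integrate(function(t) rho_op(t, b) * sin(t)^2 * cos(t),
                    -pi / 2, pi / 2, rel.tol = 1e-12)$value / 4
  }
  for (b in c(0.05, 0.5, 2, 5, 50)) {
    expect_equal(kappa_op(b), kop_oracle(b), tolerance = 1e-8)
  }
  expect_equal(kappa_op(5), 0.4750, tolerance = 1e-4)
  # analytic limits: 1/3 as b -> 0, 1/2 as b -> infinity
  expect_equal(kappa_op(0), 1 / 3)
  expect_equal(kappa_op(1e-9), 1 / 3, tolerance = 1e-7)
  expect_equal(kappa_op(1e6), 0.5, tolerance = 1e-6)
  # monotone increasing, bounded in [0, 1/2]
  grid <- kappa_op(c(0, 10^seq(-2, 4, by = 0.25)))
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid >= 0 & grid <= 0.5))
  expect_error(kappa_op(-1), "must be >= 0")
})

test_that("in-plane fitting recovers parameters from exact wedge samples", {
  centers <- seq(0, 175, by = 5)
  amp <- rho_ip_mixture(centers * pi / 180, 3, 40 * pi / 180)
  fit <- fit_inplane(angular_distribution(centers, amp))
  expect_false(fit$isotropic)
  expect_equal(fit$a, 3, tolerance = 0.05 / 3)
  expect_equal(fit$alpha_deg, 40, tolerance = 0.5 / 40)
  # two mirrored delta-like peaks at +/- 50 degrees
  amp2 <- rho_ip_mixture(centers * pi / 180, 30, 50 * pi / 180)
  fit2 <- fit_inplane(angular_distribution(centers, amp2))
  expect_equal(fit2$alpha_deg, 50, tolerance = 1e-2)
  # uniform amplitudes: isotropic, a = 0, no peak reported
  fitu <- fit_inplane(angular_distribution(centers, rep(1, 36)))
  expect_true(fitu$isotropic)
  expect_lt(fitu$a, 1e-3)
  expect_true(is.na(fitu$alpha_deg))
  expect_error(angular_distribution(centers, rep(0, 36)), "degenerate")
})

test_that("out-of-plane fitting recovers the concentration parameter", {
  centers <- seq(0, 175, by = 5)
  theta <- ifelse(centers > 90, centers - 180, centers)
  amp <- rho_op(theta * pi / 180, 8)
  fit <- fit_outofplane(angular_distribution(centers, amp))
  expect_equal(fit$b, 8, tolerance = 0.1 / 8)
  fitu <- fit_outofplane(angular_distribution(centers, rep(1, 36)))
  expect_true(fitu$isotropic)
  expect_equal(fitu$b, 0)
  # 1% noise, 10 replicates: mean recovered b within 5% of 2
  set.seed(21)
  bs <- replicate(10, {
    noisy <- rho_op(theta * pi / 180, 2) * (1 + rnorm(36, 0, 0.01))
    fit_outofplane(angular_distribution(centers, pmax(noisy, 0)),
                   r2_threshold = 1)$b
  })
  expect_equal(mean(bs), 2, tolerance = 0.05)
})

test_that("isotropy classification responds to profile shape and threshold", {
  centers <- seq(0, 175, by = 5)
  expect_true(classify_isotropy(angular_distribution(centers, rep(1, 36))))
  peaked <- rho_ip_mixture(centers * pi / 180, 5, 30 * pi / 180)
  expect_false(classify_isotropy(angular_distribution(centers, peaked)))
  # degenerate threshold admits everything
  expect_true(classify_isotropy(angular_distribution(centers, peaked),
                                r2_threshold = 0))
})

test_that("stack aggregation averages peaks and concentration parameters", {
  f <- function(peak, a) structure(
    list(a = a, alpha_deg = peak, isotropic = is.na(peak)),
    class = "vonmises_fit")
  fop <- function(b) structure(list(b = b, isotropic = FALSE),
                               class = "vonmises_fit")
  one <- aggregate_stack(list(f(40, 3)), list(fop(6)))
  expect_equal(one$alpha_deg, 40)
  expect_equal(one$kappa_ip, kappa_ip(3))
  expect_equal(one$kappa_op, kappa_op(6))
  two <- aggregate_stack(list(f(30, 2), f(50, 4)))
  expect_equal(two$alpha_deg, 40)
  expect_equal(two$alpha_sd_deg, sd(c(30, 50)))
  expect_equal(two$kappa_ip, kappa_ip(3))
  expect_true(is.na(two$kappa_op))
  # isotropic images enter the concentration mean as zeros
  mix <- aggregate_stack(list(f(NA, 0), f(45, 4)))
  expect_equal(mix$a_mean, 2)
  expect_equal(mix$n_isotropic, 1L)
  # ... unless excluded by configuration
  mix2 <- aggregate_stack(list(f(NA, 0), f(45, 4)), include_isotropic = FALSE)
  expect_equal(mix2$a_mean, 4)
  # all-isotropic: alpha flagged undefined
  allis <- aggregate_stack(list(f(NA, 0), f(NA, 0)))
  expect_true(is.na(allis$alpha_deg))
  expect_error(aggregate_stack(list()), "at least one")
})
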