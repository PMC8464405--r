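test_that("objective is the brute-force residual sum and is order invariant", {
  dat <- two_fiber_testdata()
  truth <- list(c2 = 15, k1 = 12, k2 = 3.5)
  expect_equal(objective(truth, dat), 0)
  # single point with residuals (1, 2) kPa
  sc <- sc_specimen1()
  th <- cauchy_two_fiber(1.1, 1.1, truth, sc)
  one <- biaxial_dataset(
    data.frame(protocol = "p", lambda_theta = 1.1, lambda_z = 1.1,
               sigma_theta = th$sigma_theta + 1, sigma_z = th$sigma_z + 2),
    sc)
  expect_equal(objective(truth, one), 5)
  # per-point loop oracle on perturbed parameters
  pars <- list(c2 = 12, k1 = 10, k2 = 4)
  loop <- 0
  for (i in seq_len(nrow(dat))) {
    s <- cauchy_two_fiber(dat$lambda_theta[i], dat$lambda_z[i], pars, sc)
    loop <- loop + (dat$sigma_theta[i] - s$sigma_theta)^2 +
      (dat$sigma_z[i] - s$sigma_z)^2
  }
  expect_equal(objective(pars, dat), loop, tolerance = 1e-12)
  # record order does not matter
  shuf <- dat[sample(nrow(dat)), ]
  attr(shuf, "structure") <- attr(dat, "structure")
  class(shuf) <- class(dat)
  expect_equal(objective(pars, shuf), objective(pars, dat))
})

test_that("coefficients of determination match the definition-based oracle", {
  dat <- two_fiber_testdata()
  truth <- list(c2 = 15, k1 = 12, k2 = 3.5)
  expect_equal(unname(r_squared(dat, truth)), c(1, 1))
  # independent evaluation of 1 - SS_res/SS_tot at off-truth parameters
  pars <- list(c2 = 5, k1 = 20, k2 = 1)
  sc <- attr(dat, "structure")
  th <- cauchy_two_fiber(dat$lambda_theta, dat$lambda_z, pars, sc)
  oracle <- c(
    1 - sum((dat$sigma_theta - th$sigma_theta)^2) /
      sum((dat$sigma_theta - mean(dat$sigma_theta))^2),
    1 - sum((dat$sigma_z - th$sigma_z)^2) /
      sum((dat$sigma_z - mean(dat$sigma_z))^2))
  expect_equal(unname(r_squared(dat, pars)), oracle, tolerance = 1e-12)
  # constant experimental stresses: flagged undefined
  const <- biaxial_dataset(
    data.frame(protocol = rep(c("a", "b"), 2),
               lambda_theta = c(1.05, 1.1, 1.15, 1.2),
               lambda_z = c(1.05, 1.1, 1.15, 1.2),
               sigma_theta = 3, sigma_z = 3), sc)
  w <- capture_warnings(rc <- r_squared(const, truth))
  expect_match(w, "constant", all = TRUE)
  expect_length(w, 2)  # one flag per direction
  expect_true(all(is.na(rc)))
})

test_that("noise-free parameter recovery is exact to within 1 percent", {
  dat <- two_fiber_testdata(n_steps = 10)
  fit <- fiber_fit(dat, "two_fiber", n_starts = 6, seed = 42)
  expect_equal(unname(coef(fit)), c(15, 12, 3.5), tolerance = 0.01)
  expect_true(fit$converged)
  expect_gt(fit$r2[["r2_theta"]], 0.9999)
  # deterministic given the seed
  fit2 <- fiber_fit(dat, "two_fiber", n_starts = 6, seed = 42)
  expect_identical(coef(fit), coef(fit2))
})

test_that("median parameter recovery under 2 percent noise stays within 10 percent", {
  recovered <- sapply(1:20, function(r) {
    dat <- two_fiber_testdata(n_steps = 10, relative_sd = 0.02,
                              absolute_sd = 0, seed = 500 + r)
    coef(fiber_fit(dat, "two_fiber", n_starts = 1,
                   init = c(c2 = 10, k1 = 10, k2 = 1), seed = r))
  })
  med <- apply(recovered, 1, median)
  expect_equal(unname(med), c(15, 12, 3.5), tolerance = 0.10)
})

test_that("the four-fiber model fits two-fiber data at least as well", {
  dat <- two_fiber_testdata(n_steps = 8, relative_sd = 0.02,
                            absolute_sd = 0.2, seed = 77)
  f2 <- fiber_fit(dat, "two_fiber", n_starts = 4, seed = 1)
  mapped <- c(c4 = unname(coef(f2)["c2"]), k1col = 2 * unname(coef(f2)["k1"]),
              k2col = unname(coef(f2)["k2"]), k1el = 0, k2el = 1,
              k1smc = 0, k2smc = 1)
  f4 <- fiber_fit(dat, "four_fiber", n_starts = 4, init = mapped, seed = 1)
  expect_lte(f4$sse, f2$sse + 1e-8)
  expect_gte(f4$r2[["r2_theta"]], f2$r2[["r2_theta"]] - 1e-10)
  expect_gte(f4$r2[["r2_z"]], f2$r2[["r2_z"]] - 1e-10)
})

test_that("fiber_fit methods expose coefficients, predictions and residuals", {
  dat <- two_fiber_testdata(n_steps = 6, relative_sd = 0.01,
                            absolute_sd = 0.1, seed = 9)
  fit <- fiber_fit(dat, "two_fiber", n_starts = 2,
                   init = c(c2 = 15, k1 = 12, k2 = 3.5), seed = 3)
  expect_named(coef(fit), c("c2", "k1", "k2"))
  pr <- predict(fit, data.frame(lambda_theta = c(1, 1.1),
                                lambda_z = c(1, 1.1)))
  expect_equal(pr$sigma_theta[1], 0)
  res <- residuals(fit)
  expect_equal(nrow(res), nrow(dat))
  expect_equal(res$sigma_theta, dat$sigma_theta - fitted(fit)$sigma_theta)
  expect_output(print(fit), "two-fiber")
  expect_output(print(summary(fit)), "R2")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "biaxial_dataset")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("bootstrap is reproducible and degenerates to the point fit on noise-free data", {
  dat <- two_fiber_testdata(n_steps = 6)
  fit <- fiber_fit(dat, "two_fiber", n_starts = 2,
                   init = c(c2 = 15, k1 = 12, k2 = 3.5), seed = 5)
  expect_error(bootstrap_fit(fit, n_iter = 1), "at least 2")
  b1 <- bootstrap_fit(fit, n_iter = 2, seed = 10)
  b2 <- bootstrap_fit(fit, n_iter = 2, seed = 10)
  expect_identical(b1$bootstrap, b2$bootstrap)
  # noise-free data: every resample refit lands on the generating parameters
  b <- bootstrap_fit(fit, n_iter = 20, seed = 11)
  for (nm in colnames(b$bootstrap)) {
    expect_equal(unname(b$bootstrap[, nm]), rep(fit$params[[nm]], 20),
                 tolerance = 1e-4)
  }
  expect_equal(unname(b$boot_estimate), unname(fit$params), tolerance = 1e-3)
})

test_that("bootstrap intervals cover the generating parameters under noise", {
  # scaled-down coverage check: 10 replicates, 60 iterations each
  truth <- c(15, 12, 3.5)
  hits <- sapply(1:10, function(r) {
    dat <- two_fiber_testdata(n_steps = 6, relative_sd = 0.02,
                              absolute_sd = 0, seed = 900 + r)
    fit <- fiber_fit(dat, "two_fiber", n_starts = 1,
                     init = c(c2 = 10, k1 = 10, k2 = 1), seed = r)
    b <- bootstrap_fit(fit, n_iter = 60, seed = 7000 + r)
    ci <- apply(b$bootstrap, 2, quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    all(truth >= ci[1, ] & truth <= ci[2, ])
  })
  expect_gte(mean(hits), 0.7)
})

test_that("best-SSE bootstrap estimate selection is available", {
  dat <- two_fiber_testdata(n_steps = 5, relative_sd = 0.02,
                            absolute_sd = 0, seed = 13)
  fit <- fiber_fit(dat, "two_fiber", n_starts = 1,
                   init = c(c2 = 15, k1 = 12, k2 = 3.5), seed = 13)
  b <- bootstrap_fit(fit, n_iter = 10, seed = 14, estimate = "best_sse")
  expect_identical(b$boot_method, "best_sse")
  expect_equal(unname(b$boot_estimate), unname(coef(fit)), tolerance = 0.25)
})
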