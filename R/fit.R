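#' Planar biaxial dataset
#'
#' Validating constructor for a multi-protocol planar biaxial stress-stretch
#' dataset. Each record holds a protocol identifier, the circumferential and
#' longitudinal stretches and the corresponding experimental Cauchy stresses
#' in kPa. Structural constants measured by imaging travel with the dataset
#' and are held fixed during fitting.
#'
#' @param records Data frame with columns `protocol`, `lambda_theta`,
#'   `lambda_z`, `sigma_theta`, `sigma_z`.
#' @param structure A [structural_constants()] object.
#' @param specimen_id Optional specimen label.
#' @return The records as a data frame of class `biaxial_dataset` carrying
#'   `structure` and `specimen_id` attributes.
#' @export
biaxial_dataset <- function(records, structure, specimen_id = NULL) {
  need <- c("protocol", "lambda_theta", "lambda_z", "sigma_theta", "sigma_z")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  num <- c("lambda_theta", "lambda_z", "sigma_theta", "sigma_z")
  bad <- !stats::complete.cases(records[num]) |
    records$lambda_theta <= 0 | records$lambda_z <= 0 |
    !is.finite(records$sigma_theta) | !is.finite(records$sigma_z)
  if (any(bad))
    stop("invalid biaxial records at row(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  stopifnot(inherits(structure, "structural_constants"))
  structure(records, structure = structure, specimen_id = specimen_id,
            class = c("biaxial_dataset", "data.frame"))
}

.param_names <- function(model) {
  switch(model,
         two_fiber = c("c2", "k1", "k2"),
         four_fiber = c("c4", "k1col", "k2col", "k1el", "k2el",
                        "k1smc", "k2smc"),
         stop("unknown model: ", model))
}

# exponent-like parameters draw from a narrower initialization range
.param_is_exponent <- function(nm) nm %in% c("k2", "k2col", "k2el", "k2smc")

.residuals_biaxial <- function(par, dataset, sc, model) {
  names(par) <- .param_names(model)
  th <- cauchy_stress(dataset$lambda_theta, dataset$lambda_z,
                      as.list(par), sc, model)
  c(dataset$sigma_theta - th$sigma_theta, dataset$sigma_z - th$sigma_z)
}

#' Least-squares error of a constitutive parameter set
#'
#' The fitting objective: the sum over all stress-stretch records of the
#' squared circumferential and longitudinal stress residuals,
#' `e = sum((sigma_theta_exp - sigma_theta_th)^2 +
#' (sigma_z_exp - sigma_z_th)^2)` in kPa^2.
#'
#' @param params Named parameter list/vector for the chosen model.
#' @param dataset A [biaxial_dataset()].
#' @param model `"two_fiber"` or `"four_fiber"`.
#' @return The scalar error `e` (kPa^2).
#' @export
objective <- function(params, dataset,
                      model = c("two_fiber", "four_fiber")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "biaxial_dataset"))
  par <- unlist(params[.param_names(model)])
  sum(.residuals_biaxial(par, dataset, attr(dataset, "structure"), model)^2)
}

#' Coefficients of determination of a stress fit
#'
#' Direction-wise goodness of fit, `R^2 = 1 - SS_res / SS_tot`, computed
#' separately for the circumferential and longitudinal stresses with squared
#' residuals and squared deviations from the experimental mean.
#'
#' @inheritParams objective
#' @return Named numeric vector `c(r2_theta, r2_z)`; `NA` with a warning for
#'   a direction whose experimental stresses are constant.
#' @export
r_squared <- function(dataset, params,
                      model = c("two_fiber", "four_fiber")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "biaxial_dataset"))
  sc <- attr(dataset, "structure")
  th <- cauchy_stress(dataset$lambda_theta, dataset$lambda_z,
                      as.list(params), sc, model)
  one <- function(obs, pred) {
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot <= 0) {
      warning("constant experimental stresses: R^2 undefined")
      return(NA_real_)
    }
    1 - sum((obs - pred)^2) / ss_tot
  }
  c(r2_theta = one(dataset$sigma_theta, th$sigma_theta),
    r2_z = one(dataset$sigma_z, th$sigma_z))
}

.random_starts <- function(n, model) {
  nms <- .param_names(model)
  t(vapply(seq_len(n), function(i) {
    vapply(nms, function(nm) {
      if (.param_is_exponent(nm)) 10^stats::runif(1, -2, 2)
      else 10^stats::runif(1, -2, 3)
    }, numeric(1))
  }, numeric(length(nms))))
}

#' Fit a fiber-family constitutive model to planar biaxial data
#'
#' Estimates the material parameters of the two- or four-fiber-family model
#' by damped (Levenberg-Marquardt) least squares on the stress residuals,
#' with the structural constants (mean fiber angle and dispersions) held
#' fixed at their imaging-derived values. The exponential fiber laws admit
#' local minima, so the optimizer is restarted from multiple log-uniform
#' random initial points and the best minimum is kept. All parameters are
#' constrained nonnegative.
#'
#' @param data A [biaxial_dataset()].
#' @param model `"two_fiber"` or `"four_fiber"`.
#' @param n_starts Number of random restarts (default 20).
#' @param init Optional named vector used as an additional (first) start.
#' @param seed Optional integer seed making the random restarts reproducible.
#' @param ftol Relative cost-change convergence tolerance (default 1e-10).
#' @param maxfev Maximum residual evaluations per start (default 2000).
#' @return An object of class `fiber_fit` with components `params` (named
#'   best-fit vector), `sse` (kPa^2), `r2` (direction-wise coefficients of
#'   determination), `converged`, `data`, `model`, `structure`, `n_points`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`, and [bootstrap_fit()] for identifiability analysis.
#' @examples
#' sc <- structural_constants(49, 0.12, 0.39)
#' dat <- simulate_biaxial(list(c2 = 15, k1 = 12, k2 = 3.5), sc,
#'                         make_protocols(n_steps = 8),
#'                         relative_sd = 0, absolute_sd = 0)
#' fit <- fiber_fit(dat, "two_fiber", n_starts = 3, seed = 1)
#' coef(fit)
#' @export
fiber_fit <- function(data, model = c("two_fiber", "four_fiber"),
                      n_starts = 20, init = NULL, seed = NULL,
                      ftol = 1e-10, maxfev = 2000) {
  model <- match.arg(model)
  stopifnot(inherits(data, "biaxial_dataset"))
  if (length(unique(data$protocol)) < 2L)
    warning("fewer than 2 distinct protocols: parameters may not be identifiable")
  sc <- attr(data, "structure")
  nms <- .param_names(model)
  if (!is.null(seed)) set.seed(seed)
  starts <- .random_starts(n_starts, model)
  if (!is.null(init)) {
    init <- unlist(init)[nms]
    if (any(is.na(init))) stop("init must name all model parameters")
    starts <- rbind(pmax(init, 0), starts)
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = ftol, maxfev = maxfev,
                                     maxiter = 500)
  best <- NULL
  ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = rep(0, length(nms)),
                         fn = .residuals_biaxial, dataset = data, sc = sc,
                         model = model, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- res$deviance
    if (is.null(best) || sse < best$deviance) {
      best <- res
      ok <- res$info %in% 1:4
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  params <- stats::setNames(as.numeric(best$par), nms)
  out <- structure(list(
    params = params, sse = best$deviance,
    r2 = r_squared(data, as.list(params), model),
    converged = ok, model = model, structure = sc, data = data,
    n_points = nrow(data), n_starts = nrow(starts),
    call = match.call()),
    class = "fiber_fit")
  if (!ok) warning("optimizer did not report convergence; best-so-far returned")
  out
}

#' Non-parametric bootstrap identifiability analysis
#'
#' Resamples the stress-stretch records with replacement, refits the model
#' to every resample from a randomized initialization near the point
#' estimate, and collects the marginal parameter distributions. The selected
#' estimate is, per parameter, the highest-density mode of its marginal
#' (default), or alternatively the single bootstrap parameter vector with
#' the lowest error on the original dataset.
#'
#' @param object A fitted [fiber_fit()] object.
#' @param n_iter Number of bootstrap iterations (default 2000).
#' @param seed Optional integer seed.
#' @param block Resample whole protocols instead of individual records.
#' @param estimate `"mode"` (marginal highest-density mode) or `"best_sse"`.
#' @return The `fiber_fit` object augmented with `bootstrap` (an
#'   `n_iter x n_params` matrix), `boot_estimate` (named vector) and
#'   `boot_method`.
#' @export
bootstrap_fit <- function(object, n_iter = 2000, seed = NULL, block = FALSE,
                          estimate = c("mode", "best_sse")) {
  stopifnot(inherits(object, "fiber_fit"))
  estimate <- match.arg(estimate)
  if (n_iter < 2L) stop("n_iter must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  sc <- object$structure
  model <- object$model
  nms <- .param_names(model)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, maxfev = 2000,
                                     maxiter = 500)
  point <- object$params
  draws <- matrix(NA_real_, n_iter, length(nms),
                  dimnames = list(NULL, nms))
  protos <- unique(data$protocol)
  for (it in seq_len(n_iter)) {
    idx <- if (block) {
      keep <- sample(protos, length(protos), replace = TRUE)
      unlist(lapply(keep, function(p) which(data$protocol == p)))
    } else {
      sample.int(nrow(data), replace = TRUE)
    }
    boot <- data[idx, , drop = FALSE]
    attr(boot, "structure") <- sc
    class(boot) <- class(data)
    init <- pmax(point, 1e-3) * 10^stats::runif(length(point), -0.3, 0.3)
    res <- tryCatch(
      minpack.lm::nls.lm(par = init, lower = rep(0, length(nms)),
                         fn = .residuals_biaxial, dataset = boot, sc = sc,
                         model = model, control = ctrl),
      error = function(e) NULL)
    if (!is.null(res)) draws[it, ] <- as.numeric(res$par)
  }
  keep <- stats::complete.cases(draws)
  draws_ok <- draws[keep, , drop = FALSE]
  if (nrow(draws_ok) < 2L) stop("bootstrap refits failed")
  est <- if (estimate == "mode") {
    apply(draws_ok, 2L, function(x) {
      if (stats::sd(x) < 1e-12) return(mean(x))
      d <- stats::density(x)
      d$x[which.max(d$y)]
    })
  } else {
    sses <- apply(draws_ok, 1L, function(p)
      objective(as.list(stats::setNames(p, nms)), data, model))
    draws_ok[which.min(sses), ]
  }
  object$bootstrap <- draws
  object$boot_estimate <- stats::setNames(as.numeric(est), nms)
  object$boot_method <- estimate
  object
}

#' @export
print.fiber_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s-family constitutive fit (%d stress-stretch points)\n",
              sub("_", "-", x$model), x$n_points))
  print(round(x$params, digits))
  cat(sprintf("R2 (theta) = %.3f, R2 (z) = %.3f, SSE = %.4g kPa^2\n",
              x$r2[["r2_theta"]], x$r2[["r2_z"]], x$sse))
  invisible(x)
}

#' @export
coef.fiber_fit <- function(object, ...) object$params

#' @export
fitted.fiber_fit <- function(object, ...) {
  cauchy_stress(object$data$lambda_theta, object$data$lambda_z,
                as.list(object$params), object$structure, object$model)
}

#' @export
residuals.fiber_fit <- function(object, ...) {
  f <- fitted(object)
  data.frame(sigma_theta = object$data$sigma_theta - f$sigma_theta,
             sigma_z = object$data$sigma_z - f$sigma_z)
}

#' Predict biaxial stresses from a fitted constitutive model
#'
#' @param object A `fiber_fit` object.
#' @param newdata Optional data frame with columns `lambda_theta`,
#'   `lambda_z`; defaults to the fitting data.
#' @param ... Unused.
#' @return Data frame with `sigma_theta`, `sigma_z` (kPa).
#' @export
predict.fiber_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  cauchy_stress(newdata$lambda_theta, newdata$lambda_z,
                as.list(object$params), object$structure, object$model)
}

#' @export
summary.fiber_fit <- function(object, level = 0.95, ...) {
  out <- list(fit = object, level = level)
  if (!is.null(object$bootstrap)) {
    q <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- t(apply(object$bootstrap, 2L, stats::quantile, probs = q,
                  na.rm = TRUE))
    out$ci <- ci
  }
  class(out) <- "summary.fiber_fit"
  out
}

#' @export
print.summary.fiber_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat(sprintf("Bootstrap %g%% percentile intervals (%d iterations, %s estimate):\n",
                100 * x$level, nrow(x$fit$bootstrap), x$fit$boot_method))
    tab <- cbind(estimate = x$fit$boot_estimate, x$ci)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Plot experimental and fitted biaxial stress-stretch curves
#'
#' Experimental stresses (points) and model predictions (lines) against the
#' stretch of each loading direction.
#'
#' @param x A `fiber_fit` object.
#' @param protocols Optional subset of protocol identifiers to display.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.fiber_fit <- function(x, protocols = NULL, ...) {
  d <- x$data
  if (!is.null(protocols)) d <- d[d$protocol %in% protocols, , drop = FALSE]
  f <- cauchy_stress(d$lambda_theta, d$lambda_z, as.list(x$params),
                     x$structure, x$model)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (dir in c("theta", "z")) {
    lam <- if (dir == "theta") d$lambda_theta else d$lambda_z
    obs <- if (dir == "theta") d$sigma_theta else d$sigma_z
    pred <- if (dir == "theta") f$sigma_theta else f$sigma_z
    graphics::plot(lam, obs, pch = 16, cex = 0.4, col = "grey50",
                   xlab = bquote(lambda[.(dir)]),
                   ylab = sprintf("Cauchy stress %s (kPa)", dir), ...)
    for (p in unique(d$protocol)) {
      i <- d$protocol == p
      graphics::lines(lam[i][order(lam[i])], pred[i][order(lam[i])],
                      col = "red3")
    }
  }
  invisible(x)
}

#' Simulate datasets from a fitted constitutive model
#'
#' Draws new datasets at the fitted parameters over the same stretch paths,
#' perturbing the model stresses with the multiplicative/additive Gaussian
#' noise model of [simulate_biaxial()].
#'
#' @param object A `fiber_fit` object.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param relative_sd,absolute_sd Noise levels (defaults 0.02 and 0.5 kPa).
#' @param ... Unused.
#' @return A list of `nsim` [biaxial_dataset()] objects.
#' @export
simulate.fiber_fit <- function(object, nsim = 1, seed = NULL,
                               relative_sd = 0.02, absolute_sd = 0.5, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  d <- object$data
  lapply(seq_len(nsim), function(i) {
    noisy <- data.frame(
      protocol = d$protocol,
      lambda_theta = d$lambda_theta, lambda_z = d$lambda_z,
      sigma_theta = f$sigma_theta * (1 + stats::rnorm(nrow(d), 0, relative_sd)) +
        stats::rnorm(nrow(d), 0, absolute_sd),
      sigma_z = f$sigma_z * (1 + stats::rnorm(nrow(d), 0, relative_sd)) +
        stats::rnorm(nrow(d), 0, absolute_sd))
    biaxial_dataset(noisy, object$structure, attr(d, "specimen_id"))
  })
}
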