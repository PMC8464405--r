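#' Angular distribution of fiber orientations
#'
#' Container for a wedge-binned angular distribution of relative fiber
#' amplitudes, as produced by Fourier power-spectrum wedge filtering of a
#' fibrous-texture image. Wedge centers cover `[0, 180)` degrees in equal
#' steps and amplitudes are normalized to sum to one.
#'
#' @param wedge_centers Numeric vector of wedge center angles in degrees,
#'   equally spaced over `[0, 180)`.
#' @param amplitudes Nonnegative numeric vector of relative amplitudes, one
#'   per wedge. Normalized to sum to 1 on construction.
#' @return An object of class `angular_distribution`: a list with elements
#'   `wedge_centers`, `amplitudes` and `wedge_width` (degrees).
#' @examples
#' ad <- angular_distribution(seq(0, 175, by = 5), rep(1, 36))
#' sum(ad$amplitudes)  # 1
#' @export
angular_distribution <- function(wedge_centers, amplitudes) {
  wedge_centers <- as.numeric(wedge_centers)
  amplitudes <- as.numeric(amplitudes)
  if (length(wedge_centers) != length(amplitudes))
    stop("wedge_centers and amplitudes must have equal length")
  if (length(wedge_centers) < 2L)
    stop("need at least two wedges")
  steps <- diff(wedge_centers)
  w <- steps[1L]
  if (any(abs(steps - w) > 1e-9))
    stop("wedge_centers must be equally spaced")
  if (abs(length(wedge_centers) * w - 180) > 1e-6)
    stop("wedges must tile [0, 180) degrees")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0))
    stop("amplitudes must be finite and nonnegative")
  s <- sum(amplitudes)
  if (s <= 0) stop("degenerate angular distribution: all amplitudes are zero")
  structure(
    list(wedge_centers = wedge_centers, amplitudes = amplitudes / s,
         wedge_width = w),
    class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("Angular distribution: %d wedges of %g deg, peak at %g deg\n",
              length(x$wedge_centers), x$wedge_width,
              x$wedge_centers[which.max(x$amplitudes)]))
  invisible(x)
}

#' In-plane von Mises orientation density
#'
#' Probability density of the in-plane fiber angle for one fiber family,
#' `rho_ip(phi) = exp(a * cos(2 * (phi - alpha))) / I0(a)`, a pi-periodic von
#' Mises density with concentration `a` peaked at the mean fiber angle
#' `alpha`. `rho_ip_mixture()` evaluates the symmetric two-family mixture
#' `(rho(phi; +alpha) + rho(phi; -alpha)) / 2` used when fitting angular
#' profiles that show a pair of mirrored peaks.
#'
#' The density is normalized against the uniform measure on the circle:
#' `mean over [0, 2*pi) of rho_ip = 1`, i.e.
#' `(1 / (2*pi)) * integral(rho_ip) = 1`.
#'
#' @param phi In-plane angle(s), radians.
#' @param a Concentration parameter, dimensionless, `>= 0`.
#' @param alpha Mean fiber angle from the circumferential direction, radians.
#' @return Density value(s), dimensionless.
#' @seealso [kappa_ip()], [fit_inplane()]
#' @export
rho_ip <- function(phi, a, alpha = 0) {
  if (!is.finite(a) || a < 0) stop("concentration parameter a must be >= 0")
  # scaled form exp(a (cos - 1)) / (I0(a) e^-a) avoids overflow at large a
  i0s <- besselI(a, 0, expon.scaled = TRUE)
  if (i0s == 0) i0s <- 1 / sqrt(2 * pi * a)  # asymptotic, a beyond ~2e5
  exp(a * (cos(2 * (phi - alpha)) - 1)) / i0s
}

#' @rdname rho_ip
#' @export
rho_ip_mixture <- function(phi, a, alpha) {
  0.5 * (rho_ip(phi, a, alpha) + rho_ip(phi, a, -alpha))
}

#' Out-of-plane von Mises orientation density
#'
#' Probability density of the out-of-plane fiber angle,
#' `rho_op(theta) = 2 * sqrt(2*b/pi) * exp(b * (cos(2*theta) - 1)) /
#' erf(sqrt(2*b))`, an even density on `[-pi/2, pi/2]` peaked at the
#' circumferential-longitudinal plane (`theta = 0`). Normalized over the
#' sphere measure: `(1/2) * integral(rho_op(theta) * cos(theta)) = 1`.
#' The expression is 0/0 at `b = 0`; its analytic limit, the constant
#' density 1, is returned there.
#'
#' @param theta Out-of-plane angle(s), radians, in `[-pi/2, pi/2]`.
#' @param b Concentration parameter, dimensionless, `>= 0`.
#' @return Density value(s), dimensionless.
#' @seealso [kappa_op()], [fit_outofplane()]
#' @export
rho_op <- function(theta, b) {
  if (!is.finite(b) || b < 0) stop("concentration parameter b must be >= 0")
  if (any(theta < -pi / 2 - 1e-12) || any(theta > pi / 2 + 1e-12))
    stop("theta must lie in [-pi/2, pi/2]")
  if (b == 0) return(rep(1, length(theta)))
  2 * sqrt(2 * b / pi) * exp(b * (cos(2 * theta) - 1)) / erf_(sqrt(2 * b))
}

# error function via the normal CDF
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' In-plane dispersion parameter
#'
#' Maps the in-plane von Mises concentration `a` to the scalar dispersion
#' `kappa_ip = 1/2 - I1(a) / (2 * I0(a))`, bounded in `[0, 1]` (1/2 for an
#' isotropic plane, 0 for perfect alignment). Strictly decreasing in `a`.
#' For very large `a` the Bessel ratio is evaluated by its asymptotic
#' expansion to avoid underflow of the scaled Bessel functions.
#'
#' @param a Concentration parameter(s), dimensionless, `>= 0`.
#' @return `kappa_ip` value(s) in `[0, 1]`.
#' @examples
#' kappa_ip(0)    # 0.5, isotropic
#' kappa_ip(1e6)  # ~0, perfect alignment
#' @export
kappa_ip <- function(a) {
  if (any(!is.finite(a)) || any(a < 0))
    stop("concentration parameter a must be >= 0")
  ratio <- function(x) {
    if (x > 1e4) {
      # asymptotic I1/I0 for large argument
      1 - 1 / (2 * x) - 1 / (8 * x^2) - 1 / (8 * x^3)
    } else {
      besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
    }
  }
  0.5 - vapply(a, ratio, numeric(1)) / 2
}

#' Out-of-plane dispersion parameter
#'
#' Maps the out-of-plane concentration `b` to the scalar dispersion
#' `kappa_op = 1/2 - 1/(8b) + (1/4) * sqrt(2/(pi*b)) * exp(-2b) /
#' erf(sqrt(2b))`, bounded in `[0, 1/2]` (1/3 in the isotropic limit
#' `b -> 0`, 1/2 for perfect in-plane alignment). Strictly increasing in
#' `b`. The `b = 0` singularity is replaced by its analytic limit 1/3.
#'
#' @param b Concentration parameter(s), dimensionless, `>= 0`.
#' @return `kappa_op` value(s) in `[0, 1/2]`.
#' @examples
#' kappa_op(0)    # 1/3
#' kappa_op(1e6)  # ~0.5
#' @export
kappa_op <- function(b) {
  if (any(!is.finite(b)) || any(b < 0))
    stop("concentration parameter b must be >= 0")
  out <- numeric(length(b))
  small <- b < 1e-6
  # series about b = 0: kappa_op = 1/3 + 4b/45 + O(b^2)
  out[small] <- 1 / 3 + 4 * b[small] / 45
  bb <- b[!small]
  out[!small] <- 0.5 - 1 / (8 * bb) +
    0.25 * sqrt(2 / (pi * bb)) * exp(-2 * bb) / erf_(sqrt(2 * bb))
  out
}

# sum-normalized model profile at wedge centers (degrees)
.profile_ip <- function(centers_deg, a, alpha_rad) {
  q <- rho_ip_mixture(centers_deg * pi / 180, a, alpha_rad)
  q / sum(q)
}

.profile_op <- function(theta_deg, b) {
  q <- rho_op(theta_deg * pi / 180, b)
  q / sum(q)
}

#' Classify an angular distribution as isotropic or anisotropic
#'
#' An image plane is called isotropic when its cumulative angular amplitude
#' distribution is linear: a first-order polynomial is fitted to the
#' cumulative sum of wedge amplitudes against wedge index and the image is
#' isotropic when the fit's R-squared meets the threshold (a uniform angular
#' density has an exactly linear cumulative curve). Isotropic planes are
#' assigned concentration 0 and no peak location.
#'
#' @param dist An [angular_distribution()].
#' @param r2_threshold Linearity threshold on the cumulative distribution;
#'   default 0.9998.
#' @return Logical: `TRUE` when isotropic.
#' @export
classify_isotropy <- function(dist, r2_threshold = 0.9998) {
  stopifnot(inherits(dist, "angular_distribution"))
  cum <- cumsum(dist$amplitudes)
  idx <- seq_along(cum)
  fit <- stats::lm.fit(cbind(1, idx), cum)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cum - mean(cum))^2)
  if (ss_tot <= 0) return(TRUE)  # constant cumulative curve cannot occur; guard
  r2 <- 1 - ss_res / ss_tot
  r2 >= r2_threshold
}

#' Fit the in-plane von Mises model to an angular distribution
#'
#' Estimates the concentration `a` and mean fiber angle `alpha` by least
#' squares between the normalized wedge amplitudes and the symmetric
#' two-family mixture density evaluated at the wedge centers. The image is
#' first screened by [classify_isotropy()]; isotropic profiles are assigned
#' `a = 0` and no peak location.
#'
#' @param dist An [angular_distribution()] over `[0, 180)` degrees.
#' @param r2_threshold Isotropy threshold passed to [classify_isotropy()].
#' @return A list of class `vonmises_fit` with elements `a`, `alpha_deg`
#'   (in `[0, 90]`, `NA` when isotropic), `isotropic`, `sse` and `r2`
#'   (goodness of the profile fit).
#' @export
fit_inplane <- function(dist, r2_threshold = 0.9998) {
  stopifnot(inherits(dist, "angular_distribution"))
  w <- dist$amplitudes
  centers <- dist$wedge_centers
  if (classify_isotropy(dist, r2_threshold)) {
    return(structure(list(a = 0, alpha_deg = NA_real_, isotropic = TRUE,
                          sse = NA_real_, r2 = NA_real_),
                     class = "vonmises_fit"))
  }
  sse_fun <- function(par) {
    if (any(!is.finite(par))) return(1e6)
    # optimizer may probe epsilon below the box constraint
    q <- .profile_ip(centers, max(par[1L], 0), par[2L])
    if (any(!is.finite(q))) return(1e6)
    sum((w - q)^2)
  }
  # ties in the peak broken toward the smaller angle (which.max takes first)
  peak <- centers[which.max(w)]
  alpha0 <- if (peak > 90) 180 - peak else peak
  best <- NULL
  for (a0 in c(0.5, 2, 5, 15, 50)) {
    for (al0 in unique(pmin(pmax(c(alpha0, alpha0 - 10, alpha0 + 10), 0), 90))) {
      opt <- stats::optim(c(a0, al0 * pi / 180), sse_fun, method = "L-BFGS-B",
                          lower = c(0, 0), upper = c(1e4, pi / 2))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  ss_tot <- sum((w - mean(w))^2)
  structure(list(a = max(best$par[1L], 0), alpha_deg = best$par[2L] * 180 / pi,
                 isotropic = FALSE, sse = best$value,
                 r2 = 1 - best$value / ss_tot),
            class = "vonmises_fit")
}

#' Fit the out-of-plane von Mises model to an angular distribution
#'
#' Estimates the concentration `b` by least squares between the normalized
#' wedge amplitudes and `rho_op` evaluated at the wedge centers, with the
#' peak constrained to the circumferential-longitudinal plane (0 degrees).
#' Wedge centers over `[0, 180)` are mapped to out-of-plane angles in
#' `(-90, 90]`. Isotropic profiles are assigned `b = 0`.
#'
#' @inheritParams fit_inplane
#' @return A list of class `vonmises_fit` with elements `b`, `isotropic`,
#'   `sse` and `r2`.
#' @export
fit_outofplane <- function(dist, r2_threshold = 0.9998) {
  stopifnot(inherits(dist, "angular_distribution"))
  w <- dist$amplitudes
  theta_deg <- ifelse(dist$wedge_centers > 90,
                      dist$wedge_centers - 180, dist$wedge_centers)
  if (classify_isotropy(dist, r2_threshold)) {
    return(structure(list(b = 0, isotropic = TRUE,
                          sse = NA_real_, r2 = NA_real_),
                     class = "vonmises_fit"))
  }
  sse_fun <- function(b) {
    if (!is.finite(b)) return(1e6)
    q <- .profile_op(theta_deg, max(b, 0))
    if (any(!is.finite(q))) return(1e6)
    sum((w - q)^2)
  }
  best <- NULL
  for (b0 in c(0.5, 2, 8, 30, 100)) {
    opt <- stats::optim(b0, sse_fun, method = "L-BFGS-B",
                        lower = 0, upper = 1e4)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ss_tot <- sum((w - mean(w))^2)
  structure(list(b = max(best$par, 0), isotropic = FALSE, sse = best$value,
                 r2 = 1 - best$value / ss_tot),
            class = "vonmises_fit")
}

#' @export
print.vonmises_fit <- function(x, ...) {
  if (isTRUE(x$isotropic)) {
    cat("von Mises fit: isotropic plane (concentration assigned 0)\n")
  } else if (!is.null(x$alpha_deg)) {
    cat(sprintf("von Mises fit: a = %.3f, alpha = %.1f deg (profile R2 = %.4f)\n",
                x$a, x$alpha_deg, x$r2))
  } else {
    cat(sprintf("von Mises fit: b = %.3f (profile R2 = %.4f)\n", x$b, x$r2))
  }
  invisible(x)
}

#' Aggregate per-image fits into specimen-level structural parameters
#'
#' Combines per-image in-plane and out-of-plane von Mises fits into one
#' specimen-level dispersion set: the mean fiber angle is the mean of the
#' anisotropic per-image peak locations (their standard deviation is
#' reported alongside), and the dispersion parameters are computed from the
#' mean concentration parameters, `kappa_ip(mean a)` and `kappa_op(mean b)`.
#' Isotropic images contribute concentration 0 to the means (configurable).
#'
#' @param in_plane List of `vonmises_fit` objects from [fit_inplane()]
#'   (at least one required).
#' @param out_of_plane Optional list of `vonmises_fit` objects from
#'   [fit_outofplane()].
#' @param include_isotropic Should isotropic images enter the concentration
#'   means as zeros (default `TRUE`) or be excluded?
#' @return A list of class `dispersion_set` with `alpha_deg`, `alpha_sd_deg`,
#'   `kappa_ip`, `kappa_op`, `a_mean`, `b_mean`, `n_images`, `n_isotropic`.
#'   `alpha_deg` is `NA` (flagged) when every in-plane image is isotropic;
#'   `kappa_op` and `b_mean` are `NA` when no out-of-plane images are given.
#' @export
aggregate_stack <- function(in_plane, out_of_plane = list(),
                            include_isotropic = TRUE) {
  if (length(in_plane) == 0L) stop("need at least one in-plane image fit")
  stopifnot(all(vapply(in_plane, inherits, logical(1), "vonmises_fit")))
  iso_ip <- vapply(in_plane, function(f) isTRUE(f$isotropic), logical(1))
  a_all <- vapply(in_plane, function(f) f$a, numeric(1))
  a_use <- if (include_isotropic) a_all else a_all[!iso_ip]
  if (length(a_use) == 0L) a_use <- 0
  peaks <- vapply(in_plane[!iso_ip], function(f) f$alpha_deg, numeric(1))
  alpha <- if (length(peaks)) mean(peaks) else NA_real_
  alpha_sd <- if (length(peaks) > 1L) stats::sd(peaks) else
    if (length(peaks) == 1L) 0 else NA_real_

  b_mean <- NA_real_
  n_iso_op <- 0L
  if (length(out_of_plane)) {
    stopifnot(all(vapply(out_of_plane, inherits, logical(1), "vonmises_fit")))
    iso_op <- vapply(out_of_plane, function(f) isTRUE(f$isotropic), logical(1))
    n_iso_op <- sum(iso_op)
    b_all <- vapply(out_of_plane, function(f) f$b, numeric(1))
    b_use <- if (include_isotropic) b_all else b_all[!iso_op]
    if (length(b_use)) b_mean <- mean(b_use)
  }
  structure(list(
    alpha_deg = alpha, alpha_sd_deg = alpha_sd,
    kappa_ip = kappa_ip(mean(a_use)),
    kappa_op = if (is.na(b_mean)) NA_real_ else kappa_op(b_mean),
    a_mean = mean(a_use), b_mean = b_mean,
    n_images = length(in_plane) + length(out_of_plane),
    n_isotropic = sum(iso_ip) + n_iso_op),
    class = "dispersion_set")
}

#' @export
print.dispersion_set <- function(x, ...) {
  cat("Specimen dispersion set\n")
  cat(sprintf("  mean fiber angle alpha : %s deg (SD %s)\n",
              format(round(x$alpha_deg, 1)), format(round(x$alpha_sd_deg, 1))))
  cat(sprintf("  kappa_ip               : %.3f  (mean a = %.3f)\n",
              x$kappa_ip, x$a_mean))
  if (!is.na(x$kappa_op))
    cat(sprintf("  kappa_op               : %.3f  (mean b = %.3f)\n",
                x$kappa_op, x$b_mean))
  cat(sprintf("  images: %d (%d isotropic)\n", x$n_images, x$n_isotropic))
  invisible(x)
}
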