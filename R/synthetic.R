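#' Multi-ratio planar biaxial stretch protocols
#'
#' Builds the 21-protocol stretch-controlled test battery: circumferential to
#' longitudinal stretch ratios 1:0.1 through 1:0.9 and 0.9:1 through 0.1:1
#' in steps of 0.1 (19 ratio protocols), plus three equibiaxial 1:1
#' protocols interleaved at the beginning, middle and end of the sequence.
#' Each protocol is a monotone stretch path from the reference state
#' `(1, 1)`; the sub-maximal axis reaches `1 + ratio * (lambda_max - 1)`.
#'
#' @param lambda_max_theta,lambda_max_z Peak stretches of the full-stretch
#'   axis (dimensionless `> 1`, default 1.3).
#' @param n_steps Points per stretch path (default 50).
#' @return A list of protocol specifications, each a list with `id`,
#'   `ratio_theta`, `ratio_z`, `lambda_theta`, `lambda_z` (stretch paths).
#' @examples
#' length(make_protocols())  # 21
#' @export
make_protocols <- function(lambda_max_theta = 1.3, lambda_max_z = 1.3,
                           n_steps = 50) {
  if (lambda_max_theta <= 1 || lambda_max_z <= 1)
    stop("peak stretches must exceed 1")
  ratios <- rbind(
    cbind(1, seq(0.1, 0.9, by = 0.1)),   # 1:0.1 ... 1:0.9
    cbind(seq(0.9, 0.1, by = -0.1), 1))  # 0.9:1 ... 0.1:1
  specs <- lapply(seq_len(nrow(ratios)), function(i) {
    list(ratio_theta = ratios[i, 1], ratio_z = ratios[i, 2])
  })
  equib <- list(ratio_theta = 1, ratio_z = 1)
  # three equibiaxial repeats: start, middle, end of the sequence
  specs <- c(list(equib), specs[1:9], list(equib), specs[10:18], list(equib))
  t <- seq(0, 1, length.out = n_steps + 1L)[-1L]
  lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    list(id = sprintf("P%02d_%g:%g", i, s$ratio_theta, s$ratio_z),
         ratio_theta = s$ratio_theta, ratio_z = s$ratio_z,
         lambda_theta = 1 + t * s$ratio_theta * (lambda_max_theta - 1),
         lambda_z = 1 + t * s$ratio_z * (lambda_max_z - 1))
  })
}

#' Simulate a planar biaxial dataset from known parameters
#'
#' Forward-evaluates the chosen constitutive model along every protocol
#' stretch path and perturbs the stresses with a multiplicative plus
#' additive Gaussian noise model,
#' `sigma * (1 + eps_rel) + eps_abs`. With both noise levels zero the
#' dataset reproduces the model exactly (the fitting objective vanishes at
#' the generating parameters).
#'
#' @param params Named parameter list for the chosen model.
#' @param sc A [structural_constants()] object.
#' @param protocols Protocol list from [make_protocols()].
#' @param model `"two_fiber"` or `"four_fiber"`.
#' @param relative_sd Multiplicative noise SD (default 0.02).
#' @param absolute_sd Additive noise SD in kPa (default 0.5).
#' @param seed Optional integer seed.
#' @param specimen_id Optional label.
#' @return A [biaxial_dataset()].
#' @export
simulate_biaxial <- function(params, sc, protocols = make_protocols(),
                             model = c("two_fiber", "four_fiber"),
                             relative_sd = 0.02, absolute_sd = 0.5,
                             seed = NULL, specimen_id = "synthetic") {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  recs <- do.call(rbind, lapply(protocols, function(p) {
    s <- cauchy_stress(p$lambda_theta, p$lambda_z, params, sc, model)
    data.frame(protocol = p$id, lambda_theta = p$lambda_theta,
               lambda_z = p$lambda_z,
               sigma_theta = s$sigma_theta, sigma_z = s$sigma_z)
  }))
  n <- nrow(recs)
  recs$sigma_theta <- recs$sigma_theta *
    (1 + stats::rnorm(n, 0, relative_sd)) + stats::rnorm(n, 0, absolute_sd)
  recs$sigma_z <- recs$sigma_z *
    (1 + stats::rnorm(n, 0, relative_sd)) + stats::rnorm(n, 0, absolute_sd)
  biaxial_dataset(recs, sc, specimen_id)
}

#' Sample in-plane fiber angles from the symmetric von Mises mixture
#'
#' Draws angles from the two-family mixture
#' `(rho_ip(phi; a, +alpha) + rho_ip(phi; a, -alpha)) / 2` on `[-90, 90)`
#' degrees, by rejection sampling (a Gaussian approximation with
#' `sd = 1/(2*sqrt(a))` is used for very large concentrations).
#'
#' @param n Number of angles.
#' @param a Concentration parameter `>= 0`.
#' @param alpha_deg Mean fiber angle, degrees.
#' @return Angles in degrees in `[-90, 90)`.
#' @export
sample_inplane_angles <- function(n, a, alpha_deg) {
  if (a < 0) stop("a must be >= 0")
  fam <- sample(c(-1, 1), n, replace = TRUE)
  if (a == 0) return(stats::runif(n, -90, 90))
  if (a > 100) {
    dev <- stats::rnorm(n, 0, sd = 1 / (2 * sqrt(a)) * 180 / pi)
  } else {
    dev <- numeric(0)
    while (length(dev) < n) {
      m <- 4L * (n - length(dev)) + 32L
      cand <- stats::runif(m, -pi / 2, pi / 2)
      acc <- stats::runif(m) < exp(a * (cos(2 * cand) - 1))
      dev <- c(dev, cand[acc] * 180 / pi)
    }
    dev <- dev[seq_len(n)]
  }
  ang <- fam * alpha_deg + dev
  (ang + 90) %% 180 - 90
}

#' Sample out-of-plane fiber angles from the von Mises density
#'
#' Draws angles with density proportional to `rho_op(theta; b)` on
#' `[-90, 90]` degrees by rejection sampling (Gaussian approximation for
#' very large `b`).
#'
#' @param n Number of angles.
#' @param b Concentration parameter `>= 0`.
#' @return Angles in degrees in `[-90, 90]`.
#' @export
sample_outofplane_angles <- function(n, b) {
  if (b < 0) stop("b must be >= 0")
  if (b == 0) return(stats::runif(n, -90, 90))
  if (b > 100) return(stats::rnorm(n, 0, sd = 1 / (2 * sqrt(b)) * 180 / pi))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 4L * (n - length(out)) + 32L
    cand <- stats::runif(m, -pi / 2, pi / 2)
    acc <- stats::runif(m) < exp(b * (cos(2 * cand) - 1))
    out <- c(out, cand[acc] * 180 / pi)
  }
  out[seq_len(n)]
}

# rasterize a set of oriented (possibly undulated) curves into an image
.render_angles <- function(angles_deg, size_px, undulation_amplitude,
                           undulation_wavelength, background_sd) {
  img <- matrix(0, size_px, size_px)
  n_fibers <- length(angles_deg)
  cx <- stats::runif(n_fibers, 1, size_px)
  cy <- stats::runif(n_fibers, 1, size_px)
  phase <- stats::runif(n_fibers, 0, 2 * pi)
  tt <- seq(-size_px, size_px, by = 0.5)
  xs <- ys <- ws <- vector("list", n_fibers)
  for (i in seq_len(n_fibers)) {
    th <- angles_deg[i] * pi / 180
    u <- if (undulation_amplitude > 0)
      undulation_amplitude * sin(2 * pi * tt / undulation_wavelength +
                                   phase[i])
    else 0
    x <- cx[i] + tt * cos(th) - u * sin(th)
    y <- cy[i] + tt * sin(th) + u * cos(th)
    keep <- x >= 1 & x <= size_px - 1e-9 & y >= 1 & y <= size_px - 1e-9
    xs[[i]] <- x[keep]; ys[[i]] <- y[keep]
  }
  x <- unlist(xs); y <- unlist(ys)
  if (length(x)) {
    # bilinear splat onto the 4 neighbouring pixels (row = y, col = x)
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    idx <- function(r, c) (c - 1) * size_px + r
    all_i <- c(idx(y0, x0), idx(y0 + 1, x0), idx(y0, x0 + 1),
               idx(y0 + 1, x0 + 1))
    all_w <- c((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
    acc <- rowsum(all_w, all_i)
    img[as.integer(rownames(acc))] <- img[as.integer(rownames(acc))] + acc
  }
  # slight separable blur gives the fibers finite thickness
  blur1 <- function(m) {
    p <- cbind(m[, 1], m, m[, ncol(m)])
    0.25 * p[, 1:(ncol(p) - 2)] + 0.5 * m + 0.25 * p[, 3:ncol(p)]
  }
  img <- t(blur1(t(blur1(img))))
  if (background_sd > 0)
    img <- img + matrix(stats::rnorm(size_px^2, 0,
                                     background_sd * max(img, 1e-12)),
                        size_px, size_px)
  pmax(img, 0)
}

#' Render a synthetic fibrous-texture image
#'
#' Draws bright anti-aliased fiber curves on a dark background, with chord
#' orientations sampled from the symmetric in-plane von Mises mixture
#' (`plane = "in_plane"`, concentration `a`, mean angle `alpha_deg`) or from
#' the out-of-plane density (`plane = "out_of_plane"`, concentration `b`,
#' peak at 0 degrees). Optional sinusoidal undulation emulates collagen
#' waviness; Gaussian background noise emulates detector noise. Angles are
#' measured from the image x axis (the circumferential direction).
#'
#' @param a Concentration of the in-plane density (`in_plane` only).
#' @param alpha_deg Mean fiber angle, degrees (`in_plane` only).
#' @param b Concentration of the out-of-plane density (`out_of_plane` only).
#' @param n_fibers Number of fiber curves (default 300).
#' @param undulation_amplitude Waviness amplitude in pixels (default 0,
#'   straight fibers).
#' @param undulation_wavelength Waviness wavelength in pixels (default 128;
#'   longer than the orientation band's longest analyzed period, so the
#'   waviness modulation itself stays outside the wedge-filter band).
#' @param size_px Image side length in pixels (default 256).
#' @param background_sd Background noise SD relative to the peak intensity
#'   (default 0.02).
#' @param plane `"in_plane"` or `"out_of_plane"`.
#' @param seed Optional integer seed; fixing it makes the image reproducible.
#' @return A numeric intensity matrix (`size_px x size_px`, `>= 0`) with
#'   attribute `plane`.
#' @export
render_fiber_image <- function(a = NULL, alpha_deg = NULL, b = NULL,
                               n_fibers = 300, undulation_amplitude = 0,
                               undulation_wavelength = 128, size_px = 256,
                               background_sd = 0.02,
                               plane = c("in_plane", "out_of_plane"),
                               seed = NULL) {
  plane <- match.arg(plane)
  if (!is.null(seed)) set.seed(seed)
  angles <- if (plane == "in_plane") {
    if (is.null(a) || is.null(alpha_deg))
      stop("in-plane rendering needs a and alpha_deg")
    sample_inplane_angles(n_fibers, a, alpha_deg)
  } else {
    if (is.null(b)) stop("out-of-plane rendering needs b")
    sample_outofplane_angles(n_fibers, b)
  }
  img <- .render_angles(angles, size_px, undulation_amplitude,
                        undulation_wavelength, background_sd)
  attr(img, "plane") <- plane
  img
}

#' Generate a synthetic cohort with an imposed age trend
#'
#' Emulates the structure of a cohort table: ages uniform on `[12, 70]`
#' years, out-of-plane dispersion following
#' `kappa_op = slope * age + intercept + noise`, with configurable linear
#' trends for the in-plane dispersion and the mean fiber angle.
#'
#' @param n Number of specimens (`>= 3`).
#' @param slope,intercept Imposed `kappa_op`-on-age trend (default 0.0011
#'   per year and 0.37).
#' @param noise_sd Gaussian noise SD on `kappa_op` (default 0.02).
#' @param alpha_mean,alpha_slope Mean fiber angle intercept (degrees) and
#'   age slope (degrees/year).
#' @param kip_mean,kip_slope In-plane dispersion intercept and age slope.
#' @param seed Optional integer seed.
#' @return Data frame with columns `id`, `age`, `sex`, `alpha_deg`,
#'   `kappa_ip`, `kappa_op`.
#' @export
synth_cohort <- function(n = 14, slope = 0.0011, intercept = 0.37,
                         noise_sd = 0.02, alpha_mean = 50,
                         alpha_slope = -0.15, kip_mean = 0.16,
                         kip_slope = 0, seed = NULL) {
  if (n < 3) stop("need at least 3 specimens")
  if (!is.null(seed)) set.seed(seed)
  age <- stats::runif(n, 12, 70)
  kop <- slope * age + intercept + stats::rnorm(n, 0, noise_sd)
  data.frame(
    id = seq_len(n), age = age,
    sex = sample(c("M", "F"), n, replace = TRUE),
    alpha_deg = pmin(pmax(alpha_mean + alpha_slope * (age - mean(age)) +
                            stats::rnorm(n, 0, 5), 0), 90),
    kappa_ip = pmin(pmax(kip_mean + kip_slope * age +
                           stats::rnorm(n, 0, 0.02), 0), 1),
    kappa_op = pmin(pmax(kop, 0), 0.5))
}
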