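#' 2-D median filter
#'
#' Square-window median filter with edge replication, used by the
#' despeckling steps of [preprocess_image()]. Vectorized rank-counting
#' implementation (no per-pixel sorting), exact for odd window sizes.
#'
#' @param img Numeric matrix.
#' @param size Odd window side length (default 3).
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter <- function(img, size = 3) {
  stopifnot(is.matrix(img), size %% 2 == 1, size >= 1)
  if (size == 1) return(img)
  r <- (size - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # replicate-padded shifted copies, one column per window offset
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  k <- nrow(offs)
  m <- matrix(0, nr * nc, k)
  for (j in seq_len(k)) {
    rows <- pmin(pmax(seq_len(nr) + offs$dy[j], 1L), nr)
    cols <- pmin(pmax(seq_len(nc) + offs$dx[j], 1L), nc)
    m[, j] <- as.vector(img[rows, cols])
  }
  target <- (k + 1L) %/% 2L
  out <- rep(NA_real_, nr * nc)
  for (j in seq_len(k)) {
    less <- rowSums(m < m[, j])
    leq <- less + rowSums(m == m[, j])
    hit <- is.na(out) & less < target & leq >= target
    out[hit] <- m[hit, j]
  }
  matrix(out, nr, nc)
}

#' Preprocess a fibrous-texture image
#'
#' Contrast enhancement and despeckling ahead of orientation analysis:
#' saturated maxima (white noise from calcification or dust) are clipped at
#' a high intensity quantile, followed by a first median filter pass,
#' min-max normalization to `[0, 1]`, a second median filter pass, and a
#' final contrast stretch back to `[0, 1]`. A constant image is returned
#' unchanged with a warning.
#'
#' @param img Numeric intensity matrix (finite, `>= 0`).
#' @param clip_quantile Quantile above which intensities are clipped
#'   (default 0.999).
#' @param median_size Median filter window for both passes (default 3).
#' @return Preprocessed matrix with intensities in `[0, 1]`.
#' @export
preprocess_image <- function(img, clip_quantile = 0.999, median_size = 3) {
  stopifnot(is.matrix(img))
  if (any(!is.finite(img)) || any(img < 0))
    stop("image intensities must be finite and nonnegative")
  if (min(dim(img)) < 64) stop("image must be at least 64 px on each side")
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("constant image: preprocessing skipped")
    return(img)
  }
  hi <- stats::quantile(img, clip_quantile, names = FALSE)
  img <- pmin(img, hi)
  img <- median_filter(img, median_size)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  img <- median_filter(img, median_size)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  img
}

#' Angular orientation distribution by Fourier wedge filtering
#'
#' Estimates the distribution of texture orientations from the 2-D Fourier
#' power spectrum: the image is windowed (raised cosine, suppressing edge
#' discontinuity artifacts), transformed, and the spectral power is summed
#' over angular wedges within a radial frequency band that excludes the DC
#' region and illumination gradients at the low end and pixel noise at the
#' high end. Spectral orientation is rotated by 90 degrees to give spatial
#' fiber orientation. Amplitudes are normalized to sum to one.
#'
#' @param img Numeric intensity matrix (ideally from [preprocess_image()]).
#' @param wedge_width Wedge width in degrees; must divide 180 (default 5).
#' @param radial_band Radial band as a fraction of the Nyquist frequency
#'   (default `c(1/20, 1/4)`).
#' @param window Apply the raised-cosine window (default `TRUE`).
#' @return An [angular_distribution()].
#' @export
orientation_distribution <- function(img, wedge_width = 5,
                                     radial_band = c(1 / 20, 1 / 4),
                                     window = TRUE) {
  stopifnot(is.matrix(img))
  if (180 %% wedge_width != 0) stop("wedge_width must divide 180")
  nr <- nrow(img); nc <- ncol(img)
  img <- img - mean(img)
  if (window) {
    han <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    img <- img * (han(nr) %o% han(nc))
  }
  P <- Mod(stats::fft(img))^2
  # unshifted FFT frequency coordinates in cycles/px (row = y, col = x)
  fy <- (((seq_len(nr) - 1) + nr %/% 2) %% nr - nr %/% 2) / nr
  fx <- (((seq_len(nc) - 1) + nc %/% 2) %% nc - nc %/% 2) / nc
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  rad <- sqrt(FX^2 + FY^2)
  band <- rad >= radial_band[1] * 0.5 & rad <= radial_band[2] * 0.5
  # spatial fiber orientation is the spectral orientation rotated by 90 deg
  ang <- (atan2(FY, FX) * 180 / pi + 90) %% 180
  centers <- seq(0, 180 - wedge_width, by = wedge_width)
  # half-open wedges [c - w/2, c + w/2)
  bin <- floor(((ang + wedge_width / 2) %% 180) / wedge_width) + 1L
  amp <- vapply(seq_along(centers), function(k)
    sum(P[band & bin == k]), numeric(1))
  if (sum(amp) <= 0) stop("no spectral power in the radial band")
  angular_distribution(centers, amp)
}

#' Structural parameters from an image stack
#'
#' Full imaging pipeline for one specimen: every image is preprocessed,
#' converted to an angular distribution by Fourier wedge filtering,
#' classified isotropic/anisotropic, and fitted with the matching von Mises
#' model; the per-image fits are aggregated by [aggregate_stack()] into the
#' specimen-level mean fiber angle and dispersion parameters.
#'
#' @param in_plane List of circumferential-longitudinal plane images
#'   (matrices); at least one required.
#' @param out_of_plane Optional list of circumferential-radial plane images.
#' @param wedge_width Wedge width in degrees (default 5).
#' @param isotropy_r2 Isotropy threshold (default 0.9998).
#' @param clip_quantile,median_size Passed to [preprocess_image()].
#' @param radial_band Passed to [orientation_distribution()].
#' @param include_isotropic Passed to [aggregate_stack()].
#' @return A `dispersion_set` (see [aggregate_stack()]), with the per-image
#'   fits attached as attribute `fits`.
#' @export
stack_pipeline <- function(in_plane, out_of_plane = list(), wedge_width = 5,
                           isotropy_r2 = 0.9998, clip_quantile = 0.999,
                           median_size = 3, radial_band = c(1 / 20, 1 / 4),
                           include_isotropic = TRUE) {
  if (length(in_plane) == 0L) stop("need at least one in-plane image")
  run <- function(img, fitter) {
    pre <- preprocess_image(img, clip_quantile, median_size)
    fitter(orientation_distribution(pre, wedge_width, radial_band),
           r2_threshold = isotropy_r2)
  }
  ip_fits <- lapply(in_plane, run, fitter = fit_inplane)
  op_fits <- lapply(out_of_plane, run, fitter = fit_outofplane)
  out <- aggregate_stack(ip_fits, op_fits, include_isotropic)
  attr(out, "fits") <- list(in_plane = ip_fits, out_of_plane = op_fits)
  out
}
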