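#' Structural constants of the dispersed fiber model
#'
#' Packs the imaging-derived structural parameters (mean fiber angle and the
#' in-plane/out-of-plane dispersions) together with the derived structure
#' tensor constants `A = 2 * kappa_op * kappa_ip` and
#' `B = 2 * kappa_op * (1 - 2 * kappa_ip)`. The generalized structure tensor
#' of each collagen family is
#' `H = A I + B M (x) M + (1 - 3A - B) Mn (x) Mn`, with `M` the mean in-plane
#' fiber direction at `+/- alpha` from the circumferential axis and `Mn` the
#' radial normal. Structural constants are measured, not fitted: they are
#' held fixed during parameter estimation.
#'
#' @param alpha_deg Mean fiber angle from the circumferential direction,
#'   degrees in `[0, 90]`.
#' @param kappa_ip In-plane dispersion, in `[0, 1]`.
#' @param kappa_op Out-of-plane dispersion, in `[0, 1/2]`.
#' @return A list of class `structural_constants` with fields `alpha_deg`,
#'   `alpha` (radians), `kappa_ip`, `kappa_op`, `A`, `B`.
#' @examples
#' structural_constants(61, 0.21, 0.38)
#' @export
structural_constants <- function(alpha_deg, kappa_ip, kappa_op) {
  stopifnot(is.finite(alpha_deg), is.finite(kappa_ip), is.finite(kappa_op))
  if (kappa_ip < 0 || kappa_ip > 1) stop("kappa_ip must lie in [0, 1]")
  if (kappa_op < 0 || kappa_op > 0.5) stop("kappa_op must lie in [0, 1/2]")
  A <- 2 * kappa_op * kappa_ip
  B <- 2 * kappa_op * (1 - 2 * kappa_ip)
  structure(list(alpha_deg = alpha_deg, alpha = alpha_deg * pi / 180,
                 kappa_ip = kappa_ip, kappa_op = kappa_op, A = A, B = B),
            class = "structural_constants")
}

#' @export
print.structural_constants <- function(x, ...) {
  cat(sprintf(
    "Structural constants: alpha = %g deg, kappa_ip = %g, kappa_op = %g (A = %.4f, B = %.4f)\n",
    x$alpha_deg, x$kappa_ip, x$kappa_op, x$A, x$B))
  invisible(x)
}

# radial stretch from incompressibility
.lambda_r <- function(lambda_theta, lambda_z) 1 / (lambda_theta * lambda_z)

.check_stretches <- function(lambda_theta, lambda_z) {
  if (any(!is.finite(lambda_theta)) || any(!is.finite(lambda_z)) ||
      any(lambda_theta <= 0) || any(lambda_z <= 0))
    stop("stretches must be positive and finite")
}

#' Dispersion-weighted fiber strain
#'
#' The Green-Lagrange strain-like quantity of a dispersed collagen family,
#' `E = H : (C - I) = A I1 + B Ii + (1 - 3A - B) In - 1`, where
#' `I1 = lt^2 + lz^2 + lr^2`, `Ii = lt^2 cos^2(alpha) + lz^2 sin^2(alpha)`
#' (identical for both symmetric families) and `In = lr^2`, with
#' `lr = 1/(lt*lz)` from incompressibility.
#'
#' @param lambda_theta,lambda_z Circumferential and longitudinal stretches
#'   (vectorized), dimensionless `> 0`.
#' @param sc A [structural_constants()] object.
#' @return Fiber strain `E`, dimensionless (0 at the identity).
#' @export
fiber_strain <- function(lambda_theta, lambda_z, sc) {
  stopifnot(inherits(sc, "structural_constants"))
  .check_stretches(lambda_theta, lambda_z)
  lr <- .lambda_r(lambda_theta, lambda_z)
  I1 <- lambda_theta^2 + lambda_z^2 + lr^2
  Ii <- lambda_theta^2 * cos(sc$alpha)^2 + lambda_z^2 * sin(sc$alpha)^2
  In <- lr^2
  sc$A * I1 + sc$B * Ii + (1 - 3 * sc$A - sc$B) * In - 1
}

# dPsi_f/dE for the exponential fiber law (per family, Eq. 15 convention)
.psi_prime <- function(k1, k2, E) k1 * E * exp(k2 * E^2)

.check_params <- function(params, fields) {
  miss <- setdiff(fields, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(unlist(params[fields]) < 0))
    stop("material parameters must be nonnegative")
}

#' Planar biaxial Cauchy stresses of the two-fiber-family model
#'
#' Cauchy stresses of the incompressible two-fiber-family model under planar
#' biaxial stretch, with the Lagrange pressure eliminated through the
#' traction-free radial face (`sigma_rr = 0`):
#' \deqn{\sigma_{\theta\theta} = [c_2 + 4(A + B\cos^2\alpha)\psi']\lambda_\theta^2 - p,}
#' \deqn{\sigma_{zz} = [c_2 + 4(A + B\sin^2\alpha)\psi']\lambda_z^2 - p,}
#' \deqn{p = [c_2 + 4(1 - 2A - B)\psi']\lambda_r^2,}
#' with `psi' = k1 * E * exp(k2 * E^2)` and `E` from [fiber_strain()].
#'
#' @inheritParams fiber_strain
#' @param params Named list/vector with `c2`, `k1` (kPa) and `k2`
#'   (dimensionless), all `>= 0`.
#' @return A data frame with columns `sigma_theta`, `sigma_z` (kPa).
#' @export
cauchy_two_fiber <- function(lambda_theta, lambda_z, params, sc) {
  stopifnot(inherits(sc, "structural_constants"))
  .check_stretches(lambda_theta, lambda_z)
  params <- as.list(params)
  .check_params(params, c("c2", "k1", "k2"))
  lr <- .lambda_r(lambda_theta, lambda_z)
  E <- fiber_strain(lambda_theta, lambda_z, sc)
  psi <- .psi_prime(params$k1, params$k2, E)
  c2 <- params$c2
  A <- sc$A; B <- sc$B; ca2 <- cos(sc$alpha)^2; sa2 <- sin(sc$alpha)^2
  p <- (c2 + 4 * (1 - 2 * A - B) * psi) * lr^2
  data.frame(
    sigma_theta = (c2 + 4 * (A + B * ca2) * psi) * lambda_theta^2 - p,
    sigma_z     = (c2 + 4 * (A + B * sa2) * psi) * lambda_z^2 - p)
}

#' Planar biaxial Cauchy stresses of the four-fiber-family model
#'
#' Extends the two-fiber collagen model with two perfectly aligned families:
#' longitudinal elastin (`alpha = pi/2`, `A = 0`, `B = 1`, strain
#' `lz^2 - 1`) and circumferential smooth muscle (`alpha = 0`, strain
#' `lt^2 - 1`). With the fiber energies carrying the `k1/(4 k2)` prefactor,
#' the stresses are
#' \deqn{\sigma_{\theta\theta} = [c_4 + 2(A + B\cos^2\alpha)\psi'_{col} +
#'   k_1^{smc}(\lambda_\theta^2-1)e^{k_2^{smc}(\lambda_\theta^2-1)^2}]\lambda_\theta^2 - p,}
#' \deqn{\sigma_{zz} = [c_4 + 2(A + B\sin^2\alpha)\psi'_{col} +
#'   k_1^{el}(\lambda_z^2-1)e^{k_2^{el}(\lambda_z^2-1)^2}]\lambda_z^2 - p,}
#' \deqn{p = [c_4 + 2(1 - 2A - B)\psi'_{col}]\lambda_r^2,}
#' with `psi'_col = k1col * E * exp(k2col * E^2)`.
#'
#' @inheritParams fiber_strain
#' @param params Named list/vector with `c4`, `k1col`, `k2col`, `k1el`,
#'   `k2el`, `k1smc`, `k2smc`, all `>= 0` (stiffness-like entries in kPa,
#'   exponents dimensionless).
#' @return A data frame with columns `sigma_theta`, `sigma_z` (kPa).
#' @export
cauchy_four_fiber <- function(lambda_theta, lambda_z, params, sc) {
  stopifnot(inherits(sc, "structural_constants"))
  .check_stretches(lambda_theta, lambda_z)
  params <- as.list(params)
  .check_params(params, c("c4", "k1col", "k2col", "k1el", "k2el",
                          "k1smc", "k2smc"))
  lr <- .lambda_r(lambda_theta, lambda_z)
  E <- fiber_strain(lambda_theta, lambda_z, sc)
  psi_col <- .psi_prime(params$k1col, params$k2col, E)
  E_smc <- lambda_theta^2 - 1
  E_el <- lambda_z^2 - 1
  smc <- params$k1smc * E_smc * exp(params$k2smc * E_smc^2)
  el <- params$k1el * E_el * exp(params$k2el * E_el^2)
  c4 <- params$c4
  A <- sc$A; B <- sc$B; ca2 <- cos(sc$alpha)^2; sa2 <- sin(sc$alpha)^2
  p <- (c4 + 2 * (1 - 2 * A - B) * psi_col) * lr^2
  data.frame(
    sigma_theta = (c4 + 2 * (A + B * ca2) * psi_col + smc) * lambda_theta^2 - p,
    sigma_z     = (c4 + 2 * (A + B * sa2) * psi_col + el) * lambda_z^2 - p)
}

#' Cauchy stresses for either fiber-family model
#'
#' Dispatcher over [cauchy_two_fiber()] and [cauchy_four_fiber()].
#'
#' @inheritParams fiber_strain
#' @param params Parameter list for the chosen model.
#' @param model `"two_fiber"` or `"four_fiber"`.
#' @return A data frame with columns `sigma_theta`, `sigma_z` (kPa).
#' @export
cauchy_stress <- function(lambda_theta, lambda_z, params, sc,
                          model = c("two_fiber", "four_fiber")) {
  model <- match.arg(model)
  if (model == "two_fiber")
    cauchy_two_fiber(lambda_theta, lambda_z, params, sc)
  else
    cauchy_four_fiber(lambda_theta, lambda_z, params, sc)
}

#' Strain-energy density of the fiber-family models
#'
#' Total strain energy per reference volume with the radial stretch
#' eliminated by incompressibility, so `Psi` is a function of
#' `(lambda_theta, lambda_z)` alone. For the two-fiber model
#' `Psi = c2/2 (I1 - 3) + 2 * k1/(2 k2) * (exp(k2 E^2) - 1)`; the four-fiber
#' model adds the elastin and smooth-muscle terms with `k1/(4 k2)`
#' prefactors. Under plane stress the Cauchy stresses are the stretch
#' derivatives `sigma_tt = lt * dPsi/dlt`, `sigma_zz = lz * dPsi/dlz`, which
#' provides an independent finite-difference check of the stress formulas.
#'
#' @inheritParams cauchy_stress
#' @return Energy density (kPa), 0 at the identity.
#' @export
strain_energy <- function(lambda_theta, lambda_z, params, sc,
                          model = c("two_fiber", "four_fiber")) {
  model <- match.arg(model)
  stopifnot(inherits(sc, "structural_constants"))
  .check_stretches(lambda_theta, lambda_z)
  params <- as.list(params)
  lr <- .lambda_r(lambda_theta, lambda_z)
  I1 <- lambda_theta^2 + lambda_z^2 + lr^2
  E <- fiber_strain(lambda_theta, lambda_z, sc)
  if (model == "two_fiber") {
    .check_params(params, c("c2", "k1", "k2"))
    ground <- params$c2 / 2 * (I1 - 3)
    fibers <- if (params$k2 > 0)
      2 * params$k1 / (2 * params$k2) * (exp(params$k2 * E^2) - 1)
    else params$k1 * E^2  # k2 -> 0 limit of the exponential law
    ground + fibers
  } else {
    .check_params(params, c("c4", "k1col", "k2col", "k1el", "k2el",
                            "k1smc", "k2smc"))
    expterm <- function(k1, k2, E) {
      if (k2 > 0) k1 / (4 * k2) * (exp(k2 * E^2) - 1) else k1 * E^2 / 4
    }
    E_el <- lambda_z^2 - 1
    E_smc <- lambda_theta^2 - 1
    params$c4 / 2 * (I1 - 3) +
      2 * expterm(params$k1col, params$k2col, E) +
      expterm(params$k1el, params$k2el, E_el) +
      expterm(params$k1smc, params$k2smc, E_smc)
  }
}
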