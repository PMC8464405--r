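# shared in-code fixtures for the test suite

# sinusoidal grating whose stripes run at `angle_deg` from the image x axis
# (the circumferential direction); f in cycles/px
make_grating <- function(angle_deg, size = 256, f = 0.08) {
  th <- angle_deg * pi / 180
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  0.5 + 0.5 * sin(2 * pi * f * (-x * sin(th) + y * cos(th)))
}

# reference structural constants (first cohort specimen)
sc_specimen1 <- function() structural_constants(61, 0.21, 0.38)

# linearity R^2 of the cumulative angular distribution (independent of the
# package's classify_isotropy internals)
cum_linearity_r2 <- function(ad) {
  cum <- cumsum(ad$amplitudes)
  idx <- seq_along(cum)
  fit <- stats::lm(cum ~ idx)
  summary(fit)$r.squared
}

# independent tensor-contraction oracle for the fiber strain:
# E = H : (C - I) with explicit 3x3 matrices in the (theta, z, r) basis
fiber_strain_oracle <- function(lt, lz, alpha_deg, kip, kop) {
  lr <- 1 / (lt * lz)
  A <- 2 * kop * kip
  B <- 2 * kop * (1 - 2 * kip)
  al <- alpha_deg * pi / 180
  M <- c(cos(al), sin(al), 0)
  Mn <- c(0, 0, 1)
  H <- A * diag(3) + B * (M %o% M) + (1 - 3 * A - B) * (Mn %o% Mn)
  C <- diag(c(lt^2, lz^2, lr^2))
  sum(H * (C - diag(3)))
}

# finite-difference Cauchy stresses from the strain energy (plane stress,
# incompressible): sigma_tt = lt dPsi/dlt, sigma_zz = lz dPsi/dlz
fd_stresses <- function(lt, lz, params, sc, model, h = 1e-6) {
  st <- (strain_energy(lt + h, lz, params, sc, model) -
           strain_energy(lt - h, lz, params, sc, model)) / (2 * h) * lt
  sz <- (strain_energy(lt, lz + h, params, sc, model) -
           strain_energy(lt, lz - h, params, sc, model)) / (2 * h) * lz
  c(sigma_theta = st, sigma_z = sz)
}

# small noise-free two-fiber dataset used across fitting tests
two_fiber_testdata <- function(n_steps = 10, relative_sd = 0,
                               absolute_sd = 0, seed = NULL) {
  simulate_biaxial(list(c2 = 15, k1 = 12, k2 = 3.5), sc_specimen1(),
                   make_protocols(n_steps = n_steps),
                   relative_sd = relative_sd, absolute_sd = absolute_sd,
                   seed = seed)
}
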