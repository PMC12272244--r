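# Fixtures built in code: exact-density FOD histograms, band-limited FODs, and
# analytic two-compartment kurtosis tensors.

# histogram whose bin densities are the exact Watson density (no sampling noise)
watson_hist <- function(kappa, n0 = c(0, 0, 1), level = 4) {
  mesh <- axonsm:::icosphere(level)
  dens <- reference_fod_eval("watson", list(kappa = kappa),
                             as.numeric(mesh$centroids %*% n0))
  dens <- dens / (sum(dens * mesh$solid_angle) / (4 * pi))
  structure(list(density = dens, mesh = mesh), class = "sph_hist")
}

# band-limited SH representation of an exponential-decay-family FOD
family_sh <- function(C, lambda, n0 = c(0, 0, 1), lmax = 8, level = 4) {
  mesh <- axonsm:::icosphere(level)
  dens <- family_eval(C, lambda, as.numeric(mesh$centroids %*% n0))
  Y <- axonsm:::sh_basis(mesh$centroids, lmax)
  coef <- as.numeric(t(Y) %*% (dens * mesh$solid_angle))
  idx <- axonsm:::sh_index(lmax)
  names(coef) <- paste0("l", idx$l, "m", idx$m)
  structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
}

# exact cumulant (D, W) tensors of an aligned two-compartment Gaussian mixture
# (stick along z + axially symmetric extra-axonal tensor), packed as a dki_fit
two_comp_dki <- function(f, Da, depar, deperp) {
  Di <- diag(c(0, 0, Da))
  De <- diag(c(deperp, deperp, depar))
  Dbar <- f * Di + (1 - f) * De
  md <- mean(diag(Dbar))
  symprod <- function(A, B) {
    W <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      W[i, j, k, l] <- (A[i, j] * B[k, l] + A[i, k] * B[j, l] + A[i, l] * B[j, k]) / 3
    }
    W
  }
  Wfull <- (3 / md^2) * (f * symprod(Di, Di) + (1 - f) * symprod(De, De) -
                           symprod(Dbar, Dbar))
  idx <- axonsm:::.w4_idx
  w15 <- vapply(1:15, function(j) Wfull[idx[j, 1], idx[j, 2], idx[j, 3], idx[j, 4]], 0)
  structure(list(D = Dbar, W = w15, S0 = 1, md = md), class = "dki_fit")
}

# straight cylinder axon along a direction (no undulation/beading)
straight_axon <- function(direction = c(0, 0, 1), length = 12, diameter = 1,
                          g_ratio = 1, step = 0.25) {
  generate_axon(direction, length, diameter = diameter, g_ratio = g_ratio,
                step_dz = step,
                phases = list(undulation = 0, undulation_azimuth = 0, beading = 0))
}
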