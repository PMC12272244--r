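# The four SM estimators and the DKI machinery.

test_that("DKI recovers single-Gaussian and mixture cumulants", {
  prot <- make_protocol()
  # single tensor: W = 0, D exact
  Dt <- diag(c(1.8, 0.6, 0.4))
  sig <- exp(-prot$b * rowSums((prot$dirs %*% Dt) * prot$dirs))
  dk <- fit_dki(sig, prot)
  expect_equal(dk$D, Dt, tolerance = 1e-8)
  expect_lt(max(abs(dk$W)), 1e-8)
  # isotropic mono-exponential: MD = D0, MK = 0
  sigi <- exp(-prot$b * 1.1)
  dki <- fit_dki(sigi, prot)
  expect_equal(dki$md, 1.1, tolerance = 1e-8)
  expect_lt(max(abs(dki$W)), 1e-8)
  # aligned two-Gaussian mixture: fitted cumulants approach the analytic ones
  # within the b-range truncation error of the quadratic expansion
  f <- 0.4; Da <- 1.2; dep <- 1.8; der <- 0.5
  mix <- f * exp(-prot$b * Da * prot$dirs[, 3]^2) +
    (1 - f) * exp(-prot$b * (der + (dep - der) * prot$dirs[, 3]^2))
  dkm <- fit_dki(mix, prot)
  oracle <- two_comp_dki(f, Da, dep, der)
  # truncation bias is real; quantify against the exact moments
  expect_equal(diag(dkm$D), diag(oracle$D), tolerance = 0.15)
  dirs_chk <- rbind(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))
  K_fit <- axonsm:::dki_akc(dkm, dirs_chk)
  K_or <- axonsm:::dki_akc(oracle, dirs_chk)
  expect_equal(K_fit, K_or, tolerance = 0.35)
})

test_that("WMTI inverts exact two-compartment moments and the p2 formula limits", {
  # exact-moment input with Da < De_par: machine-precision recovery
  for (par in list(c(0.45, 1.6, 1.9, 0.5), c(0.3, 1.0, 1.5, 0.8))) {
    r <- wmti(two_comp_dki(par[1], par[2], par[3], par[4]))
    expect_true(r$valid)
    expect_equal(r$kernel$f, par[1], tolerance = 1e-6)
    expect_equal(r$kernel$Da, par[2], tolerance = 1e-6)
    expect_equal(r$kernel$depar, par[3], tolerance = 1e-6)
    expect_equal(r$kernel$deperp, par[4], tolerance = 1e-6)
    expect_equal(r$p2, 1, tolerance = 1e-6) # aligned truth
  }
  # p2 formula: fully aligned eigenvalues (Da, 0, 0) -> 1; isotropic -> 0
  p2_of <- function(la) {
    Da <- sum(la)
    sqrt(1.5 * sum((la - Da / 3)^2) / Da^2)
  }
  expect_equal(p2_of(c(1.7, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(p2_of(rep(0.4, 3)), 0, tolerance = 1e-12)
})

test_that("NODDI recovers its own generative parameters", {
  prot <- make_protocol()
  kern <- axonsm:::noddi_kernel(0.6, 0.1)
  h <- watson_hist(kappa = 4, n0 = c(1, 2, 2) / 3, level = 4)
  sig <- simulate_signal(prot, h, kern, route = "direct")
  r <- noddi_fit(sig)
  expect_equal(r$f_noddi, 0.6, tolerance = 0.01)
  expect_equal(r$fw, 0.1, tolerance = 0.01)
  expect_equal(unname(r$kappa), 4, tolerance = 0.04)
  expect_true(r$diagnostics$converged)
  # f = 0 data: a single extra-axonal tensor obeying the tortuosity constraint
  sig0 <- simulate_signal(prot, h, axonsm:::noddi_kernel(1e-9, 0), route = "direct")
  expect_lt(noddi_fit(sig0)$f_noddi, 0.05)
  # kappa maps monotonically onto p2 in [0, 1]
  p2s <- vapply(c(0.5, 2, 8, 32), function(k)
    reference_fod_invariants("watson", list(kappa = k), 2), 0)
  expect_true(all(diff(p2s) > 0) && all(p2s >= 0 & p2s <= 1))
})

test_that("SMT recovers its constrained kernel and ignores the FOD", {
  prot <- make_protocol()
  truth <- kernel_params(0.5, 1.8, 1.8, 1.8 * 0.5)
  h <- watson_hist(kappa = 6, level = 4)
  r <- smt_fit(simulate_signal(prot, h, truth, route = "direct"))
  expect_equal(r$kernel$f, 0.5, tolerance = 0.01)
  expect_equal(r$kernel$Da, 1.8, tolerance = 0.01)
  # same kernel, delta FOD: the spherical mean (and hence the fit) is unchanged
  shd <- sh_fit(matrix(c(0, 0, 1), 1), lmax = 6)
  rd <- smt_fit(simulate_signal(prot, shd, truth, route = "sh", lmax = 6))
  expect_equal(rd$kernel$f, r$kernel$f, tolerance = 0.02)
  expect_equal(rd$kernel$Da, r$kernel$Da, tolerance = 0.03)
  # stick signal reproduces the closed-form mean
  stick <- kernel_params(1, 2, 0, 0)
  rs <- smt_fit(simulate_signal(prot, shd, stick, route = "sh", lmax = 6))
  pred <- kernel_projection(rs$kernel, 2, 0)
  expect_equal(pred, 0.4410, tolerance = 5e-3) # 43-direction design quadrature error
  expect_error(smt_fit(c(`2` = 1.5, `3` = 0.2, `4` = 0.1)))
})

test_that("SMI training is seed-stable and meets the recovery gates", {
  prot <- make_protocol()
  mod <- smi_train(prot, n_train = 2e4, seed = 3)
  mod2 <- smi_train(prot, n_train = 2e4, seed = 3)
  expect_identical(mod$coef, mod2$coef)
  # noiseless draws from the prior: median absolute errors under the gates
  set.seed(99)
  n <- 200
  th <- cbind(f = runif(n, .05, .95), Da = runif(n, .5, 2),
              depar = runif(n, .5, 2), deperp = runif(n, .05, 1.5))
  lam <- runif(n, 0, 0.95)
  pl <- outer(lam, seq(0, 6, 2), `^`); pl[, 1] <- 1
  feats <- axonsm:::smi_features(th, pl, prot$bvals)
  err <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    m <- matrix(feats[i, ], nrow = length(prot$bvals), byrow = TRUE,
                dimnames = list(as.character(prot$bvals), paste0("s", seq(0, 6, 2))))
    si <- structure(list(sl = m, bvals = prot$bvals, lmax = 6),
                    class = "signal_invariants")
    r <- smi_fit(si, mod)
    err[i, ] <- c(abs(r$kernel$f - th[i, "f"]), abs(r$kernel$Da - th[i, "Da"]),
                  abs(r$p2 - lam[i]^2))
  }
  expect_lt(median(err[, 1]), 0.03)
  expect_lt(median(err[, 2]), 0.15)
  expect_lt(median(err[, 3]), 0.05)
  # delta-FOD sample: p2 estimate near 1
  xi <- kernel_params(0.5, 1.6, 1.8, 0.4)
  sig <- simulate_signal(prot, sh_fit(matrix(c(0, 0, 1), 1), lmax = 6), xi, lmax = 6)
  rd <- smi_fit(sig, mod)
  expect_gt(rd$p2, 0.85)
})

test_that("FOD recovery from the kernel inverts the convolution", {
  prot <- make_protocol()
  xi <- kernel_params(0.55, 1.7, 1.9, 0.45)
  sh <- family_sh(C = 0.9, lambda = 0.75, n0 = c(1, 0, 2) / sqrt(5), lmax = 6)
  sig <- simulate_signal(prot, sh, xi, route = "sh", lmax = 6)
  rec <- fod_from_kernel(sig, xi, lmax = 6)
  expect_equal(unname(rec$coef[rec$index$l > 0]), unname(sh$coef[sh$index$l > 0]),
               tolerance = 1e-4)
  # uniform FOD: recovered anisotropic coefficients vanish (up to the mesh
  # quadrature ripple amplified by the small Kl)
  mesh <- axonsm:::icosphere(4)
  hu <- structure(list(density = rep(1, length(mesh$solid_angle)), mesh = mesh),
                  class = "sph_hist")
  sigu <- simulate_signal(prot, hu, xi, route = "direct")
  recu <- fod_from_kernel(sigu, xi, lmax = 6)
  expect_lt(max(abs(recu$coef[recu$index$l > 0])), 1e-3)
  # chained analysis: recovered invariants fit back to the generative (C, lambda)
  inv <- rot_invariants(rec)
  fit <- fit_expdecay(inv$pl, inv$l)
  expect_equal(fit$C, 0.9, tolerance = 0.02)
  expect_equal(fit$lambda, 0.75, tolerance = 0.02)
})

test_that("sm_fit front-end dispatches and its methods are coherent", {
  prot <- make_protocol()
  truth <- kernel_params(0.5, 1.8, 1.8, 0.9)
  h <- watson_hist(kappa = 8, level = 4)
  sig <- simulate_signal(prot, h, truth, route = "direct")
  fit <- sm_fit(sig, method = "smt")
  expect_s3_class(fit, "sm_fit")
  expect_named(coef(fit), c("f", "Da", "De_par", "De_perp", "fw", "p2"))
  expect_equal(unname(coef(fit)["f"]), 0.5, tolerance = 0.02)
  # p2 from the factored-out l = 2 invariant tracks the Watson value
  expect_equal(fit$p2, reference_fod_invariants("watson", list(kappa = 8), 2),
               tolerance = 0.05)
  pred <- predict(fit)
  expect_length(pred, length(prot$b))
  # SMT models only spherical means: the per-shell mean residual must vanish
  # even though directional residuals carry the FOD anisotropy
  for (bb in prot$bvals)
    expect_lt(abs(mean(residuals(fit)[fit$protocol$b == bb])), 2e-3)
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("SMT", out)))
})
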