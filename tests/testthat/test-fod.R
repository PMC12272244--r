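# FOD representation, invariants, the exponential-decay family, and reference
# FODs.

test_that("SH projection reproduces the delta and uniform limits", {
  # delta bundle along z: pl = 1 for every even degree
  sh <- sh_fit(matrix(c(0, 0, 1), 1), lmax = 8)
  inv <- rot_invariants(sh)
  expect_equal(inv$pl, rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(sh$coef[sh$index$l == 0]), sqrt(4 * pi), tolerance = 1e-12)
  # m != 0 coefficients vanish for an axially symmetric FOD along z
  expect_lt(max(abs(sh$coef[sh$index$m != 0])), 1e-12)

  # uniform density: all invariants vanish
  mesh <- axonsm:::icosphere(3)
  hu <- structure(list(density = rep(1, length(mesh$solid_angle)), mesh = mesh),
                  class = "sph_hist")
  invu <- rot_invariants(sh_fit(hu, lmax = 8))
  expect_lt(max(invu$pl), 1e-4) # face-centroid quadrature ripple

})

test_that("invariants of axially symmetric FODs equal |<Pl>| from quadrature", {
  for (kappa in c(2, 4, 16)) {
    h <- watson_hist(kappa, n0 = c(1, 2, 2) / 3, level = 5)
    inv <- rot_invariants(sh_fit(h, lmax = 8))
    oracle <- reference_fod_invariants("watson", list(kappa = kappa), inv$l)
    expect_lt(max(abs(inv$pl - oracle)), 1e-4)
  }
})

test_that("theta_p2 formula evaluates the printed limits and values", {
  expect_equal(theta_from_p2(1), 0)
  expect_equal(theta_from_p2(0), 54.7356, tolerance = 1e-4)
  expect_equal(theta_from_p2(0.7), acos(sqrt(0.8)) * 180 / pi, tolerance = 1e-10)
  expect_error(theta_from_p2(1.2))
})

test_that("log-linear fit recovers exact exponential-decay invariants", {
  l <- seq(2, 12, 2)
  fit <- fit_expdecay(0.9 * 0.8^l, l)
  expect_equal(fit$C, 0.9, tolerance = 1e-12)
  expect_equal(fit$lambda, 0.8, tolerance = 1e-12)
  fit1 <- fit_expdecay(rep(1, 4), seq(2, 8, 2))
  expect_equal(c(fit1$C, fit1$lambda), c(1, 1), tolerance = 1e-12)
  expect_error(fit_expdecay(c(0, -1), c(2, 4)))
})

test_that("family density resums to invariants C lambda^l (quadrature, 1e-6)", {
  grid <- expand.grid(C = c(0.25, 0.6, 1), lambda = c(0.3, 0.6, 0.8, 0.9))
  for (i in seq_len(nrow(grid))) {
    C <- grid$C[i]; lam <- grid$lambda[i]
    for (l in seq(2, 16, 2)) {
      pl <- axonsm:::legendre_mean(function(t) family_eval(C, lam, t), l)
      expect_equal(pl, C * lam^l, tolerance = 1e-6)
    }
    # normalization
    expect_equal(axonsm:::legendre_mean(function(t) family_eval(C, lam, t), 0), 1,
                 tolerance = 1e-10)
  }
  # degenerate members are uniform
  expect_equal(family_eval(0, 0.7, c(-1, 0, 1)), rep(1, 3))
  expect_equal(family_eval(0.8, 0, c(-1, 0, 1)), rep(1, 3))
})

test_that("non-negativity domain matches the grid oracle and equator bound", {
  expect_true(family_domain(0, 0.5))
  expect_true(family_domain(1, 0.8))
  expect_false(family_domain(1.5, 0.8))
  expect_true(family_domain(1, 0.999))
  # boundary equals the analytic equator bound
  for (lam in c(0.3, 0.6, 0.8)) {
    analytic <- 1 / (1 - (1 - lam^2) * (1 + lam^2)^(-1.5))
    expect_equal(family_cmax(lam), analytic, tolerance = 1e-6)
    # brute-force check just inside/outside the boundary
    tg <- seq(-1, 1, length.out = 4001)
    expect_gte(min(family_eval(0.999 * analytic, lam, tg)), -1e-9)
    expect_lt(min(family_eval(1.01 * analytic, lam, tg)), 0)
  }
})

test_that("round trip: family samples -> SH fit -> invariant decay recovers (C, lambda)", {
  sh <- family_sh(C = 0.9, lambda = 0.8, n0 = c(1, 1, 3) / sqrt(11), lmax = 16)
  inv <- rot_invariants(sh)
  fit <- fit_expdecay(inv$pl, inv$l)
  expect_equal(fit$C, 0.9, tolerance = 0.01)
  expect_equal(fit$lambda, 0.8, tolerance = 0.01)
})

test_that("Watson invariants behave at the limits and monotonically in kappa", {
  expect_lt(reference_fod_invariants("watson", list(kappa = 0), 2), 1e-10)
  expect_gt(reference_fod_invariants("watson", list(kappa = 1e6), 2), 0.999)
  p2s <- vapply(c(0.5, 1, 2, 4, 8, 16, 64), function(k)
    reference_fod_invariants("watson", list(kappa = k), 2), 0)
  expect_true(all(diff(p2s) > 0))
  expect_true(all(p2s > 0 & p2s < 1))
})

test_that("Watson and Poisson invariants are not exponential in l (family discriminant)", {
  # at matched p2, a pure exponential family misses the Watson p4..p8 by > 5%
  p2w <- reference_fod_invariants("watson", list(kappa = 4), 2)
  plw <- reference_fod_invariants("watson", list(kappa = 4), c(4, 6, 8))
  lam_matched <- sqrt(p2w)
  rel <- abs(lam_matched^c(4, 6, 8) / plw - 1)
  expect_gt(max(rel), 0.05)
  # Poisson kernel at matched p2 likewise disagrees with Watson higher orders
  rel_poisson <- abs(reference_fod_invariants("poisson", list(lambda = sqrt(p2w)),
                                              c(4, 6, 8)) / plw - 1)
  expect_gt(max(rel_poisson), 0.05)
})

test_that("SH CSV round trip preserves coefficients", {
  sh <- family_sh(0.8, 0.7, n0 = c(0, 1, 1) / sqrt(2), lmax = 6)
  path <- tempfile(fileext = ".csv")
  write_sh_csv(sh, path)
  back <- read_sh_csv(path)
  expect_equal(back$coef, sh$coef, tolerance = 1e-12)
  expect_equal(back$lmax, sh$lmax)
})

test_that("lobe segmentation isolates bundles and preserves mass ratios", {
  set.seed(42)
  d1 <- sample_directions("watson", list(kappa = 16, n0 = c(0, 0, 1)), 2e4)
  d2 <- sample_directions("watson", list(kappa = 16, n0 = c(1, 0, 0)), 2e4)
  # single bundle: one lobe, per-lobe invariants equal the global invariants
  h1 <- spherical_histogram(d1, level = 4)
  single <- lobe_invariants(h1)
  expect_length(single, 1)
  glob <- rot_invariants(sh_fit(h1, 8))
  expect_equal(single[[1]]$pl, glob$pl, tolerance = 0.02)
  single_theta <- single[[1]]$theta_p2
  # two orthogonal equal bundles: two lobes, each near the single-bundle theta
  mix <- lobe_invariants(spherical_histogram(rbind(d1, d2), level = 4))
  expect_length(mix, 2)
  expect_equal(sapply(mix, `[[`, "mass"), c(0.5, 0.5), tolerance = 0.05)
  for (lb in mix) expect_lt(abs(lb$theta_p2 - single_theta), 3)
  # 2:1 mass split
  l21 <- lobe_invariants(spherical_histogram(rbind(d1, d2[seq_len(1e4), ]), level = 4))
  expect_length(l21, 2)
  expect_equal(sort(sapply(l21, `[[`, "mass")), c(1 / 3, 2 / 3), tolerance = 0.05)
  # isotropic: no peak above the floor, single lobe
  hu <- spherical_histogram(axonsm:::runif_sphere(2e4), level = 3)
  expect_length(lobe_invariants(hu), 1)
})
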