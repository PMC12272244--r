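# Morphometry pipeline: alignment/trim/smoothing, dispersion, volume
# fractions, per-axon profiles, and the Da prediction.

test_that("preprocessing aligns, trims, and low-passes skeletons", {
  # oblique straight axon: all tangents become z after alignment
  ax <- straight_axon(c(1, 1, 1) / sqrt(3), length = 12)
  pr <- preprocess_skeleton(ax)
  tg <- axonsm:::axon_tangents(pr)
  expect_equal(as.numeric(tg$tangents[, 3]), rep(1, nrow(tg$tangents)), tolerance = 1e-9)
  # 1 um trimmed from each end
  expect_equal(axon_arc_length(pr), 10, tolerance = 0.05)
  # the diffusion length sets the kernel width: sigma = sqrt(2 D t)/2
  expect_equal(sqrt(2 * 2 * 11.5) / 2, 3.391165, tolerance = 1e-6)
  # short-wavelength undulation is smoothed away (theta_u -> 0)
  axu <- generate_axon(c(0, 0, 1), 30, undulation = list(amplitude = 0.5, wavelength = 2),
                       step_dz = 0.05,
                       phases = list(undulation = 0.4, undulation_azimuth = 1, beading = 0))
  theta_sm <- axon_profile(preprocess_skeleton(axu))$theta_u
  theta_raw <- axon_profile(preprocess_skeleton(axu, smooth = FALSE))$theta_u
  expect_lt(theta_sm, 4)
  expect_gt(theta_raw, 30)
  # too-short axons are rejected with a message
  expect_message(out <- preprocess_skeleton(straight_axon(length = 3.5)), "rejected")
  expect_null(out)
})

test_that("population dispersion angle matches hand values", {
  # all segments at 20 degrees from the axis
  a <- 20 * pi / 180
  t20 <- cbind(sin(a) * cos(seq(0, 2 * pi, length.out = 37)[-37]),
               sin(a) * sin(seq(0, 2 * pi, length.out = 37)[-37]), cos(a))
  expect_equal(population_dispersion(t20), 20, tolerance = 1e-9)
  # half at 0, half at 90 degrees: <cos^2> = 1/2 -> 45 degrees
  mix <- rbind(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE),
               matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE))
  expect_equal(population_dispersion(mix), 45, tolerance = 1e-9)
  # isotropic limit: acos(1/sqrt(3)) ~ 54.74 degrees
  di <- axonsm:::runif_sphere(2e5)
  expect_equal(population_dispersion(di), 54.7356, tolerance = 0.3)
  # invariant under global rotation
  R <- axonsm:::rotation_from_z(c(2, -1, 2) / 3)
  d <- sample_directions("watson", list(kappa = 8, n0 = c(0, 0, 1)), 5e3, seed = 1)
  expect_equal(population_dispersion(d %*% t(R), main_direction = as.numeric(R %*% c(0, 0, 1))),
               population_dispersion(d, main_direction = c(0, 0, 1)), tolerance = 1e-9)
})

test_that("volume fraction follows the analytic cylinder geometry", {
  expect_equal(volume_fractions(list(), box = c(10, 10, 10)), 0)
  ax <- straight_axon(c(0, 0, 1), length = 10, diameter = 2, g_ratio = 0.8)
  ax$points <- sweep(ax$points, 2, c(5, 5, 5), `+`)
  f1 <- volume_fractions(list(ax), box = c(10, 10, 10))
  expect_equal(f1, 0.0320, tolerance = 1e-3)
  # doubling all areas approximately doubles f in the dilute regime
  ax2 <- ax; ax2$area <- 2 * ax$area
  ax2$myelin_thickness <- (sqrt(ax2$area / pi)) * (1 / 0.8 - 1)
  f2 <- volume_fractions(list(ax2), box = c(10, 10, 10))
  expect_equal(f2 / f1, 2, tolerance = 0.05)
})

test_that("axon profile recovers tortuosity and undulation oracles", {
  # constant area: tortuosity exactly 1
  pr <- axon_profile(straight_axon(length = 12, diameter = 1.2))
  expect_equal(pr$tortuosity, 1, tolerance = 1e-12)
  expect_equal(pr$mean_diameter, 1.2, tolerance = 1e-12)
  # sinusoidal beading: quadrature oracle 1/sqrt(1 - a^2)
  for (a in c(0.25, 0.5, 0.75)) {
    axb <- generate_axon(c(0, 0, 1), 60, beading = list(amplitude = a, wavelength = 6),
                         step_dz = 0.005,
                         phases = list(undulation = 0, undulation_azimuth = 0, beading = 0))
    expect_equal(axon_profile(axb)$tortuosity, 1 / sqrt(1 - a^2), tolerance = 1e-3)
  }
  # undulation: dense numeric average of 1/(1 + slope^2) over whole periods
  u <- 0.5; wl <- 10; k <- 2 * pi / wl
  axu <- generate_axon(c(0, 0, 1), 50, undulation = list(amplitude = u, wavelength = wl),
                       step_dz = 0.005,
                       phases = list(undulation = 0, undulation_azimuth = 0, beading = 0))
  z <- seq(0, 50, 5e-4)
  slope <- u * k * cos(k * z)
  arc <- sqrt(1 + slope^2)
  oracle <- sum(arc / (1 + slope^2)) / sum(arc)
  prof <- axon_profile(axu)
  expect_equal(prof$cos2_undulation, oracle, tolerance = 1e-3)
  expect_equal(prof$theta_u, acos(sqrt(oracle)) * 180 / pi, tolerance = 0.1)
  expect_error(axon_profile(axon_geometry(matrix(0:5, 2, 3), c(1, -1))))
})

test_that("predicted Da aggregates tortuosity and undulation with volume weights", {
  mk <- function(tort, cos2, vol) list(tortuosity = tort, cos2_undulation = cos2,
                                       volume = vol, mean_diameter = 1, diameter = 1,
                                       theta_u = 0)
  expect_equal(predict_Da(list(mk(1, 1, 2)), D0 = 2), 2)
  expect_equal(predict_Da(list(mk(1.1547, 1, 1)), D0 = 2), 2 / 1.1547, tolerance = 1e-4)
  expect_equal(predict_Da(list(mk(1, 1, 1), mk(1.1547, 1, 1)), D0 = 2),
               0.5 * 2 + 0.5 * 2 / 1.1547, tolerance = 1e-4)
  # Jensen: tortuosity >= 1 ensures Da_pred <= D0 on generated populations
  pop <- generate_population(population_spec(n_axons = 40, seed = 3))
  expect_true(all(pop$ground_truth$tortuosity >= 1))
  expect_lte(pop$ground_truth$Da_pred, 2)
})

test_that("tangent FOD is normalized, antipodal, and peaks where the bundle points", {
  pop <- generate_population(population_spec(
    n_axons = 120, undulation = list(amplitude = 0, wavelength = 8),
    beading = list(amplitude = 0, wavelength = 6), seed = 9))
  h <- tangent_fod(pop, level = 3)
  w <- h$density * h$mesh$solid_angle / (4 * pi)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(h$density, h$density[h$mesh$opposite], tolerance = 1e-12)
  peak_dir <- h$mesh$centroids[which.max(h$density), ]
  expect_gt(abs(sum(peak_dir * c(0, 0, 1))), 0.9)
  expect_error(tangent_fod(list()))
})

test_that("morphometry matches generator ground truth on a synthetic population", {
  pop <- generate_population(population_spec(n_axons = 250, seed = 21))
  pm <- population_metrics(pop, level = 3, lmax = 6)
  gt <- pop$ground_truth
  expect_equal(pm$f, gt$f, tolerance = 1e-12) # same volumes, same formula
  # theta from the pipeline (smoothed tangents) within MC/smoothing error
  expect_lt(abs(pm$theta - gt$theta), 3)
  expect_lt(abs(pm$theta_p2 - pm$theta), 2)
  # tortuosity unaffected by centerline smoothing (areas untouched)
  expect_equal(pm$mean_tortuosity, unname(gt$mean_tortuosity), tolerance = 0.02)
  expect_lte(pm$Da_pred, 2)
  expect_gte(pm$mean_cos2_undulation, gt$mean_cos2_undulation - 0.01)
})
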