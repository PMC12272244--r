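# Synthetic populations of myelinated-axon skeletons with known ground truth:
# the electron-microscopy-segmentation surrogate. An axon is an ordered 3d
# centerline (um) with per-point cross-sectional area (um^2) and myelin
# thickness (um). Undulation is a single transverse sinusoid per axon (random
# phase and azimuth); beading is a sinusoidal area modulation
# A(z) = Abar (1 + a sin(2 pi z / wavelength + phase)), which admits the
# closed-form axial tortuosity 1/sqrt(1 - a^2) used as an oracle.

#' Construct an axon geometry object
#'
#' @param points n x 3 matrix of ordered centerline coordinates (um)
#' @param area per-point cross-sectional area (um^2), all > 0
#' @param myelin_thickness per-point myelin sheath thickness (um)
#' @return object of class `axon`
#' @export
axon_geometry <- function(points, area, myelin_thickness = rep(0, length(area))) {
  points <- rbind(points)
  stopifnot(nrow(points) >= 2, ncol(points) == 3,
            length(area) == nrow(points), all(area > 0),
            length(myelin_thickness) == nrow(points), all(myelin_thickness >= 0))
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0)) stop("consecutive centerline points must be distinct")
  structure(list(points = points, area = area, myelin_thickness = myelin_thickness),
            class = "axon")
}

#' @export
print.axon <- function(x, ...) {
  cat(sprintf("Axon skeleton: %d points, arc length %.2f um, mean area %.3f um^2\n",
              nrow(x$points), axon_arc_length(x), mean(x$area)))
  invisible(x)
}

#' Arc length of an axon centerline
#' @param axon an `axon`
#' @return length in um
#' @export
axon_arc_length <- function(axon) sum(sqrt(rowSums(diff(axon$points)^2)))

# per-segment tangents and lengths
axon_tangents <- function(axon) {
  seg <- diff(axon$points)
  len <- sqrt(rowSums(seg^2))
  list(tangents = seg / len, lengths = len)
}

# intra-axonal and myelin volume by arc-length quadrature (trapezoid in A)
axon_volumes <- function(axon) {
  len <- sqrt(rowSums(diff(axon$points)^2))
  a_mid <- (axon$area[-1] + axon$area[-length(axon$area)]) / 2
  r <- sqrt(axon$area / pi)
  a_out <- pi * (r + axon$myelin_thickness)^2
  ao_mid <- (a_out[-1] + a_out[-length(a_out)]) / 2
  c(intra = sum(a_mid * len), myelin = sum((ao_mid - a_mid) * len))
}

#' Population specification for the synthetic-axon generator
#'
#' Defaults emulate a healthy-white-matter corpus-callosum-like sample at a
#' scale small enough for routine analysis: a 20 um box, moderate Watson
#' dispersion (kappa = 16, dispersion angle near 20 degrees), light undulation
#' and beading, ~0.8 um inner diameter and g-ratio 0.7.
#'
#' @param n_axons number of axons
#' @param box 3 extents in um
#' @param fod_model `"watson"`, `"expdecay_family"`, or `"delta"`
#' @param fod_params model parameters: `kappa` or `C`,`lambda`, plus main
#'   direction `n0` (unit vector)
#' @param undulation list `amplitude` (um), `wavelength` (um)
#' @param beading list `amplitude` (relative, in \[0,1)), `wavelength` (um)
#' @param diameter list `mean` (um, inner), `sd` (um)
#' @param g_ratio inner/outer radius ratio in (0, 1]
#' @param length_um generated axon length before clipping (>= 12 by default so
#'   the 10-um morphometry filter passes)
#' @param step_dz centerline sampling step (um)
#' @param seed master seed; per-axon streams are derived deterministically
#' @return object of class `population_spec`
#' @export
population_spec <- function(n_axons = 300,
                            box = c(20, 20, 20),
                            fod_model = c("watson", "expdecay_family", "delta"),
                            fod_params = list(kappa = 16, n0 = c(0, 0, 1)),
                            undulation = list(amplitude = 0.3, wavelength = 8),
                            beading = list(amplitude = 0.2, wavelength = 6),
                            diameter = list(mean = 0.8, sd = 0.15),
                            g_ratio = 0.7,
                            length_um = 24,
                            step_dz = 0.25,
                            seed = 1L) {
  fod_model <- match.arg(fod_model)
  stopifnot(n_axons >= 1, all(box > 0),
            undulation$wavelength > 0, beading$wavelength > 0,
            beading$amplitude >= 0, beading$amplitude < 1,
            diameter$mean > 0, g_ratio > 0, g_ratio <= 1,
            step_dz > 0, length_um >= 2 * step_dz)
  fod_params$n0 <- fod_params$n0 / sqrt(sum(fod_params$n0^2))
  structure(list(n_axons = as.integer(n_axons), box = box, fod_model = fod_model,
                 fod_params = fod_params, undulation = undulation, beading = beading,
                 diameter = diameter, g_ratio = g_ratio, length_um = length_um,
                 step_dz = step_dz, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample unit directions from an FOD model
#'
#' Watson by numerical inverse-CDF in `t = cos(theta)`; the exponential-decay
#' family by rejection sampling against its closed-form density (parameters must
#' lie in the non-negativity domain); `"delta"` returns `+/- n0`.
#'
#' @param model `"watson"`, `"expdecay_family"`, or `"delta"`
#' @param params list with `kappa` or (`C`, `lambda`) and main direction `n0`
#' @param n number of directions
#' @param seed optional seed
#' @return n x 3 matrix of unit vectors (antipodally symmetric ensemble)
#' @export
sample_directions <- function(model, params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n0 <- params$n0
  if (is.null(n0)) n0 <- c(0, 0, 1)
  n0 <- n0 / sqrt(sum(n0^2))
  t_abs <- switch(model,
    delta = rep(1, n),
    watson = {
      kappa <- params$kappa
      stopifnot(kappa >= 0)
      if (kappa >= 1e6) rep(1, n) else {
        tg <- seq(0, 1, length.out = 4097)
        dens <- exp(kappa * (tg^2 - 1))
        cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2)
        cdf <- c(0, cdf / cdf[length(cdf)])
        stats::approx(cdf, tg, xout = stats::runif(n), ties = "ordered")$y
      }
    },
    expdecay_family = {
      C <- params$C; lambda <- params$lambda
      if (!family_domain(C, lambda))
        stop("(C, lambda) outside the non-negativity domain")
      tg <- seq(-1, 1, length.out = 2001)
      M <- max(family_eval(C, lambda, tg)) * 1.001
      out <- numeric(0)
      while (length(out) < n) {
        m <- max(2L * (n - length(out)), 64L)
        tt <- stats::runif(m, -1, 1)
        acc <- stats::runif(m) * M < family_eval(C, lambda, tt)
        out <- c(out, tt[acc])
      }
      out[seq_len(n)]
    },
    stop("unknown FOD model: ", model))
  t <- if (model == "expdecay_family") t_abs else t_abs * sample(c(-1, 1), n, replace = TRUE)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - t^2))
  local <- cbind(st * cos(phi), st * sin(phi), t)
  local %*% t(rotation_from_z(n0))
}

#' Generate one synthetic axon
#'
#' Straight line along `direction` plus a transverse sinusoid (amplitude `u`,
#' wavelength `l`, given phase/azimuth), sinusoidal area modulation, and a
#' myelin annulus from the g-ratio.
#'
#' @param direction unit vector
#' @param length axial length (um), >= 2 * step_dz
#' @param undulation list `amplitude`, `wavelength` (um)
#' @param beading list `amplitude` in \[0,1), `wavelength` (um)
#' @param diameter inner diameter (um)
#' @param g_ratio inner/outer radius ratio
#' @param step_dz axial sampling step (um)
#' @param phases optional list `undulation`, `undulation_azimuth`, `beading`
#'   (radians); drawn uniformly when missing
#' @return an `axon`
#' @export
generate_axon <- function(direction, length, undulation = list(amplitude = 0, wavelength = 10),
                          beading = list(amplitude = 0, wavelength = 10),
                          diameter = 1, g_ratio = 0.7, step_dz = 0.25,
                          phases = NULL) {
  stopifnot(length >= 2 * step_dz)
  if (beading$amplitude >= 1) stop("beading amplitude must be < 1 (area would vanish)")
  if (is.null(phases))
    phases <- list(undulation = stats::runif(1, 0, 2 * pi),
                   undulation_azimuth = stats::runif(1, 0, 2 * pi),
                   beading = stats::runif(1, 0, 2 * pi))
  z <- seq(-length / 2, length / 2, by = step_dz)
  u <- undulation$amplitude
  disp <- if (u > 0) u * sin(2 * pi * z / undulation$wavelength + phases$undulation) else rep(0, length(z))
  local <- cbind(disp * cos(phases$undulation_azimuth),
                 disp * sin(phases$undulation_azimuth), z)
  abar <- pi * (diameter / 2)^2
  area <- abar * (1 + beading$amplitude * sin(2 * pi * z / beading$wavelength + phases$beading))
  r <- sqrt(area / pi)
  myelin <- r * (1 / g_ratio - 1)
  R <- rotation_from_z(direction / sqrt(sum(direction^2)))
  axon_geometry(local %*% t(R), area, myelin)
}

# keep the longest contiguous run of centerline points inside the box
clip_axon_to_box <- function(axon, box) {
  inside <- axon$points[, 1] >= 0 & axon$points[, 1] <= box[1] &
    axon$points[, 2] >= 0 & axon$points[, 2] <= box[2] &
    axon$points[, 3] >= 0 & axon$points[, 3] <= box[3]
  if (!any(inside)) return(NULL)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  if (length(idx) < 2) return(NULL)
  axon_geometry(axon$points[idx, , drop = FALSE], axon$area[idx],
                axon$myelin_thickness[idx])
}

#' Generate a synthetic axon population
#'
#' Samples directions from the spec's FOD model, builds each axon with its own
#' deterministic random stream, places it uniformly in the box, clips it to the
#' box, and records the generative ground truth.
#'
#' @param spec a [population_spec()]
#' @return object of class `population`: list with `axons`, `box`, `spec`,
#'   `ground_truth` (see [ground_truth()])
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  dirs <- sample_directions(spec$fod_model, spec$fod_params, spec$n_axons)
  axon_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_axons)
  axons <- vector("list", spec$n_axons)
  for (i in seq_len(spec$n_axons)) {
    set.seed(axon_seeds[i])
    d <- max(0.2, stats::rnorm(1, spec$diameter$mean, spec$diameter$sd))
    ax <- generate_axon(dirs[i, ], spec$length_um, spec$undulation, spec$beading,
                        diameter = d, g_ratio = spec$g_ratio, step_dz = spec$step_dz)
    center <- stats::runif(3) * spec$box
    ax$points <- sweep(ax$points, 2, center, `+`)
    axons[[i]] <- clip_axon_to_box(ax, spec$box)
  }
  keep <- !vapply(axons, is.null, TRUE)
  pop <- structure(list(axons = axons[keep], box = spec$box, spec = spec,
                        generative_directions = dirs[keep, , drop = FALSE]),
                   class = "population")
  pop$ground_truth <- ground_truth(pop)
  pop
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Synthetic axon population: %d axons in a %.0f x %.0f x %.0f um box\n",
              length(x$axons), x$box[1], x$box[2], x$box[3]))
  gt <- x$ground_truth
  cat(sprintf("  ground truth: theta = %.2f deg, f = %.4f, mean tortuosity = %.4f, Da_pred = %.4f um^2/ms\n",
              gt$theta, gt$f, gt$mean_tortuosity, gt$Da_pred))
  invisible(x)
}

#' Generative ground truth of a synthetic population
#'
#' All quantities come from the generative geometry, independent of the
#' morphometry pipeline under test: dispersion angle
#' `theta = acos(sqrt(<cos^2 theta_i>))` from length-weighted generative
#' tangents; `f` = intra-axonal volume / (box volume - myelin volume); per-axon
#' axial tortuosity `<Abar/A(z)>`; undulation `<cos^2 theta_u>` about each
#' axon's own mean direction; and the predicted intra-axonal diffusivity
#' `Da_pred = sum_k w_k (D0 / tortuosity_k) <cos^2 theta_u>_k` with
#' volume weights `w_k`.
#'
#' @param population a `population`
#' @param D0 axoplasmic free diffusivity (um^2/ms)
#' @return list of ground-truth metrics
#' @export
ground_truth <- function(population, D0 = 2.0) {
  axons <- population$axons
  if (length(axons) == 0) stop("population is empty")
  n0 <- population$spec$fod_params$n0
  vols <- t(vapply(axons, axon_volumes, c(intra = 0, myelin = 0)))
  vbox <- prod(population$box)
  if (sum(vols[, "myelin"]) >= vbox) stop("myelin volume exceeds box volume")
  f <- sum(vols[, "intra"]) / (vbox - sum(vols[, "myelin"]))
  # dispersion from generative tangents (length-weighted)
  num <- 0; den <- 0
  per_axon <- vapply(axons, function(ax) {
    tg <- axon_tangents(ax)
    ct2 <- (tg$tangents %*% n0)^2
    num <<- num + sum(tg$lengths * ct2)
    den <<- den + sum(tg$lengths)
    # own-axis undulation dispersion
    md <- colSums(tg$tangents * tg$lengths)
    md <- md / sqrt(sum(md^2))
    cu2 <- sum(tg$lengths * (tg$tangents %*% md)^2) / sum(tg$lengths)
    # tortuosity from generative areas (arc-weighted)
    len <- tg$lengths
    a_mid <- (ax$area[-1] + ax$area[-length(ax$area)]) / 2
    abar <- sum(a_mid * len) / sum(len)
    tort <- sum(abar / a_mid * len) / sum(len)
    c(tort, cu2)
  }, c(0, 0))
  theta <- acos(sqrt(num / den)) * 180 / pi
  w <- vols[, "intra"] / sum(vols[, "intra"])
  da_pred <- sum(w * (D0 / per_axon[1, ]) * per_axon[2, ])
  list(theta = theta, f = f,
       tortuosity = per_axon[1, ], cos2_undulation = per_axon[2, ],
       mean_tortuosity = sum(w * per_axon[1, ]),
       mean_cos2_undulation = sum(w * per_axon[2, ]),
       Da_pred = da_pred, D0 = D0,
       fod_model = population$spec$fod_model,
       fod_params = population$spec$fod_params)
}
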