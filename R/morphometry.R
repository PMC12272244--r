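# Skeleton morphometry: the histology arm of the validation. Computes, from
# axon skeletons, the dispersion angle, tangent FOD, intra-axonal volume
# fraction (myelin excluded), equivalent diameter, axial tortuosity, undulation
# dispersion, and the predicted intra-axonal diffusivity.

#' Align, trim and smooth an axon skeleton
#'
#' The axon main direction (length-weighted mean tangent) is rotated onto the
#' z-axis; 1 um of arc length is removed at each end (oblique end-slices); the
#' centerline is then convolved with a Gaussian of standard deviation
#' `sigma = L/2 = sqrt(2 D t)/2` along arc length (mirror boundary), emulating
#' the coarse-graining of diffusion over the diffusion time `t`.
#'
#' @param axon an `axon`
#' @param t diffusion time (ms), typically the inter-pulse duration Delta
#' @param D coarse-graining diffusivity (um^2/ms)
#' @param trim arc length removed at each end (um)
#' @param smooth apply the Gaussian smoothing
#' @return the processed `axon` with attribute `main_direction` (original
#'   frame), or `NULL` (with a message) if shorter than 2 um after trimming
#' @export
preprocess_skeleton <- function(axon, t = 11.5, D = 2.0, trim = 1, smooth = TRUE) {
  stopifnot(inherits(axon, "axon"), t > 0, D > 0)
  tg <- axon_tangents(axon)
  md <- colSums(tg$tangents * tg$lengths)
  md <- md / sqrt(sum(md^2))
  R <- rotation_from_z(md) # z -> md; align with t(R)
  pts <- axon$points %*% R # coordinates in the aligned frame
  s <- c(0, cumsum(tg$lengths))
  total <- s[length(s)]
  if (total - 2 * trim < 2) {
    message("axon rejected: arc length ", round(total, 2),
            " um leaves < 2 um after trimming")
    return(NULL)
  }
  keep <- resample_arc(pts, axon$area, axon$myelin_thickness, s, trim, total - trim)
  pts <- keep$points; area <- keep$area; myl <- keep$myelin; s <- keep$s
  if (smooth) {
    sigma <- sqrt(2 * D * t) / 2
    pts <- gaussian_smooth_arc(pts, s, sigma)
  }
  out <- axon_geometry(pts, area, myl)
  attr(out, "main_direction") <- md
  attr(out, "rotation") <- R
  out
}

# crop a polyline to arc interval [s0, s1], interpolating the cut points
resample_arc <- function(pts, area, myelin, s, s0, s1) {
  interp_at <- function(x) {
    i <- findInterval(x, s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(s) - 1L)
    w <- (x - s[i]) / (s[i + 1] - s[i])
    list(p = pts[i, ] * (1 - w) + pts[i + 1, ] * w,
         a = area[i] * (1 - w) + area[i + 1] * w,
         m = myelin[i] * (1 - w) + myelin[i + 1] * w)
  }
  eps <- 1e-9 * max(s1 - s0, 1)
  inner <- which(s > s0 + eps & s < s1 - eps)
  lo <- interp_at(s0); hi <- interp_at(s1)
  list(points = rbind(lo$p, pts[inner, , drop = FALSE], hi$p),
       area = c(lo$a, area[inner], hi$a),
       myelin = c(lo$m, myelin[inner], hi$m),
       s = c(s0, s[inner], s1) - s0)
}

# Gaussian kernel smoothing of coordinates along arc length; reflecting
# boundary via odd (point-reflection) extension about each endpoint, which
# leaves straight centerlines exactly invariant.
gaussian_smooth_arc <- function(pts, s, sigma) {
  if (sigma <= 0) return(pts)
  n <- nrow(pts)
  s_ext <- c(2 * s[1] - s[n:2], s, 2 * s[n] - s[(n - 1):1])
  p_ext <- rbind(sweep(-pts[n:2, , drop = FALSE], 2, 2 * pts[1, ], `+`),
                 pts,
                 sweep(-pts[(n - 1):1, , drop = FALSE], 2, 2 * pts[n, ], `+`))
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    w <- stats::dnorm(s_ext, s[i], sigma)
    w <- w / sum(w)
    out[i, ] <- colSums(p_ext * w)
  }
  out
}

#' Population dispersion angle
#'
#' `theta = acos(sqrt(<cos^2 theta_i>))` with the average over (length-weighted)
#' tangent segments and `theta_i` the angle of each segment to the population
#' main direction; in degrees.
#'
#' @param tangents n x 3 unit tangent matrix
#' @param lengths segment lengths (weights); zero-length segments are dropped
#' @param main_direction population main direction (unit vector)
#' @return dispersion angle in degrees
#' @export
population_dispersion <- function(tangents, lengths = rep(1, nrow(tangents)),
                                  main_direction = c(0, 0, 1)) {
  tangents <- rbind(tangents)
  stopifnot(nrow(tangents) >= 1, length(lengths) == nrow(tangents))
  keep <- lengths > 0
  if (!any(keep)) stop("no segments with positive length")
  ct2 <- (tangents[keep, , drop = FALSE] %*% main_direction)^2
  acos(sqrt(sum(lengths[keep] * ct2) / sum(lengths[keep]))) * 180 / pi
}

#' Principal direction of a set of tangents
#'
#' Leading eigenvector of the length-weighted tangent outer-product sum.
#'
#' @param tangents n x 3 unit tangents
#' @param lengths weights
#' @return unit vector
#' @export
principal_direction <- function(tangents, lengths = rep(1, nrow(tangents))) {
  tangents <- rbind(tangents)
  M <- t(tangents) %*% (tangents * lengths)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (v[3] < 0) v <- -v
  v
}

# gather tangents from axons; optionally preprocess (align/trim/smooth) first.
collect_tangents <- function(axons, t, D, smooth, min_length) {
  tl <- list(); ll <- list()
  for (ax in axons) {
    if (axon_arc_length(ax) <= min_length) next
    pr <- preprocess_skeleton(ax, t = t, D = D, smooth = smooth)
    if (is.null(pr)) next
    tg <- axon_tangents(pr)
    # rotate tangents back to the original frame
    R <- attr(pr, "rotation")
    tl[[length(tl) + 1L]] <- tg$tangents %*% t(R)
    ll[[length(ll) + 1L]] <- tg$lengths
  }
  if (length(tl) == 0) stop("no axons pass the length filter")
  list(tangents = do.call(rbind, tl), lengths = unlist(ll))
}

#' Tangent-based fiber orientation distribution of a population
#'
#' Tangent vectors of the (length-filtered, smoothed) skeletons are binned on a
#' triangulated sphere into an antipodally symmetric, dOmega/4pi-normalized
#' histogram.
#'
#' @param population a `population`, or a list of `axon` objects
#' @param t,D coarse-graining diffusion time (ms) and diffusivity (um^2/ms)
#' @param level icosphere subdivision level
#' @param min_length axons at or below this arc length (um) are excluded
#' @param length_weight weight tangents by segment length
#' @param smooth apply the diffusion-length Gaussian smoothing
#' @return a `sph_hist`
#' @export
tangent_fod <- function(population, t = 11.5, D = 2.0, level = 4,
                        min_length = 10, length_weight = TRUE, smooth = TRUE) {
  axons <- if (inherits(population, "population")) population$axons else population
  if (length(axons) == 0) stop("empty population")
  ct <- collect_tangents(axons, t, D, smooth, min_length)
  w <- if (length_weight) ct$lengths else rep(1, nrow(ct$tangents))
  spherical_histogram(ct$tangents, weights = w, level = level)
}

#' Intra-axonal volume fraction of a sample
#'
#' `f = V_intra / (V_box - V_myelin)`: myelin is excluded from the reference
#' volume because its short T2 makes it invisible to the dMRI acquisition. All
#' axons contribute, with no length filter.
#'
#' @param population a `population` or list of `axon`s
#' @param box 3 extents (um); defaults to the population box
#' @return intra-axonal water fraction in \[0, 1\]
#' @export
volume_fractions <- function(population, box = NULL) {
  axons <- if (inherits(population, "population")) population$axons else population
  if (is.null(box) && inherits(population, "population")) box <- population$box
  stopifnot(!is.null(box), all(box > 0))
  if (length(axons) == 0) return(0)
  vols <- t(vapply(axons, axon_volumes, c(intra = 0, myelin = 0)))
  vbox <- prod(box)
  if (sum(vols[, "myelin"]) >= vbox) stop("myelin volume exceeds box volume")
  f <- sum(vols[, "intra"]) / (vbox - sum(vols[, "myelin"]))
  if (f > 1) stop("intra-axonal volume exceeds available volume (overlapping axons?)")
  f
}

#' Per-axon morphometric profile
#'
#' For an aligned axon: equivalent diameter `2 r(z) = 2 sqrt(A(z)/pi)`, the
#' axial tortuosity `<Abar / A(z)>` (Fick-Jacobs), and the undulation dispersion
#' `theta_u` / `<cos^2 theta_u>` from the axon's own tangents about the z-axis.
#'
#' @param axon an aligned `axon` (output of [preprocess_skeleton()])
#' @return list with `diameter`, `mean_diameter`, `tortuosity`,
#'   `cos2_undulation`, `theta_u` (degrees), `volume`
#' @export
axon_profile <- function(axon) {
  stopifnot(inherits(axon, "axon"))
  if (any(axon$area <= 0)) stop("non-positive cross-sectional area")
  tg <- axon_tangents(axon)
  len <- tg$lengths
  a_mid <- (axon$area[-1] + axon$area[-length(axon$area)]) / 2
  abar <- sum(a_mid * len) / sum(len)
  tort <- sum(abar / a_mid * len) / sum(len)
  cu2 <- sum(len * (tg$tangents[, 3])^2) / sum(len)
  list(diameter = 2 * sqrt(axon$area / pi),
       mean_diameter = sum(2 * sqrt(a_mid / pi) * len) / sum(len),
       tortuosity = tort,
       cos2_undulation = cu2,
       theta_u = acos(sqrt(cu2)) * 180 / pi,
       volume = sum(a_mid * len))
}

#' Predicted intra-axonal diffusivity from morphometry
#'
#' `Da_pred = sum_k w_k (D0 / tortuosity_k) <cos^2 theta_u>_k`, volume-weighted
#' over axons: beading lowers the long-time axial diffusivity by the
#' Fick-Jacobs tortuosity, undulation by the tangent-dispersion factor.
#'
#' @param profiles list of [axon_profile()] results
#' @param D0 axoplasmic free diffusivity (um^2/ms)
#' @return predicted diffusivity (um^2/ms)
#' @export
predict_Da <- function(profiles, D0 = 2.0) {
  stopifnot(length(profiles) >= 1, D0 > 0)
  v <- vapply(profiles, `[[`, 0, "volume")
  w <- v / sum(v)
  sum(w * (D0 / vapply(profiles, `[[`, 0, "tortuosity")) *
        vapply(profiles, `[[`, 0, "cos2_undulation"))
}

#' Full morphometric characterization of a population
#'
#' Runs the histology arm: volume fraction (all axons), then on length-filtered,
#' aligned, trimmed, smoothed skeletons the dispersion angle, tangent FOD and
#' its invariants, diameter, tortuosity, undulation, and predicted Da.
#'
#' @param population a `population` or list of `axon`s
#' @param box sample box extents (um); default from the population
#' @param t,D coarse-graining diffusion time (ms) and diffusivity (um^2/ms)
#' @param D0 axoplasmic free diffusivity for the Da prediction (um^2/ms)
#' @param level icosphere subdivision level for the FOD
#' @param lmax even maximum SH degree
#' @param min_length length filter (um) for all metrics except `f`
#' @return object of class `population_metrics`
#' @export
population_metrics <- function(population, box = NULL, t = 11.5, D = 2.0,
                               D0 = 2.0, level = 4, lmax = 8, min_length = 10) {
  axons <- if (inherits(population, "population")) population$axons else population
  if (is.null(box) && inherits(population, "population")) box <- population$box
  f <- volume_fractions(axons, box)
  profiles <- list(); tl <- list(); ll <- list()
  for (ax in axons) {
    if (axon_arc_length(ax) <= min_length) next
    pr <- preprocess_skeleton(ax, t = t, D = D)
    if (is.null(pr)) next
    profiles[[length(profiles) + 1L]] <- axon_profile(pr)
    tg <- axon_tangents(pr)
    R <- attr(pr, "rotation")
    tl[[length(tl) + 1L]] <- tg$tangents %*% t(R)
    ll[[length(ll) + 1L]] <- tg$lengths
  }
  if (length(profiles) == 0) stop("no axons pass the length filter")
  tangents <- do.call(rbind, tl); lengths <- unlist(ll)
  n0 <- principal_direction(tangents, lengths)
  theta <- population_dispersion(tangents, lengths, n0)
  hist <- spherical_histogram(tangents, weights = lengths, level = level)
  sh <- sh_fit(hist, lmax = lmax)
  inv <- rot_invariants(sh)
  p2 <- min(1, inv$pl[1])
  v <- vapply(profiles, `[[`, 0, "volume")
  w <- v / sum(v)
  structure(list(
    f = f,
    theta = theta,
    theta_p2 = theta_from_p2(p2),
    p2 = p2,
    pl = inv$pl, l = inv$l,
    mean_diameter = sum(w * vapply(profiles, `[[`, 0, "mean_diameter")),
    mean_tortuosity = sum(w * vapply(profiles, `[[`, 0, "tortuosity")),
    mean_cos2_undulation = sum(w * vapply(profiles, `[[`, 0, "cos2_undulation")),
    Da_pred = predict_Da(profiles, D0),
    main_direction = n0,
    n_axons_used = length(profiles),
    n_axons_total = length(axons),
    fod = hist, sh = sh), class = "population_metrics")
}

#' @export
print.population_metrics <- function(x, ...) {
  cat("Population morphometry (", x$n_axons_used, "of", x$n_axons_total, "axons pass the length filter)\n")
  cat(sprintf("  f               = %.4f\n", x$f))
  cat(sprintf("  theta (Eq-like) = %.2f deg,  theta_p2 = %.2f deg (p2 = %.3f)\n",
              x$theta, x$theta_p2, x$p2))
  cat(sprintf("  mean diameter   = %.3f um\n", x$mean_diameter))
  cat(sprintf("  mean tortuosity = %.4f,  <cos^2 theta_u> = %.4f\n",
              x$mean_tortuosity, x$mean_cos2_undulation))
  cat(sprintf("  predicted Da    = %.4f um^2/ms\n", x$Da_pred))
  invisible(x)
}
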