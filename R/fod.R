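# Fiber orientation distributions: spherical histograms, SH decomposition,
# rotational invariants, the exponential-decay FOD family, and the Watson and
# Poisson-kernel reference FODs.

#' Spherical histogram of directions on a triangulated sphere
#'
#' Bins unit vectors onto the faces of a subdivided icosahedron and returns the
#' antipodally symmetrized density `P` normalized so that
#' `sum(P * solid_angle) / 4pi = 1` (density w.r.t. the dOmega/4pi measure).
#'
#' @param dirs n x 3 matrix of unit vectors
#' @param weights optional non-negative weights (e.g. segment lengths)
#' @param level icosphere subdivision level
#' @return object of class `sph_hist` with fields `density`, `mesh`
#' @export
spherical_histogram <- function(dirs, weights = NULL, level = 4) {
  dirs <- rbind(dirs)
  if (nrow(dirs) == 0) stop("no directions to bin")
  mesh <- icosphere(level)
  if (is.null(weights)) weights <- rep(1, nrow(dirs))
  stopifnot(length(weights) == nrow(dirs), all(weights >= 0))
  mass <- numeric(nrow(mesh$centroids))
  # chunked nearest-centroid assignment
  step <- 4096L
  tc <- t(mesh$centroids)
  for (i0 in seq(1L, nrow(dirs), by = step)) {
    i1 <- min(i0 + step - 1L, nrow(dirs))
    d <- dirs[i0:i1, , drop = FALSE]
    bin <- max.col(d %*% tc, ties.method = "first")
    tab <- rowsum(weights[i0:i1], bin)
    mass[as.integer(rownames(tab))] <- mass[as.integer(rownames(tab))] + tab[, 1]
  }
  mass <- (mass + mass[mesh$opposite]) / 2
  mass <- mass / sum(mass)
  dens <- mass / (mesh$solid_angle / (4 * pi))
  structure(list(density = dens, mesh = mesh), class = "sph_hist")
}

#' @export
print.sph_hist <- function(x, ...) {
  cat("Spherical histogram on icosphere level", x$mesh$level,
      sprintf("(%d face bins), max density %.3f\n",
              length(x$density), max(x$density)))
  invisible(x)
}

#' Spherical-harmonic decomposition of an FOD
#'
#' Projects a normalized FOD onto the real even-degree SH basis. The
#' coefficients follow the 4pi-normalized convention in which `p00 = sqrt(4pi)`
#' (so the l = 0 term of the synthesis is the constant 1) and a delta FOD along
#' z has `pl0 = sqrt(4pi (2l+1))`.
#'
#' @param x a `sph_hist`, or an n x 3 matrix of sampled unit directions
#' @param lmax even maximum degree (<= 16)
#' @param weights optional weights when `x` is a matrix of directions
#' @return object of class `sh_coef`: list with `lmax`, `index`, `coef`
#' @export
sh_fit <- function(x, lmax = 8, weights = NULL) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  if (lmax > 16) stop("lmax must be <= 16")
  idx <- sh_index(lmax)
  if (inherits(x, "sph_hist")) {
    Y <- sh_basis(x$mesh$centroids, lmax)
    coef <- as.numeric(t(Y) %*% (x$density * x$mesh$solid_angle))
  } else {
    x <- rbind(x)
    if (is.null(weights)) weights <- rep(1, nrow(x))
    w <- weights / sum(weights)
    Y <- sh_basis(x, lmax)
    coef <- 4 * pi * as.numeric(t(Y) %*% w)
    # enforce antipodal symmetry explicitly (even basis already ignores sign,
    # but average +/- for numerical symmetry of m-components)
    coefm <- 4 * pi * as.numeric(t(sh_basis(-x, lmax)) %*% w)
    coef <- (coef + coefm) / 2
  }
  names(coef) <- paste0("l", idx$l, "m", idx$m)
  structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
}

#' @export
print.sh_coef <- function(x, ...) {
  p <- rot_invariants(x)
  cat("Even-degree SH coefficients, lmax =", x$lmax, "\n")
  cat("rotational invariants:\n")
  print(round(stats::setNames(p$pl, paste0("p", p$l)), 4))
  invisible(x)
}

#' Rotational invariants of an SH-decomposed FOD
#'
#' `pl = sqrt(sum_m plm^2) / Nl` with `Nl = sqrt(4pi (2l+1))`, so `0 <= pl <= 1`
#' with `pl = 1` for a fully aligned bundle and `pl = 0` (l >= 2) for the
#' uniform FOD.
#'
#' @param sh an `sh_coef` object
#' @return list with `l` (even degrees >= 2), `pl`, and `p0 = 1`
#' @export
rot_invariants <- function(sh) {
  stopifnot(inherits(sh, "sh_coef"))
  ls <- seq(2, sh$lmax, by = 2)
  pl <- vapply(ls, function(l) {
    Nl <- sqrt(4 * pi * (2 * l + 1))
    sqrt(sum(sh$coef[sh$index$l == l]^2)) / Nl
  }, 0)
  list(l = ls, pl = pmax(pl, 0), p0 = 1)
}

#' Dispersion angle from the l = 2 invariant
#'
#' `theta_p2 = acos(sqrt((2 p2 + 1) / 3))` in degrees; equals the Eq.-style
#' population dispersion angle exactly for axially symmetric FODs.
#'
#' @param p2 invariant in \[0, 1\]
#' @return angle in degrees
#' @export
theta_from_p2 <- function(p2) {
  if (any(p2 < -1e-12 | p2 > 1 + 1e-12)) stop("p2 must lie in [0, 1]")
  p2 <- pmin(1, pmax(0, p2))
  acos(sqrt((2 * p2 + 1) / 3)) * 180 / pi
}

#' Fit the exponential-decay law to FOD invariants
#'
#' Log-linear least squares of `log(pl)` on `l`, returning `C = exp(intercept)`
#' and `lambda = exp(slope)` of the law `pl = C * lambda^l`.
#'
#' @param pl invariants for the degrees in `l`
#' @param l even degrees (>= 2)
#' @return list with `C`, `lambda`, `r_squared`, `n_used`
#' @export
fit_expdecay <- function(pl, l = seq(2, by = 2, length.out = length(pl))) {
  stopifnot(length(pl) == length(l))
  keep <- is.finite(pl) & pl > 0
  if (sum(keep) < 2) stop("need at least 2 positive invariants")
  fit <- stats::lm.fit(cbind(1, l[keep]), log(pl[keep]))
  r2 <- if (sum(keep) > 2) {
    y <- log(pl[keep]); 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else 1
  list(C = exp(fit$coefficients[[1]]), lambda = exp(fit$coefficients[[2]]),
       r_squared = r2, n_used = sum(keep))
}

#' Evaluate SH coefficients as a band-limited spherical histogram
#'
#' Synthesizes the density `P = 1 + sum plm Ylm` on the bins of a triangulated
#' sphere, renormalized over the bins; useful to feed a band-limited FOD to
#' quadrature-based consumers.
#'
#' @param sh an `sh_coef`
#' @param level icosphere subdivision level
#' @return a `sph_hist`
#' @export
sh_to_hist <- function(sh, level = 4) {
  stopifnot(inherits(sh, "sh_coef"))
  mesh <- icosphere(level)
  coef <- sh$coef
  coef[sh$index$l == 0] <- sqrt(4 * pi)
  dens <- as.numeric(sh_basis(mesh$centroids, sh$lmax) %*% coef)
  dens <- dens / (sum(dens * mesh$solid_angle) / (4 * pi))
  structure(list(density = dens, mesh = mesh), class = "sph_hist")
}

# ---- exponential-decay FOD family ------------------------------------------

# symmetrized Poisson kernel g(t) = (1/2)(1-l2)[(1-2 lam t+l2)^-3/2 + (1+2 lam t+l2)^-3/2]
poisson_pair_kernel <- function(lambda, t) {
  l2 <- lambda^2
  0.5 * (1 - l2) * ((1 - 2 * lambda * t + l2)^(-1.5) + (1 + 2 * lambda * t + l2)^(-1.5))
}

#' Closed-form exponential-decay FOD family
#'
#' Axially symmetric FOD whose even rotational invariants are exactly
#' `pl = C * lambda^l`: the density is the resummation of that series via the
#' Poisson-kernel generating function,
#' `P(t) = (1 - C) + (C/2)(1 - lambda^2) ((1 - 2 lambda t + lambda^2)^{-3/2} +
#'  (1 + 2 lambda t + lambda^2)^{-3/2})`,
#' the potential of two symmetric point sources at `+/- lambda n0` inside the
#' unit sphere. `t = cos` of the angle to the main direction.
#'
#' @param C amplitude parameter (>= 0)
#' @param lambda decay parameter in \[0, 1)
#' @param t cosine(s) of the polar angle
#' @return density values (w.r.t. dOmega/4pi)
#' @export
family_eval <- function(C, lambda, t) {
  stopifnot(C >= 0)
  if (lambda >= 1 || lambda < 0) stop("lambda must lie in [0, 1)")
  (1 - C) + C * poisson_pair_kernel(lambda, t)
}

# minimum over t of the symmetrized Poisson kernel (grid + local refinement)
poisson_pair_min <- function(lambda, n_grid = 1001) {
  tg <- seq(-1, 1, length.out = n_grid)
  g <- poisson_pair_kernel(lambda, tg)
  i <- which.min(g)
  lo <- tg[max(1, i - 2)]; hi <- tg[min(n_grid, i + 2)]
  opt <- stats::optimize(function(t) poisson_pair_kernel(lambda, t), c(lo, hi))
  min(opt$objective, g[i])
}

#' Non-negativity domain of the exponential-decay family
#'
#' A pair `(C, lambda)` is admissible iff `min_t P(t) >= 0`. Because `C` enters
#' linearly, the boundary is `C_max(lambda) = 1 / (1 - min_t g(t))` with `g` the
#' symmetrized Poisson kernel; the minimum sits at the equator, giving the
#' analytic cross-check `C <= 1 / (1 - (1-lambda^2)(1+lambda^2)^{-3/2})`.
#'
#' @param C amplitude
#' @param lambda decay parameter in \[0, 1)
#' @return logical: is the FOD non-negative on the sphere
#' @export
family_domain <- function(C, lambda) {
  stopifnot(length(C) == length(lambda) || length(C) == 1 || length(lambda) == 1)
  mapply(function(C, lambda) {
    if (C < 0 || lambda < 0 || lambda >= 1) return(FALSE)
    gmin <- poisson_pair_min(lambda)
    if (gmin >= 1) return(TRUE)
    C <= 1 / (1 - gmin) + 1e-12
  }, C, lambda)
}

#' Admissibility boundary C_max(lambda) of the exponential-decay family
#'
#' @param lambda decay parameter(s) in \[0, 1)
#' @return maximal admissible `C` for each `lambda`
#' @export
family_cmax <- function(lambda) {
  vapply(lambda, function(l) {
    gmin <- poisson_pair_min(l)
    if (gmin >= 1) Inf else 1 / (1 - gmin)
  }, 0)
}

# ---- reference FODs --------------------------------------------------------

watson_log_norm <- function(kappa) {
  # Z = (1/2) int_{-1}^{1} exp(kappa t^2) dt, computed as exp(kappa) * (1/2) int exp(kappa(t^2-1))
  gl <- pracma::gaussLegendre(256, -1, 1)
  kappa + log(0.5 * sum(gl$w * exp(kappa * (gl$x^2 - 1))))
}

#' Evaluate a reference FOD density
#'
#' Watson: `P(t) = exp(kappa t^2) / Z`, normalized w.r.t. dOmega/4pi.
#' Poisson kernel: symmetrized `(1 - lambda^2) (1 -/+ 2 lambda t + lambda^2)^{-3/2}`
#' average, the `C = 1` member of the exponential-decay family with `pl = lambda^l`.
#'
#' @param model `"watson"` or `"poisson"`
#' @param params list with `kappa` (Watson) or `lambda` (Poisson)
#' @param t cosine(s) of the polar angle
#' @return density values
#' @export
reference_fod_eval <- function(model = c("watson", "poisson"), params, t) {
  model <- match.arg(model)
  if (model == "watson") {
    kappa <- params$kappa
    stopifnot(kappa >= 0, is.finite(kappa))
    exp(kappa * t^2 - watson_log_norm(kappa))
  } else {
    lambda <- params$lambda
    if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
    poisson_pair_kernel(lambda, t)
  }
}

#' Rotational invariants of a reference FOD
#'
#' Watson invariants by 1d Gauss-Legendre quadrature of `<Pl(t)>`; Poisson-kernel
#' invariants are `lambda^l` analytically.
#'
#' @param model `"watson"` or `"poisson"`
#' @param params list with `kappa` or `lambda`
#' @param l even degree(s)
#' @return `pl` values
#' @export
reference_fod_invariants <- function(model = c("watson", "poisson"), params, l) {
  model <- match.arg(model)
  stopifnot(all(l %% 2 == 0))
  if (model == "poisson") return(params$lambda^l)
  vapply(l, function(ll)
    abs(legendre_mean(function(t) reference_fod_eval("watson", params, t), ll)), 0)
}

#' Watson concentration giving a target dispersion angle
#'
#' Solves for `kappa` such that `acos(sqrt(<cos^2 theta>))` under Watson(kappa)
#' equals `theta_deg`.
#'
#' @param theta_deg target dispersion angle in degrees (0, 54.7356)
#' @return concentration parameter `kappa`
#' @export
watson_kappa_for_theta <- function(theta_deg) {
  stopifnot(theta_deg > 0, theta_deg < acos(1 / sqrt(3)) * 180 / pi)
  target <- cos(theta_deg * pi / 180)^2
  gl <- pracma::gaussLegendre(256, -1, 1)
  moment2 <- function(k)
    0.5 * sum(gl$w * reference_fod_eval("watson", list(kappa = k), gl$x) * gl$x^2)
  r <- stats::uniroot(function(logk) moment2(exp(logk)) - target,
                      c(log(1e-3), log(1e4)), tol = 1e-12)
  exp(r$root)
}

# ---- FOD lobe segmentation -------------------------------------------------

#' Segment FOD lobes and compute per-lobe invariants
#'
#' Assigns every histogram bin to its nearest density peak by steepest ascent on
#' the face-adjacency graph, merges antipodal peak pairs (the FOD is even), drops
#' peaks not exceeding the isotropic floor `P = 1`, renormalizes each lobe to
#' unit mass and computes its rotational invariants.
#'
#' @param hist a `sph_hist`
#' @param lmax even maximum degree for per-lobe invariants
#' @param floor isotropic density floor a peak must exceed (default 1.25: the
#'   uniform FOD has density 1, and sampling noise keeps spurious smoothed
#'   peaks below ~1.2 for the histogram sizes in routine use)
#' @return list of lobes, each with `mass`, `direction`, `l`, `pl`, `theta_p2`
#' @export
lobe_invariants <- function(hist, lmax = 8, floor = 1.25) {
  stopifnot(inherits(hist, "sph_hist"))
  Praw <- hist$density; mesh <- hist$mesh
  # watershed on the band-limited density: histogram noise creates spurious
  # local maxima, the smooth SH synthesis does not
  P <- sh_to_hist(sh_fit(hist, lmax = lmax), level = mesh$level)$density
  nf <- length(P)
  ord <- order(P, decreasing = TRUE)
  label <- integer(nf)
  peak_face <- integer(0)
  for (f in ord) {
    nb <- mesh$neighbours[f, ]
    nb <- nb[label[nb] > 0L]
    if (length(nb) == 0L) {
      peak_face <- c(peak_face, f)
      label[f] <- length(peak_face)
    } else {
      label[f] <- label[nb[which.max(P[nb])]]
    }
  }
  # merge antipodal basins (peak with the basin owning its antipodal face)
  parent <- seq_along(peak_face)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_along(peak_face)) {
    j <- label[mesh$opposite[peak_face[k]]]
    a <- find(k); b <- find(j)
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  for (k in seq_along(parent)) parent[k] <- find(k)
  label <- parent[label]
  # merge peaks closer than 20 degrees (split ridges) into the stronger one
  repeat {
    gs <- sort(unique(label))
    if (length(gs) < 2) break
    pk <- t(vapply(gs, function(g) {
      ff <- which(label == g)
      i <- ff[which.max(P[ff])]
      c(mesh$centroids[i, ], P[i])
    }, numeric(4)))
    merged <- FALSE
    for (a in seq_along(gs)) {
      for (b in seq_along(gs)) {
        if (a == b) next
        if (pk[a, 4] <= pk[b, 4] &&
            abs(sum(pk[a, 1:3] * pk[b, 1:3])) > cos(20 * pi / 180)) {
          label[label == gs[a]] <- gs[b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # keep peaks above the isotropic floor
  groups <- sort(unique(label))
  peak_height <- vapply(groups, function(g) max(P[label == g]), 0)
  names(peak_height) <- groups
  keep <- as.integer(names(peak_height)[peak_height > floor])
  if (length(keep) == 0L) {
    label[] <- 1L
    keep <- 1L
  } else if (length(keep) < length(unique(label))) {
    # reassign discarded basins to the nearest surviving peak direction
    kept_dirs <- t(vapply(keep, function(g) {
      ff <- which(label == g); mesh$centroids[ff[which.max(P[ff])], ]
    }, numeric(3)))
    lost <- which(!(label %in% keep))
    if (length(lost)) {
      aff <- max.col(abs(mesh$centroids[lost, , drop = FALSE] %*% t(kept_dirs)))
      label[lost] <- keep[aff]
    }
  }
  lobes <- lapply(sort(unique(label)), function(g) {
    sel <- label == g
    mass <- sum(P[sel] * mesh$solid_angle[sel]) / (4 * pi)
    dens <- P[sel] / mass
    Y <- sh_basis(mesh$centroids[sel, , drop = FALSE], lmax)
    coef <- as.numeric(t(Y) %*% (dens * mesh$solid_angle[sel]))
    idx <- sh_index(lmax)
    names(coef) <- paste0("l", idx$l, "m", idx$m)
    sh <- structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
    inv <- rot_invariants(sh)
    ff <- which(sel)
    list(mass = mass,
         direction = mesh$centroids[ff[which.max(P[sel])], ],
         l = inv$l, pl = inv$pl, theta_p2 = theta_from_p2(min(1, inv$pl[1])))
  })
  lobes[order(vapply(lobes, `[[`, 0, "mass"), decreasing = TRUE)]
}
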