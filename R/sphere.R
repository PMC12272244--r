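# Spherical basis functions and triangulated-sphere quadrature.
#
# Conventions (stated once, used everywhere):
#   * real spherical harmonics Ylm, orthonormal under the canonical measure dOmega,
#     Condon-Shortley phase inside the associated Legendre functions;
#   * coefficient ordering: even l ascending, m from -l to +l within each degree;
#   * the FOD P(n) is a density w.r.t. dn = dOmega/4pi, so integral dn P = 1 and
#     plm = 4pi * integral dn Ylm P = integral dOmega Ylm P.

#' Legendre polynomial P_l(x)
#'
#' Bonnet three-term recurrence; vectorized in `x`.
#'
#' @param l non-negative integer degree
#' @param x numeric vector in \[-1, 1\]
#' @return numeric vector of P_l(x)
#' @export
legendre_p <- function(l, x) {
  stopifnot(length(l) == 1L, l >= 0, l == round(l))
  if (l == 0) return(rep(1, length(x)))
  if (l == 1) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:l) {
    p <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

# Normalized associated Legendre \bar P_l^m(x) = sqrt((2l+1)/(4pi) (l-m)!/(l+m)!) P_l^m(x),
# m >= 0, Condon-Shortley included. Stable diagonal-then-upward recurrence.
norm_assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    for (k in 1:m) pmm <- -pmm * sqrt((2 * k + 1) / (2 * k)) * somx2
  }
  if (l == m) return(pmm)
  # \bar P_{m+1,m} = x sqrt(2m+3) \bar P_mm
  pmmp1 <- x * sqrt(2 * m + 3) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    a <- sqrt((4 * ll^2 - 1) / (ll^2 - m^2))
    b <- sqrt(((ll - 1)^2 - m^2) / (4 * (ll - 1)^2 - 1))
    pll <- a * (x * pmmp1 - b * pmm)
    pmm <- pmmp1; pmmp1 <- pll
  }
  pll
}

#' Index table for an even-degree real SH basis
#'
#' @param lmax even maximum degree
#' @param include_l0 include the l = 0 row
#' @return data.frame with columns `l`, `m`
#' @export
sh_index <- function(lmax, include_l0 = TRUE) {
  stopifnot(lmax %% 2 == 0, lmax >= 0)
  ls <- seq(0, lmax, by = 2)
  if (!include_l0) ls <- setdiff(ls, 0)
  out <- do.call(rbind, lapply(ls, function(l) data.frame(l = l, m = seq(-l, l))))
  if (is.null(out)) out <- data.frame(l = integer(), m = integer())
  rownames(out) <- NULL
  out
}

#' Real spherical-harmonic design matrix
#'
#' Evaluates the real orthonormal SH basis (even degrees only, antipodal symmetry)
#' at unit directions.
#'
#' @param dirs n x 3 matrix of unit vectors
#' @param lmax even maximum degree
#' @param include_l0 include the Y00 column
#' @return n x ncoef matrix; columns ordered per [sh_index()]
#' @export
sh_basis <- function(dirs, lmax, include_l0 = TRUE) {
  dirs <- rbind(dirs)
  idx <- sh_index(lmax, include_l0)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  out <- matrix(0, nrow(dirs), nrow(idx))
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]; am <- abs(m)
    plm <- norm_assoc_legendre(l, am, ct)
    out[, j] <- if (m == 0) plm
    else if (m > 0) sqrt(2) * plm * cos(am * phi)
    else sqrt(2) * plm * sin(am * phi)
  }
  colnames(out) <- paste0("l", idx$l, "m", idx$m)
  out
}

#' Gauss-Legendre projection of an axially symmetric density onto P_l
#'
#' Computes < P_l(t) > under a density `f(t)` on t = cos(theta) in \[-1, 1\]
#' that is normalized w.r.t. dn = dOmega/4pi (so (1/2) integral f dt = 1).
#'
#' @param f vectorized density function of t
#' @param l Legendre degree
#' @param n quadrature order
#' @return scalar < P_l >
#' @export
legendre_mean <- function(f, l, n = 256) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  0.5 * sum(gl$w * f(gl$x) * legendre_p(l, gl$x))
}

# ---- icosphere -------------------------------------------------------------

.axonsm_cache <- new.env(parent = emptyenv())

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_icosphere <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  key <- function(a, b) paste(min(a, b), max(a, b))
  mid <- new.env(parent = emptyenv())
  nv <- nrow(v)
  vlist <- list(v)
  getmid <- function(a, b) {
    k <- key(a, b)
    if (!is.null(mid[[k]])) return(mid[[k]])
    p <- v[a, ] + v[b, ]
    p <- p / sqrt(sum(p^2))
    nv <<- nv + 1L
    vlist[[length(vlist) + 1L]] <<- p
    mid[[k]] <- nv
    nv
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    nf[(i - 1) * 4 + 1, ] <- c(a, ab, ca)
    nf[(i - 1) * 4 + 2, ] <- c(b, bc, ab)
    nf[(i - 1) * 4 + 3, ] <- c(c, ca, bc)
    nf[(i - 1) * 4 + 4, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, c(list(v[0, , drop = FALSE]), vlist)), faces = nf)
}

# solid angle of a spherical triangle (Van Oosterom & Strackee)
tri_solid_angle <- function(v1, v2, v3) {
  num <- abs(det(rbind(v1, v2, v3)))
  den <- 1 + sum(v1 * v2) + sum(v2 * v3) + sum(v3 * v1)
  2 * atan2(num, den)
}

#' Triangulated unit sphere (subdivided icosahedron)
#'
#' Face bins carry unit centroid directions, exact solid angles, the index of the
#' antipodal face, and face adjacency (shared-edge neighbours) used by the FOD
#' lobe segmentation.
#'
#' @param level subdivision level (0 = icosahedron); level 4 has 5120 faces
#' @return list with `vertices`, `faces`, `centroids`, `solid_angle`, `opposite`,
#'   `neighbours`
#' @export
icosphere <- function(level = 4) {
  key <- paste0("icosphere_", level)
  if (!is.null(.axonsm_cache[[key]])) return(.axonsm_cache[[key]])
  mesh <- icosahedron()
  if (level > 0) for (i in seq_len(level)) mesh <- subdivide_icosphere(mesh)
  v <- mesh$vertices; f <- mesh$faces
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  cen <- cen / sqrt(rowSums(cen^2))
  sa <- vapply(seq_len(nrow(f)), function(i)
    tri_solid_angle(v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0)
  # antipodal face: nearest centroid to -centroid (icosahedron is centrally symmetric)
  opp <- max.col(-cen %*% t(cen))
  # adjacency via shared edges
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(
    data.frame(k = ek(f[, 1], f[, 2]), face = seq_len(nrow(f))),
    data.frame(k = ek(f[, 2], f[, 3]), face = seq_len(nrow(f))),
    data.frame(k = ek(f[, 3], f[, 1]), face = seq_len(nrow(f))))
  sp <- split(edges$face, edges$k)
  nb <- matrix(0L, nrow(f), 3)
  cnt <- integer(nrow(f))
  for (pr in sp) {
    if (length(pr) == 2) {
      cnt[pr[1]] <- cnt[pr[1]] + 1L; nb[pr[1], cnt[pr[1]]] <- pr[2]
      cnt[pr[2]] <- cnt[pr[2]] + 1L; nb[pr[2], cnt[pr[2]]] <- pr[1]
    }
  }
  out <- list(vertices = v, faces = f, centroids = cen, solid_angle = sa,
              opposite = opp, neighbours = nb, level = level)
  .axonsm_cache[[key]] <- out
  out
}

#' Rotation matrix taking the z-axis onto a unit vector
#'
#' @param n0 target unit vector
#' @return 3 x 3 rotation matrix `R` with `R %*% c(0,0,1) = n0`
#' @export
rotation_from_z <- function(n0) {
  n0 <- n0 / sqrt(sum(n0^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n0[3] - z[3] * n0[2], z[3] * n0[1] - z[1] * n0[3], z[1] * n0[2] - z[2] * n0[1])
  c_ <- sum(z * n0)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# uniform random unit vectors
runif_sphere <- function(n) {
  z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
  m <- cbind(x, y, z)
  m / sqrt(rowSums(m^2))
}
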