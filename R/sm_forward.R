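# Standard Model forward signal generation: the fascicle kernel, its Legendre
# projections, spherical convolution with an FOD (SH-product and direct
# quadrature routes), per-shell signal rotational invariants, the multi-shell
# PGSE protocol, and Rician/Gaussian noise.

#' SM kernel parameters
#'
#' Compartment fractions are fractions of the total dMRI-visible water:
#' intra-axonal `f`, free water `fw`, extra-axonal `1 - f - fw`, so the kernel
#' is 1 at b = 0. Diffusivities in um^2/ms.
#'
#' @param f intra-axonal fraction in \[0, 1\]
#' @param Da intra-axonal (stick) diffusivity
#' @param depar extra-axonal parallel diffusivity De_par
#' @param deperp extra-axonal perpendicular diffusivity De_perp
#' @param fw free-water fraction (f + fw <= 1)
#' @param Dw free-water diffusivity (room temperature ~2)
#' @return object of class `kernel_params`
#' @export
kernel_params <- function(f, Da, depar, deperp, fw = 0, Dw = 2.0) {
  stopifnot(f >= 0, f <= 1, fw >= 0, f + fw <= 1 + 1e-12,
            Da >= 0, depar >= 0, deperp >= 0, Dw >= 0)
  structure(list(f = f, Da = Da, depar = depar, deperp = deperp, fw = fw, Dw = Dw),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("SM kernel: f = %.3f, Da = %.3f, De_par = %.3f, De_perp = %.3f, fw = %.3f (um^2/ms)\n",
              x$f, x$Da, x$depar, x$deperp, x$fw))
  invisible(x)
}

#' Evaluate the SM fascicle kernel
#'
#' `K(b, x) = f exp(-b Da x^2) + (1 - f - fw) exp(-b De_perp - b (De_par - De_perp) x^2)
#'  + fw exp(-b Dw)` with `x` the cosine between the measurement direction and
#' the fascicle axis.
#'
#' @param params a [kernel_params()]
#' @param b diffusion weighting (ms/um^2)
#' @param x cosine(s) in \[-1, 1\]
#' @return kernel values
#' @export
kernel_eval <- function(params, b, x) {
  with(params,
       f * exp(-b * Da * x^2) +
         (1 - f - fw) * exp(-b * deperp - b * (depar - deperp) * x^2) +
         fw * exp(-b * Dw))
}

#' Legendre projections of the SM kernel
#'
#' `Kl(b) = int_0^1 K(b, x) Pl(x) dx` by fixed-order Gauss-Legendre quadrature.
#' With the even orthonormal-SH conventions used throughout, the signal
#' harmonics factorize as `slm = plm Kl`.
#'
#' @param params a [kernel_params()]
#' @param b diffusion weighting (ms/um^2); vectorized
#' @param l even Legendre degree
#' @param order quadrature order
#' @return `Kl` value per `b`
#' @export
kernel_projection <- function(params, b, l, order = 96) {
  stopifnot(l %% 2 == 0)
  key <- paste0("gl01_", order)
  if (is.null(.axonsm_cache[[key]]))
    .axonsm_cache[[key]] <- pracma::gaussLegendre(order, 0, 1)
  gl <- .axonsm_cache[[key]]
  pl <- legendre_p(l, gl$x)
  vapply(b, function(bb) sum(gl$w * kernel_eval(params, bb, gl$x) * pl), 0)
}

#' Multi-shell PGSE acquisition protocol
#'
#' Defaults reproduce the study design: 3 shells at b = 2, 3, 4 ms/um^2 with 43
#' directions each (electrostatic repulsion on the half-sphere, seeded) plus 3
#' b = 0 volumes; pulse length delta = 6 ms, inter-pulse duration Delta = 11.5
#' ms (timing is metadata for Gaussian compartments).
#'
#' @param bvals shell b-values (ms/um^2)
#' @param n_dir directions per shell
#' @param n_b0 number of b = 0 measurements
#' @param delta,Delta gradient pulse length and separation (ms)
#' @param seed seed for the direction design
#' @return object of class `protocol` with per-volume `b` and `dirs`
#' @export
make_protocol <- function(bvals = c(2, 3, 4), n_dir = 43, n_b0 = 3,
                          delta = 6, Delta = 11.5, seed = 42) {
  stopifnot(all(bvals > 0), n_dir >= 6, n_b0 >= 0)
  dirs <- electrostatic_directions(n_dir, seed = seed)
  b <- c(rep(0, n_b0), rep(bvals, each = n_dir))
  dmat <- rbind(matrix(rep(c(0, 0, 1), n_b0), ncol = 3, byrow = TRUE),
                do.call(rbind, replicate(length(bvals), dirs, simplify = FALSE)))
  structure(list(b = b, dirs = dmat, bvals = bvals, n_dir = n_dir, n_b0 = n_b0,
                 delta = delta, Delta = Delta),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("PGSE protocol: %d shells (b = %s ms/um^2) x %d directions + %d b0 = %d volumes; delta = %g ms, Delta = %g ms\n",
              length(x$bvals), paste(x$bvals, collapse = ", "), x$n_dir, x$n_b0,
              length(x$b), x$delta, x$Delta))
  invisible(x)
}

#' Electrostatic-repulsion direction set on the half-sphere
#'
#' Minimizes the Coulomb energy of antipodal point pairs by projected gradient
#' descent from a seeded random start.
#'
#' @param n number of directions
#' @param n_iter iterations
#' @param seed seed for the initial configuration
#' @return n x 3 matrix of unit vectors with non-negative z
#' @export
electrostatic_directions <- function(n, n_iter = 400, seed = 42) {
  set.seed(seed)
  p <- runif_sphere(n)
  p[p[, 3] < 0, ] <- -p[p[, 3] < 0, , drop = FALSE]
  step <- 0.05
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(-p, 2, p[i, ], `+`) # p_i - p_j
      d2 <- sweep(p, 2, p[i, ], `+`)  # p_i - (-p_j)
      r1 <- rowSums(d1^2); r1[i] <- Inf
      r2 <- rowSums(d2^2)
      force[i, ] <- colSums(d1 / r1^1.5) + colSums(d2 / r2^1.5)
    }
    p <- p + step * force / max(sqrt(rowSums(force^2)))
    p <- p / sqrt(rowSums(p^2))
    step <- step * 0.99
  }
  p[p[, 3] < 0, ] <- -p[p[, 3] < 0, , drop = FALSE]
  p
}

# FOD SH coefficients from any accepted FOD representation
fod_to_sh <- function(fod, lmax) {
  if (inherits(fod, "sh_coef")) {
    if (fod$lmax >= lmax) {
      keep <- fod$index$l <= lmax
      structure(list(lmax = lmax, index = fod$index[keep, ], coef = fod$coef[keep]),
                class = "sh_coef")
    } else {
      idx <- sh_index(lmax)
      coef <- stats::setNames(numeric(nrow(idx)), paste0("l", idx$l, "m", idx$m))
      coef[names(fod$coef)] <- fod$coef
      structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
    }
  } else if (inherits(fod, "sph_hist")) {
    sh_fit(fod, lmax = lmax)
  } else stop("fod must be an sh_coef or sph_hist")
}

#' Simulate the SM signal for a protocol
#'
#' Spherical convolution of a normalized FOD with the SM kernel. Two routes:
#' `"sh"` multiplies FOD harmonics by the kernel projections (`slm = plm Kl`)
#' and synthesizes at the protocol directions; `"direct"` integrates
#' `int dn P(n) K(b, u.n)` over the histogram bins. Both agree to ~1e-5 for
#' band-limited FODs.
#'
#' @param protocol a [make_protocol()] object
#' @param fod an `sh_coef` or `sph_hist` (normalized)
#' @param params a [kernel_params()]
#' @param route `"sh"` or `"direct"`
#' @param lmax SH band limit for the `"sh"` route
#' @return object of class `signal_set`: `values` (S/S0 per volume), `protocol`
#' @export
simulate_signal <- function(protocol, fod, params, route = c("sh", "direct"), lmax = 8) {
  route <- match.arg(route)
  stopifnot(inherits(protocol, "protocol"), inherits(params, "kernel_params"))
  if (route == "direct") {
    if (!inherits(fod, "sph_hist")) stop("direct route requires a sph_hist FOD")
    mesh <- fod$mesh
    w <- fod$density * mesh$solid_angle / (4 * pi)
    if (abs(sum(w) - 1) > 1e-3) stop("FOD is not normalized")
    w <- w / sum(w)
    vals <- vapply(seq_along(protocol$b), function(i) {
      x <- mesh$centroids %*% protocol$dirs[i, ]
      sum(w * kernel_eval(params, protocol$b[i], x))
    }, 0)
  } else {
    sh <- fod_to_sh(fod, lmax)
    # include l = 0 with p00 = sqrt(4 pi) so the isotropic term is K0
    coef <- sh$coef
    coef[sh$index$l == 0] <- sqrt(4 * pi)
    ls <- sort(unique(sh$index$l))
    vals <- numeric(length(protocol$b))
    for (bb in unique(protocol$b)) {
      sel <- protocol$b == bb
      Y <- sh_basis(protocol$dirs[sel, , drop = FALSE], sh$lmax)
      kl <- stats::setNames(vapply(ls, function(l) kernel_projection(params, bb, l), 0),
                            ls)
      slm <- coef * kl[as.character(sh$index$l)]
      vals[sel] <- as.numeric(Y %*% slm)
    }
  }
  structure(list(values = vals, protocol = protocol), class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("Signal set: %d volumes, S/S0 in [%.4f, %.4f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Per-shell rotational invariants of a signal set
#'
#' Least-squares SH fit of the signal on each shell (even degrees up to
#' `lmax`), then `sl = sqrt(sum_m slm^2) / Nl`. On noiseless SM data the
#' factorization `sl = pl Kl` holds per degree and shell; `s0` is the spherical
#' mean.
#'
#' @param signals a `signal_set` or numeric vector of S/S0 values
#' @param protocol protocol (required if `signals` is a vector)
#' @param lmax even maximum degree (reduced with a warning if a shell has too
#'   few directions)
#' @return object of class `signal_invariants`: matrix `sl` (shell x degree,
#'   including l = 0), `bvals`
#' @export
signal_invariants <- function(signals, protocol = NULL, lmax = 6) {
  if (inherits(signals, "signal_set")) {
    protocol <- signals$protocol
    signals <- signals$values
  }
  stopifnot(inherits(protocol, "protocol"), lmax %% 2 == 0)
  out <- list()
  for (bb in protocol$bvals) {
    sel <- protocol$b == bb
    nd <- sum(sel)
    lm <- lmax
    while ((lm / 2 + 1) * (lm + 1) > nd && lm > 0) {
      lm <- lm - 2
      warning("shell b = ", bb, ": too few directions, reducing lmax to ", lm)
    }
    Y <- sh_basis(protocol$dirs[sel, , drop = FALSE], lm)
    slm <- stats::lm.fit(Y, signals[sel])$coefficients
    idx <- sh_index(lm)
    sl <- vapply(seq(0, lm, 2), function(l)
      sqrt(sum(slm[idx$l == l]^2)) / sqrt(4 * pi * (2 * l + 1)), 0)
    out[[as.character(bb)]] <- stats::setNames(sl, paste0("s", seq(0, lm, 2)))
  }
  ls <- seq(0, lmax, 2)
  mat <- do.call(rbind, lapply(out, function(v) v[paste0("s", ls)]))
  colnames(mat) <- paste0("s", ls)
  rownames(mat) <- names(out)
  structure(list(sl = mat, bvals = protocol$bvals, lmax = lmax),
            class = "signal_invariants")
}

#' @export
print.signal_invariants <- function(x, ...) {
  cat("Per-shell signal rotational invariants (S/S0 units):\n")
  print(round(x$sl, 5))
  invisible(x)
}

#' Spherical mean signal per shell
#'
#' Average of S/S0 over the (uniform) direction set of each shell; the spherical
#' mean factors out the FOD entirely and depends only on the kernel.
#'
#' @param signals a `signal_set` or numeric vector
#' @param protocol protocol if `signals` is a vector
#' @return named vector of per-shell means
#' @export
spherical_mean <- function(signals, protocol = NULL) {
  if (inherits(signals, "signal_set")) {
    protocol <- signals$protocol
    signals <- signals$values
  }
  stats::setNames(
    vapply(protocol$bvals, function(bb) mean(signals[protocol$b == bb]), 0),
    protocol$bvals)
}

#' Add measurement noise to a signal set
#'
#' Rician: `|S + n1 + i n2|` with independent Gaussian parts of standard
#' deviation `1/SNR` (SNR defined at S0 = 1); Gaussian: `S + n1`.
#'
#' @param signals a `signal_set`
#' @param snr signal-to-noise ratio at b = 0; `Inf` returns the input
#' @param model `"rician"` or `"gaussian"`
#' @param seed optional seed
#' @return a `signal_set` with noisy values
#' @export
add_noise <- function(signals, snr, model = c("rician", "gaussian"), seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(signals, "signal_set"), snr > 0)
  if (!is.finite(snr)) return(signals)
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  n <- length(signals$values)
  signals$values <- if (model == "gaussian") {
    signals$values + stats::rnorm(n, 0, sigma)
  } else {
    sqrt((signals$values + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  signals
}
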