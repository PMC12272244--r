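# The four Standard Model estimators (WMTI, NODDI, SMT, SMI), the DKI fit that
# feeds WMTI, and FOD recovery from a fitted kernel. All estimators are exposed
# through the sm_fit() front-end in sm_fit.R.

# ---- DKI -------------------------------------------------------------------

# unique symmetric tensor components and their multiplicities
.d2_idx <- cbind(c(1, 2, 3, 1, 1, 2), c(1, 2, 3, 2, 3, 3))
.d2_mult <- c(1, 1, 1, 2, 2, 2)
.w4_idx <- rbind(
  c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
  c(1, 1, 1, 2), c(1, 1, 1, 3), c(2, 2, 2, 1), c(2, 2, 2, 3), c(3, 3, 3, 1), c(3, 3, 3, 2),
  c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
  c(1, 1, 2, 3), c(2, 2, 1, 3), c(3, 3, 1, 2))
.w4_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

dki_design <- function(b, dirs) {
  n <- length(b)
  X2 <- matrix(0, n, 6)
  for (j in 1:6)
    X2[, j] <- .d2_mult[j] * dirs[, .d2_idx[j, 1]] * dirs[, .d2_idx[j, 2]]
  X4 <- matrix(0, n, 15)
  for (j in 1:15)
    X4[, j] <- .w4_mult[j] * dirs[, .w4_idx[j, 1]] * dirs[, .w4_idx[j, 2]] *
      dirs[, .w4_idx[j, 3]] * dirs[, .w4_idx[j, 4]]
  cbind(1, -b * X2, (b^2 / 6) * X4)
}

#' Fit the diffusion and kurtosis tensors
#'
#' Weighted linear least squares on the cumulant expansion of the log-signal up
#' to b^2 (two-pass: OLS, then weights equal to the squared predicted signal).
#' The kurtosis tensor W is scaled by the squared mean diffusivity in the usual
#' convention.
#'
#' @param signals a `signal_set` or numeric vector of S/S0
#' @param protocol protocol if `signals` is a vector
#' @return object of class `dki_fit`: `D` (3 x 3), `W` (15-vector, see
#'   `w4_index`), `S0`, `md`
#' @export
fit_dki <- function(signals, protocol = NULL) {
  if (inherits(signals, "signal_set")) {
    protocol <- signals$protocol
    signals <- signals$values
  }
  stopifnot(length(unique(protocol$bvals)) >= 2)
  X <- dki_design(protocol$b, protocol$dirs)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient DKI design")
  y <- log(pmax(signals, 1e-12))
  beta <- stats::lm.fit(X, y)$coefficients
  for (pass in 1:2) {
    w <- exp(2 * as.numeric(X %*% beta))
    beta <- stats::lm.fit(X * sqrt(w), y * sqrt(w))$coefficients
  }
  D <- matrix(0, 3, 3)
  for (j in 1:6) {
    D[.d2_idx[j, 1], .d2_idx[j, 2]] <- beta[1 + j]
    D[.d2_idx[j, 2], .d2_idx[j, 1]] <- beta[1 + j]
  }
  md <- mean(diag(D))
  W <- beta[8:22] / md^2
  structure(list(D = D, W = W, S0 = exp(beta[1]), md = md), class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  ev <- eigen(x$D, symmetric = TRUE)$values
  cat(sprintf("DKI fit: MD = %.4f um^2/ms, eigenvalues = (%.3f, %.3f, %.3f)\n",
              x$md, ev[1], ev[2], ev[3]))
  invisible(x)
}

# apparent diffusivity and kurtosis along directions (n x 3)
dki_adc <- function(fit, dirs) rowSums((dirs %*% fit$D) * dirs)
dki_akc <- function(fit, dirs) {
  wu <- numeric(nrow(dirs))
  for (j in 1:15)
    wu <- wu + .w4_mult[j] * fit$W[j] * dirs[, .w4_idx[j, 1]] * dirs[, .w4_idx[j, 2]] *
      dirs[, .w4_idx[j, 3]] * dirs[, .w4_idx[j, 4]]
  fit$md^2 * wu / dki_adc(fit, dirs)^2
}

# ---- WMTI ------------------------------------------------------------------

# fit a 3x3 symmetric tensor to a quadratic form sampled on directions
fit_quadratic_form <- function(dirs, values) {
  X <- matrix(0, nrow(dirs), 6)
  for (j in 1:6)
    X[, j] <- .d2_mult[j] * dirs[, .d2_idx[j, 1]] * dirs[, .d2_idx[j, 2]]
  beta <- stats::lm.fit(X, values)$coefficients
  M <- matrix(0, 3, 3)
  for (j in 1:6) {
    M[.d2_idx[j, 1], .d2_idx[j, 2]] <- beta[j]
    M[.d2_idx[j, 2], .d2_idx[j, 1]] <- beta[j]
  }
  M
}

#' White matter tract integrity (WMTI) estimator
#'
#' Closed-form SM parameters from the diffusion and kurtosis tensors, valid for
#' nearly aligned fibers: the axonal water fraction is
#' `f = Kmax / (Kmax + 3)` at the direction of maximal kurtosis, and the intra-
#' and extra-axonal tensors follow the two-compartment branch formulas
#' `D_intra(u) = D(u) (1 - sqrt(K(u) (1-f) / (3 f)))` (the branch enforcing
#' `Da <= De_par`) and `D_extra(u) = D(u) (1 + sqrt(K(u) f / (3 (1-f))))`.
#' `p2` is derived from the intra-axonal tensor eigenvalues as
#' `p2^2 = (3/2) (1/Da^2) sum_i (lambda_i - Da/3)^2`.
#'
#' @param dki a `dki_fit`
#' @param n_dirs directions used to locate Kmax and sample the branch formulas
#' @return list with `kernel` ([kernel_params()]), `p2`, `lambda_intra`,
#'   `valid`, `diagnostics`
#' @export
wmti <- function(dki, n_dirs = 256) {
  stopifnot(inherits(dki, "dki_fit"))
  dirs <- electrostatic_directions(n_dirs, n_iter = 150, seed = 7)
  K <- dki_akc(dki, dirs)
  i0 <- which.max(K)
  # refine the kurtosis maximum on the sphere
  obj <- function(ang) {
    u <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    -dki_akc(dki, rbind(u))
  }
  a0 <- c(acos(dirs[i0, 3]), atan2(dirs[i0, 2], dirs[i0, 1]))
  op <- stats::optim(a0, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 500))
  kmax <- max(-op$value, K[i0])
  valid <- TRUE
  if (!is.finite(kmax) || kmax <= 0) { kmax <- max(kmax, 0); valid <- FALSE }
  f <- kmax / (kmax + 3)
  Du <- dki_adc(dki, dirs)
  Ku <- pmax(K, 0)
  disc_i <- Ku * (1 - f) / (3 * f)
  disc_e <- Ku * f / (3 * (1 - f))
  Dai_u <- Du * (1 - sqrt(disc_i))
  Dae_u <- Du * (1 + sqrt(disc_e))
  if (any(!is.finite(Dai_u)) || any(!is.finite(Dae_u))) valid <- FALSE
  Ti <- fit_quadratic_form(dirs, Dai_u)
  Te <- fit_quadratic_form(dirs, Dae_u)
  la <- sort(eigen(Ti, symmetric = TRUE)$values, decreasing = TRUE)
  le <- sort(eigen(Te, symmetric = TRUE)$values, decreasing = TRUE)
  Da <- sum(la)
  if (Da <= 0) { valid <- FALSE; Da <- max(Da, 1e-6) }
  p2 <- sqrt(pmax(0, 1.5 * sum((la - Da / 3)^2) / Da^2))
  kern <- kernel_params(f = min(max(f, 0), 1), Da = max(Da, 0),
                        depar = max(le[1], 0),
                        deperp = max(mean(le[2:3]), 0), fw = 0)
  if (kern$Da > kern$depar + 1e-9) valid <- FALSE
  list(kernel = kern, p2 = min(p2, 1), lambda_intra = la, valid = valid,
       diagnostics = list(kmax = kmax))
}

# ---- NODDI -----------------------------------------------------------------

# Watson invariants pl for l = 0..lmax (even), quadrature
watson_pl <- function(kappa, lmax) {
  ls <- seq(0, lmax, 2)
  vapply(ls, function(l)
    if (l == 0) 1 else
      abs(legendre_mean(function(t) reference_fod_eval("watson", list(kappa = kappa), t), l)),
    0)
}

# spline interpolants of Watson pl over log-kappa, cached (fast path for fits)
watson_pl_interp <- function(lmax) {
  key <- paste0("watson_pl_", lmax)
  if (is.null(.axonsm_cache[[key]])) {
    lk <- seq(log(1e-3), log(1e4), length.out = 160)
    tab <- t(vapply(exp(lk), watson_pl, numeric(lmax / 2 + 1), lmax = lmax))
    ls <- seq(0, lmax, 2)
    .axonsm_cache[[key]] <- lapply(seq_along(ls), function(j)
      stats::splinefun(lk, tab[, j], method = "monoH.FC"))
  }
  .axonsm_cache[[key]]
}

watson_pl_fast <- function(kappa, lmax) {
  fns <- watson_pl_interp(lmax)
  lk <- min(max(log(kappa), log(1e-3)), log(1e4))
  pmin(1, pmax(0, vapply(fns, function(f) f(lk), 0)))
}

noddi_kernel <- function(f, fw, dpar = 0.6, Dw = 2.0) {
  kernel_params(f = f * (1 - fw), Da = dpar, depar = dpar,
                deperp = dpar * (1 - f), fw = fw, Dw = Dw)
}

#' NODDI estimator
#'
#' Watson-FOD model with fixed axial diffusivities `Da = De_par = 0.6` um^2/ms
#' (ex vivo), tortuosity constraint `De_perp = De_par (1 - f)`, and an estimated
#' free-water fraction. Fitted by Gaussian maximum likelihood on the per-shell
#' signal rotational invariants `sl(b) = pl(kappa) Kl(b)` (l <= lmax), with
#' multi-start over the concentration parameter.
#'
#' @param signals a `signal_set` or numeric vector of S/S0
#' @param protocol protocol if `signals` is a vector
#' @param dpar fixed axial diffusivity (um^2/ms)
#' @param Dw free-water diffusivity (um^2/ms)
#' @param lmax invariants used in the fit
#' @return list with `kernel`, `f_noddi`, `fw`, `kappa`, `p2`, `diagnostics`
#' @export
noddi_fit <- function(signals, protocol = NULL, dpar = 0.6, Dw = 2.0, lmax = 6) {
  si <- signal_invariants(signals, protocol, lmax = lmax)
  ls <- seq(0, lmax, 2)
  data_sl <- si$sl
  gl <- pracma::gaussLegendre(96, 0, 1)
  PLw <- vapply(ls, function(l) gl$w * legendre_p(l, gl$x), numeric(length(gl$x)))
  model_sl <- function(par) {
    f <- par[1]; fw <- par[2]; kappa <- exp(par[3])
    pl <- watson_pl_fast(kappa, lmax)
    kern <- noddi_kernel(f, fw, dpar, Dw)
    t(vapply(si$bvals, function(bb)
      pl * abs(as.numeric(kernel_eval(kern, bb, gl$x) %*% PLw)), numeric(length(ls))))
  }
  obj <- function(par) {
    if (par[1] < 0 || par[1] > 1 || par[2] < 0 || par[2] > 1) return(1e6)
    sum((model_sl(par) - data_sl)^2)
  }
  starts <- expand.grid(f = c(0.3, 0.6, 0.85), fw = 0.05, lk = log(c(0.5, 2, 8, 32)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- stats::nlminb(as.numeric(starts[i, ]), obj,
                        lower = c(0, 0, log(1e-3)), upper = c(1, 1, log(1e4)),
                        control = list(rel.tol = 1e-12))
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  f <- best$par[1]; fw <- best$par[2]; kappa <- exp(best$par[3])
  p2 <- reference_fod_invariants("watson", list(kappa = kappa), 2)
  list(kernel = noddi_kernel(f, fw, dpar, Dw), f_noddi = f, fw = fw, kappa = kappa,
       p2 = p2,
       diagnostics = list(objective = best$objective,
                          converged = best$convergence == 0))
}

# ---- SMT -------------------------------------------------------------------

#' Spherical mean technique (SMT) estimator
#'
#' Fits `(f, Dpar)` to the per-shell spherical means, which factor out the FOD:
#' the model is the l = 0 kernel projection under the constraints
#' `Da = De_par = Dpar` and `De_perp = Dpar (1 - f)`, with the diffusivity
#' bounded above by free water at room temperature (2 um^2/ms).
#'
#' @param signals a `signal_set`, numeric vector, or per-shell spherical means
#' @param protocol protocol if `signals` is not a `signal_set`
#' @param d_max upper bound for the diffusivity (um^2/ms)
#' @return list with `kernel`, `diagnostics`
#' @export
smt_fit <- function(signals, protocol = NULL, d_max = 2.0) {
  smeans <- if (inherits(signals, "signal_set") ||
                (!is.null(protocol) && length(signals) == length(protocol$b))) {
    spherical_mean(signals, protocol)
  } else signals
  if (any(smeans <= 0) || any(smeans > 1 + 1e-9)) stop("spherical means must lie in (0, 1]")
  bv <- as.numeric(names(smeans))
  smt_kernel <- function(f, dpar)
    kernel_params(f = f, Da = dpar, depar = dpar, deperp = dpar * (1 - f), fw = 0)
  obj <- function(par) {
    pred <- vapply(bv, function(bb) kernel_projection(smt_kernel(par[1], par[2]), bb, 0), 0)
    sum((pred - smeans)^2)
  }
  best <- NULL
  for (f0 in c(0.2, 0.5, 0.8)) for (d0 in c(0.6, 1.2, 1.8)) {
    op <- stats::nlminb(c(f0, d0), obj, lower = c(0, 1e-3), upper = c(1, d_max),
                        control = list(rel.tol = 1e-14))
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  list(kernel = smt_kernel(best$par[1], best$par[2]),
       diagnostics = list(objective = best$objective,
                          converged = best$convergence == 0))
}

# ---- SMI -------------------------------------------------------------------

# exponent table for all monomials of total degree 1..3 in p variables
poly3_exponents <- function(p) {
  e1 <- diag(p)
  e2 <- NULL
  for (i in 1:p) for (j in i:p) { v <- numeric(p); v[i] <- v[i] + 1; v[j] <- v[j] + 1; e2 <- rbind(e2, v) }
  e3 <- NULL
  for (i in 1:p) for (j in i:p) for (k in j:p) {
    v <- numeric(p); v[i] <- v[i] + 1; v[j] <- v[j] + 1; v[k] <- v[k] + 1; e3 <- rbind(e3, v)
  }
  rbind(e1, e2, e3)
}

poly3_expand <- function(X, expo) {
  out <- matrix(1, nrow(X), nrow(expo))
  for (j in seq_len(nrow(expo))) {
    nz <- which(expo[j, ] > 0)
    col <- rep(1, nrow(X))
    for (v in nz) col <- col * X[, v]^expo[j, v]
    out[, j] <- col
  }
  cbind(1, out)
}

#' Default SMI training prior
#'
#' Uniform kernel prior spanning the ex vivo diffusivity bound, with the FOD
#' invariants drawn as `pl = lambda^l` (exponential decay, `lambda` uniform)
#' and no free water.
#'
#' @return list of ranges
#' @export
smi_default_prior <- function() {
  list(f = c(0.05, 0.95), Da = c(0.5, 2), depar = c(0.5, 2), deperp = c(0.05, 1.5),
       lambda = c(0, 0.95))
}

# noiseless invariant features sl(b, l) for a matrix of kernel draws; vectorized
smi_features <- function(theta, pl_mat, bvals, lmax = 6, order = 96) {
  ls <- seq(0, lmax, 2)
  gl <- pracma::gaussLegendre(order, 0, 1)
  n <- nrow(theta)
  feats <- matrix(0, n, length(bvals) * length(ls))
  cn <- character(0)
  col <- 0
  for (bb in bvals) {
    Ei <- exp(-bb * outer(theta[, "Da"], gl$x^2))
    Ee <- exp(-bb * theta[, "deperp"]) *
      exp(-bb * outer(theta[, "depar"] - theta[, "deperp"], gl$x^2))
    Kn <- theta[, "f"] * Ei + (1 - theta[, "f"]) * Ee
    for (li in seq_along(ls)) {
      l <- ls[li]
      Kl <- as.numeric(Kn %*% (gl$w * legendre_p(l, gl$x)))
      col <- col + 1
      feats[, col] <- pl_mat[, li] * abs(Kl)
      cn <- c(cn, paste0("b", bb, "_s", l))
    }
  }
  colnames(feats) <- cn
  feats
}

# propagate measurement noise onto rotational invariants (fiber frame)
smi_noisify <- function(feats, bvals, lmax, snr, n_dir) {
  if (!is.finite(snr)) return(feats)
  sigma_lm <- (1 / snr) * sqrt(4 * pi / n_dir)
  ls <- seq(0, lmax, 2)
  n <- nrow(feats)
  col <- 0
  for (bb in bvals) for (l in ls) {
    col <- col + 1
    Nl <- sqrt(4 * pi * (2 * l + 1))
    sl0 <- Nl * feats[, col] + stats::rnorm(n, 0, sigma_lm)
    rest <- if (l > 0) matrix(stats::rnorm(n * 2 * l, 0, sigma_lm), n) else NULL
    tot <- sl0^2 + if (l > 0) rowSums(rest^2) else 0
    feats[, col] <- sqrt(tot) / Nl
  }
  feats
}

#' Train the SMI polynomial regression
#'
#' Standard Model Imaging maps per-shell signal rotational invariants to kernel
#' parameters with a cubic polynomial regression trained on a synthetic prior:
#' kernel draws from [smi_default_prior()], noiseless invariants via
#' `sl = pl |Kl|`, optional noise propagation at the stated SNR, then one ridge
#' least-squares solve for all targets `(f, Da, De_par, De_perp, p2, p4, p6)`.
#'
#' @param protocol the acquisition protocol (shell b-values and direction count)
#' @param prior list of parameter ranges, as [smi_default_prior()]
#' @param n_train training-set size
#' @param snr training SNR (`Inf` = noiseless)
#' @param seed seed for the training draw
#' @param lmax invariants used (even, <= 6 typical)
#' @return object of class `smi_model`
#' @export
smi_train <- function(protocol, prior = smi_default_prior(), n_train = 5e4,
                      snr = Inf, seed = 1, lmax = 6) {
  set.seed(seed)
  draw <- function(r) stats::runif(n_train, r[1], r[2])
  theta <- cbind(f = draw(prior$f), Da = draw(prior$Da),
                 depar = draw(prior$depar), deperp = draw(prior$deperp))
  lambda <- draw(prior$lambda)
  ls <- seq(0, lmax, 2)
  pl_mat <- outer(lambda, ls, `^`)
  pl_mat[, 1] <- 1
  feats <- smi_features(theta, pl_mat, protocol$bvals, lmax)
  feats <- smi_noisify(feats, protocol$bvals, lmax, snr, protocol$n_dir)
  ctr <- colMeans(feats); scl <- apply(feats, 2, stats::sd)
  Xs <- sweep(sweep(feats, 2, ctr), 2, scl, `/`)
  expo <- poly3_exponents(ncol(Xs))
  X <- poly3_expand(Xs, expo)
  Y <- cbind(theta, p2 = pl_mat[, 2], p4 = pl_mat[, 3], p6 = pl_mat[, 4])
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + 1e-8 * mean(diag(XtX))
  B <- solve(XtX, crossprod(X, Y))
  structure(list(coef = B, center = ctr, scale = scl, exponents = expo,
                 bvals = protocol$bvals, lmax = lmax, snr = snr, seed = seed,
                 feature_range = apply(feats, 2, range), prior = prior),
            class = "smi_model")
}

#' @export
print.smi_model <- function(x, ...) {
  cat(sprintf("SMI cubic regression: %d features (b = %s; l <= %d), %d terms, training SNR = %s\n",
              length(x$center), paste(x$bvals, collapse = ","), x$lmax,
              nrow(x$coef), format(x$snr)))
  invisible(x)
}

#' Apply a trained SMI regression
#'
#' @param signals a `signal_set`, numeric vector, or `signal_invariants`
#' @param model an `smi_model`
#' @param protocol protocol if `signals` is a vector
#' @return list with `kernel`, `p2`, `pl`, `diagnostics` (extrapolation flag)
#' @export
smi_fit <- function(signals, model, protocol = NULL) {
  stopifnot(inherits(model, "smi_model"))
  si <- if (inherits(signals, "signal_invariants")) signals
  else signal_invariants(signals, protocol, lmax = model$lmax)
  ls <- seq(0, model$lmax, 2)
  feats <- matrix(0, 1, length(model$bvals) * length(ls))
  col <- 0
  for (bb in model$bvals) for (li in seq_along(ls)) {
    col <- col + 1
    feats[1, col] <- si$sl[as.character(bb), li]
  }
  rng <- model$feature_range
  span <- rng[2, ] - rng[1, ]
  extrap <- any(feats[1, ] < rng[1, ] - 0.1 * span | feats[1, ] > rng[2, ] + 0.1 * span)
  Xs <- sweep(sweep(feats, 2, model$center), 2, model$scale, `/`)
  pred <- as.numeric(poly3_expand(Xs, model$exponents) %*% model$coef)
  names(pred) <- colnames(model$coef)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  kern <- kernel_params(f = clamp(pred["f"], 0, 1), Da = clamp(pred["Da"], 0, 3),
                        depar = clamp(pred["depar"], 0, 3),
                        deperp = clamp(pred["deperp"], 0, 3), fw = 0)
  pl <- pmin(1, pmax(0, pred[c("p2", "p4", "p6")]))
  list(kernel = kern, p2 = unname(pl[1]), pl = unname(pl), l = c(2, 4, 6),
       diagnostics = list(extrapolated = extrap))
}

# ---- FOD recovery from a fitted kernel -------------------------------------

#' Recover FOD SH coefficients from signals and a fitted kernel
#'
#' Inverts `slm = plm Kl` per shell, combining shells with weights
#' proportional to `Kl^2` (ridge-regularized):
#' `plm = sum_b Kl(b) slm(b) / (sum_b Kl(b)^2 + eps^2)`.
#' Degrees whose `|Kl|` is below `eps` on every shell are omitted (zeroed).
#'
#' @param signals a `signal_set` or numeric vector
#' @param params fitted [kernel_params()]
#' @param protocol protocol if `signals` is a vector
#' @param lmax even maximum degree
#' @param eps ridge floor for `|Kl|`
#' @return an `sh_coef` with the recovered `plm` (l = 0 fixed to sqrt(4 pi))
#' @export
fod_from_kernel <- function(signals, params, protocol = NULL, lmax = 6, eps = 1e-4) {
  if (inherits(signals, "signal_set")) {
    protocol <- signals$protocol
    signals <- signals$values
  }
  idx <- sh_index(lmax)
  num <- numeric(nrow(idx)); den <- numeric(nrow(idx))
  for (bb in protocol$bvals) {
    sel <- protocol$b == bb
    Y <- sh_basis(protocol$dirs[sel, , drop = FALSE], lmax)
    slm <- stats::lm.fit(Y, signals[sel])$coefficients
    kl <- stats::setNames(vapply(seq(0, lmax, 2), function(l)
      kernel_projection(params, bb, l), 0), seq(0, lmax, 2))
    klv <- kl[as.character(idx$l)]
    num <- num + klv * slm
    den <- den + klv^2
  }
  coef <- num / (den + eps^2)
  coef[idx$l == 0] <- sqrt(4 * pi)
  names(coef) <- paste0("l", idx$l, "m", idx$m)
  structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
}
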