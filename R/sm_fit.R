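# Front-end for Standard Model parameter estimation: one fitting function,
# classed result, and the usual methods.

#' Fit Standard Model parameters to a multi-shell signal set
#'
#' Dispatches to one of the four estimators:
#' \describe{
#'   \item{`"wmti"`}{diffusion/kurtosis tensor fit, then closed-form branch
#'     formulas (aligned-fiber regime, `Da <= De_par`).}
#'   \item{`"noddi"`}{Watson FOD, fixed `Da = De_par = 0.6` um^2/ms, tortuosity
#'     constraint, free-water fraction estimated.}
#'   \item{`"smt"`}{spherical-mean fit of `(f, Dpar)` under
#'     `Da = De_par = Dpar`, `De_perp = Dpar (1 - f)`.}
#'   \item{`"smi"`}{machine-learning (cubic polynomial) regression from signal
#'     rotational invariants, no hard constraints; requires a trained
#'     [smi_train()] model via `smi_model` (one is trained on the fly at a
#'     reduced size if missing).}
#' }
#'
#' @param signals a `signal_set` (see [simulate_signal()]) or numeric vector of
#'   S/S0 values
#' @param protocol a [make_protocol()] object (taken from `signals` when absent)
#' @param method one of `"smi"`, `"wmti"`, `"noddi"`, `"smt"`
#' @param smi_model optional pre-trained [smi_train()] model (SMI only)
#' @param ... passed to the underlying estimator
#' @return object of class `sm_fit` with elements `method`, `kernel`
#'   ([kernel_params()]), `p2`, optional `pl`, `diagnostics`
#' @export
#' @examples
#' prot <- make_protocol()
#' fod <- sh_fit(matrix(c(0, 0, 1), 1), lmax = 6) # fully aligned bundle
#' truth <- kernel_params(f = 0.5, Da = 2, depar = 1.5, deperp = 0.5)
#' sig <- simulate_signal(prot, fod, truth, lmax = 6)
#' fit <- sm_fit(sig, method = "smt")
#' coef(fit)
sm_fit <- function(signals, protocol = NULL, method = c("smi", "wmti", "noddi", "smt"),
                   smi_model = NULL, ...) {
  method <- match.arg(method)
  if (inherits(signals, "signal_set") && is.null(protocol)) protocol <- signals$protocol
  stopifnot(inherits(protocol, "protocol"))
  res <- switch(method,
    wmti = {
      r <- wmti(fit_dki(signals, protocol), ...)
      list(kernel = r$kernel, p2 = r$p2, pl = NULL,
           diagnostics = c(r$diagnostics, list(valid = r$valid,
                                               lambda_intra = r$lambda_intra)))
    },
    noddi = {
      r <- noddi_fit(signals, protocol, ...)
      list(kernel = r$kernel, p2 = unname(r$p2), pl = NULL,
           diagnostics = c(r$diagnostics, list(f_noddi = r$f_noddi, fw = r$fw,
                                               kappa = r$kappa)))
    },
    smt = {
      r <- smt_fit(signals, protocol, ...)
      si <- signal_invariants(signals, protocol, lmax = 2)
      k2 <- abs(vapply(protocol$bvals, function(bb) kernel_projection(r$kernel, bb, 2), 0))
      p2 <- sum(k2 * si$sl[, "s2"]) / sum(k2^2) # invariant-ratio factor-out
      list(kernel = r$kernel, p2 = min(1, max(0, p2)), pl = NULL,
           diagnostics = r$diagnostics)
    },
    smi = {
      if (is.null(smi_model))
        smi_model <- smi_train(protocol, n_train = 2e4, seed = 1)
      r <- smi_fit(signals, smi_model, protocol)
      list(kernel = r$kernel, p2 = r$p2, pl = r$pl, diagnostics = r$diagnostics)
    })
  structure(c(res, list(method = method, protocol = protocol,
                        signals = if (inherits(signals, "signal_set")) signals$values else signals)),
            class = "sm_fit")
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("Standard Model fit (", toupper(x$method), ")\n", sep = "")
  print(x$kernel)
  cat(sprintf("  p2 = %.4f  (theta_p2 = %.2f deg)\n", x$p2, theta_from_p2(x$p2)))
  invisible(x)
}

#' @export
summary.sm_fit <- function(object, ...) {
  out <- list(method = object$method, coef = coef(object),
              theta_p2 = theta_from_p2(object$p2),
              diagnostics = object$diagnostics,
              rmse = sqrt(mean(residuals(object)^2)))
  class(out) <- "summary.sm_fit"
  out
}

#' @export
print.summary.sm_fit <- function(x, ...) {
  cat("Standard Model fit (", toupper(x$method), ")\n", sep = "")
  print(round(x$coef, 4))
  cat(sprintf("theta_p2 = %.2f deg; signal RMSE = %.2e\n", x$theta_p2, x$rmse))
  if (!is.null(x$diagnostics$valid) && !x$diagnostics$valid)
    cat("note: branch constraints violated, fit flagged invalid\n")
  invisible(x)
}

#' @export
coef.sm_fit <- function(object, ...) {
  k <- object$kernel
  c(f = k$f, Da = k$Da, De_par = k$depar, De_perp = k$deperp, fw = k$fw,
    p2 = object$p2)
}

#' Model-predicted signals of a Standard Model fit
#'
#' Reconstructs the fitted signal at the protocol directions: the FOD is
#' recovered from the fitted kernel ([fod_from_kernel()]; for NODDI the Watson
#' FOD at the fitted concentration is used through the same route), then
#' convolved with the kernel. For SMT, which only models spherical means, the
#' per-shell mean is returned at every direction of the shell.
#'
#' @param object an `sm_fit`
#' @param protocol protocol to predict at (default: the fitted one)
#' @param lmax SH band limit of the recovered FOD
#' @param ... unused
#' @return numeric vector of predicted S/S0
#' @export
predict.sm_fit <- function(object, protocol = NULL, lmax = 6, ...) {
  if (is.null(protocol)) protocol <- object$protocol
  if (object$method == "smt") {
    sm <- vapply(protocol$bvals, function(bb) kernel_projection(object$kernel, bb, 0), 0)
    out <- rep(1, length(protocol$b))
    for (i in seq_along(protocol$bvals)) out[protocol$b == protocol$bvals[i]] <- sm[i]
    return(out)
  }
  fod <- fod_from_kernel(object$signals, object$kernel, object$protocol, lmax = lmax)
  simulate_signal(protocol, fod, object$kernel, route = "sh", lmax = lmax)$values
}

#' @export
residuals.sm_fit <- function(object, ...) {
  object$signals - predict(object)
}
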