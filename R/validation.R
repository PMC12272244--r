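# Correlation machinery for the dMRI-vs-morphometry comparison: Pearson with
# t-test p-values and Fisher-transform confidence intervals, Benjamini-Hochberg
# FDR, Lin's concordance, and the sensitivity/specificity matrix report.

#' Pearson correlation with p-value and Fisher confidence interval
#'
#' Two-sided p from `t = rho sqrt((N-2)/(1-rho^2))` with N-2 degrees of
#' freedom; confidence interval from the asymptotic Gaussian distribution of
#' `atanh(rho)` with variance `1/(N-3)`.
#'
#' @param x,y paired numeric vectors, N >= 4
#' @param conf confidence level
#' @return list with `rho`, `p`, `ci` (length 2), `n`
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4, all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                degenerate = TRUE))
  rho <- stats::cor(x, y)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(rho) + c(-1, 1) * z / sqrt(n - 3))
  list(rho = rho, p = p, ci = ci, n = n, degenerate = FALSE)
}

#' Permutation p-value for a Pearson correlation
#'
#' @param x,y paired vectors
#' @param n_perm number of permutations
#' @param seed optional seed
#' @return two-sided permutation p-value
#' @export
pearson_perm_p <- function(x, y, n_perm = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r0 <- abs(stats::cor(x, y))
  hits <- sum(vapply(seq_len(n_perm), function(i)
    abs(stats::cor(x, sample(y))) >= r0 - 1e-15, TRUE))
  (hits + 1) / (n_perm + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up procedure: after sorting, `q(i) = min_{j >= i} p(j) m / j`, returned
#' in the original order.
#'
#' @param p vector of p-values in \[0, 1\]
#' @return q-values
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  q <- pv[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  qq <- numeric(m)
  qq[o] <- q
  out[ok] <- qq
  out
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/N) moments, penalizing both scatter and deviation from the
#' identity line.
#'
#' @param x,y paired vectors, N >= 2
#' @return concordance coefficient in \[-1, 1\]
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * cxy / den
}

#' Sensitivity/specificity correlation report
#'
#' Cross-correlates every dMRI-derived metric with every morphometry metric
#' across paired samples; p-values by the Pearson t-test (optionally by
#' permutation), FDR across the whole matrix, and a summary reading: a
#' corresponding (diagonal) pair is "sensitive" when its q < alpha; an estimator
#' is "specific" when no non-corresponding pair in the submatrix reaches q <
#' alpha.
#'
#' @param dmri data.frame of dMRI metrics (rows = samples)
#' @param em data.frame of morphometry metrics, same row order
#' @param pairs named character vector mapping dMRI columns to their
#'   corresponding EM columns, e.g. `c(f = "f_em", theta_p2 = "theta",
#'   Da = "Da_pred")`
#' @param alpha significance threshold on p and q
#' @param p_method `"ttest"` or `"permutation"`
#' @param n_perm permutations when `p_method = "permutation"`
#' @param seed seed for the permutation option
#' @return object of class `specificity_report` with matrices `rho`, `p`, `q`,
#'   `ci_lo`, `ci_hi`, logical `significant`, and the summary fields
#' @export
specificity_report <- function(dmri, em, pairs, alpha = 0.05,
                               p_method = c("ttest", "permutation"),
                               n_perm = 1e4, seed = NULL) {
  p_method <- match.arg(p_method)
  stopifnot(nrow(dmri) == nrow(em))
  if (!all(names(pairs) %in% colnames(dmri)))
    stop("pairing map names missing from the dMRI table")
  if (!all(pairs %in% colnames(em)))
    stop("pairing map values missing from the EM table")
  dm <- colnames(dmri); emc <- colnames(em)
  rho <- p <- lo <- hi <- matrix(NA_real_, length(dm), length(emc),
                                 dimnames = list(dm, emc))
  for (i in seq_along(dm)) for (j in seq_along(emc)) {
    r <- pearson_with_ci(dmri[[dm[i]]], em[[emc[j]]])
    rho[i, j] <- r$rho
    p[i, j] <- if (p_method == "permutation")
      pearson_perm_p(dmri[[dm[i]]], em[[emc[j]]], n_perm, seed) else r$p
    lo[i, j] <- r$ci[1]; hi[i, j] <- r$ci[2]
  }
  q <- matrix(fdr_bh(as.numeric(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  sig <- q < alpha
  diag_pairs <- data.frame(dmri = names(pairs), em = unname(pairs),
                           rho = NA_real_, p = NA_real_, q = NA_real_,
                           significant = NA)
  for (k in seq_len(nrow(diag_pairs))) {
    i <- diag_pairs$dmri[k]; j <- diag_pairs$em[k]
    diag_pairs$rho[k] <- rho[i, j]; diag_pairs$p[k] <- p[i, j]
    diag_pairs$q[k] <- q[i, j]; diag_pairs$significant[k] <- sig[i, j]
  }
  off <- sig
  for (k in seq_len(nrow(diag_pairs))) off[diag_pairs$dmri[k], diag_pairs$em[k]] <- NA
  structure(list(rho = rho, p = p, q = q, ci_lo = lo, ci_hi = hi,
                 significant = sig, pairs = pairs, alpha = alpha,
                 sensitivity = diag_pairs,
                 n_spurious = sum(off[names(pairs), unname(pairs)], na.rm = TRUE),
                 specific = sum(off[names(pairs), unname(pairs)], na.rm = TRUE) == 0),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Correlation matrix (dMRI rows x EM columns), rho:\n")
  print(round(x$rho, 3))
  cat("\nCorresponding pairs (sensitivity, q <", x$alpha, "):\n")
  print(x$sensitivity, row.names = FALSE)
  cat("\nSpurious significant off-diagonal pairs in the submatrix:",
      x$n_spurious, if (x$specific) "(specific)" else "(not specific)", "\n")
  invisible(x)
}
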