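# Readers and writers for the exchange formats (skeleton CSV, FSL-style
# bval/bvec, SH coefficient CSV, metric tables, JSON population specs) and the
# end-to-end pipeline driver.

#' Write axon skeletons to the skeleton CSV dialect
#'
#' Columns `axon_id, point_index, x_um, y_um, z_um, area_um2,
#' myelin_thickness_um`, header required, points ordered along each axon.
#'
#' @param axons a `population` or list of `axon` objects
#' @param path output file
#' @export
write_skeleton_csv <- function(axons, path) {
  if (inherits(axons, "population")) axons <- axons$axons
  rows <- lapply(seq_along(axons), function(i) {
    ax <- axons[[i]]
    data.frame(axon_id = i, point_index = seq_len(nrow(ax$points)),
               x_um = ax$points[, 1], y_um = ax$points[, 2], z_um = ax$points[, 3],
               area_um2 = ax$area, myelin_thickness_um = ax$myelin_thickness)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read axon skeletons from the skeleton CSV dialect
#'
#' @param path CSV file written by [write_skeleton_csv()]
#' @return list of `axon` objects
#' @export
read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("axon_id", "point_index", "x_um", "y_um", "z_um", "area_um2",
            "myelin_thickness_um")
  if (!all(need %in% colnames(df)))
    stop("malformed skeleton CSV: expected columns ", paste(need, collapse = ", "))
  lapply(split(df, df$axon_id), function(d) {
    d <- d[order(d$point_index), ]
    axon_geometry(as.matrix(d[, c("x_um", "y_um", "z_um")]), d$area_um2,
                  d$myelin_thickness_um)
  })
}

#' Write/read FSL-style bval and bvec files
#'
#' `bval`: one row of b-values; written in s/mm^2 (ms/um^2 x 1000). `bvec`:
#' three rows (x, y, z components). On reading, b-values larger than 100 are
#' assumed to be s/mm^2 and are divided by 1000 (with a message); non-unit
#' gradient columns are renormalized with a warning.
#'
#' @param protocol a `protocol`
#' @param bval_path,bvec_path output/input paths
#' @return (reader) a list with `b` (ms/um^2) and `dirs`
#' @export
write_bval_bvec <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(protocol$b * 1000, collapse = " "), bval_path)
  writeLines(apply(t(protocol$dirs), 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  v <- as.matrix(utils::read.table(bvec_path))
  if (nrow(v) == 3) v <- t(v)
  if (nrow(v) != length(b)) stop("bval/bvec volume counts disagree")
  if (max(b) > 100) {
    message("bval magnitudes look like s/mm^2; converting to ms/um^2")
    b <- b / 1000
  }
  nrm <- sqrt(rowSums(v^2))
  bad <- which(b > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad)) {
    warning(length(bad), " non-unit bvec column(s) renormalized")
    v[bad, ] <- v[bad, ] / nrm[bad]
  }
  list(b = b, dirs = v)
}

#' Write/read SH coefficients as CSV
#'
#' Columns `l, m, value`; metadata header lines (prefixed `#`) state the basis
#' convention.
#'
#' @param sh an `sh_coef`
#' @param path file path
#' @return (reader) an `sh_coef`
#' @export
write_sh_csv <- function(sh, path) {
  con <- file(path, "w")
  writeLines(c(
    "# real spherical harmonics, orthonormal in dOmega, Condon-Shortley phase",
    "# even degrees only; coefficients plm = integral dOmega Ylm P, p00 = sqrt(4 pi)",
    "l,m,value"), con)
  utils::write.table(data.frame(sh$index$l, sh$index$m, sh$coef), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_sh_csv
#' @export
read_sh_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  colnames(df) <- c("l", "m", "value")
  lmax <- max(df$l)
  idx <- sh_index(lmax)
  key <- paste(df$l, df$m)
  o <- match(paste(idx$l, idx$m), key)
  if (any(is.na(o))) stop("SH CSV is missing (l, m) entries")
  coef <- df$value[o]
  names(coef) <- paste0("l", idx$l, "m", idx$m)
  structure(list(lmax = lmax, index = idx, coef = coef), class = "sh_coef")
}

#' Serialize / load a population spec as JSON
#'
#' @param spec a [population_spec()]
#' @param path file path
#' @return (reader) a `population_spec`
#' @export
write_population_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(population_spec, x)
}

#' Run the full validation pipeline on synthetic samples
#'
#' Generates `n_samples` axon populations whose microstructure drifts from a
#' sham-like to an injury-like condition (fewer axons, more beading, more
#' dispersion), computes the morphometry arm, simulates the matched dMRI arm
#' (SM kernel tied to each sample's ground truth, FOD from the sample's
#' tangents), fits the requested estimators, and cross-correlates the two arms.
#'
#' @param config list (or path to a JSON file) with optional fields
#'   `n_samples`, `n_axons`, `seed`, `snr`, `methods`, `smi_n_train`,
#'   `out_dir`; missing fields take the defaults below
#' @return list with `em` and per-method `dmri` metric tables, the
#'   `specificity` reports, and a reproducibility `manifest`
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    n_samples = 8, n_axons = 220, seed = 1, snr = Inf,
    methods = c("smi", "wmti", "noddi", "smt"),
    smi_n_train = 2e4, out_dir = NULL), config)
  set.seed(cfg$seed)
  prot <- make_protocol()
  smi_mod <- if ("smi" %in% cfg$methods)
    smi_train(prot, n_train = cfg$smi_n_train, seed = cfg$seed) else NULL
  severity <- seq(0, 1, length.out = cfg$n_samples)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_samples)
  em <- NULL
  dmri <- stats::setNames(vector("list", length(cfg$methods)), cfg$methods)
  for (s in seq_len(cfg$n_samples)) {
    sv <- severity[s]
    spec <- population_spec(
      n_axons = round(cfg$n_axons * (1 - 0.45 * sv)),
      fod_params = list(kappa = 18 - 10 * sv, n0 = c(0, 0, 1)),
      undulation = list(amplitude = 0.2 + 0.35 * sv, wavelength = 8),
      beading = list(amplitude = 0.1 + 0.5 * sv, wavelength = 6),
      seed = sample_seeds[s])
    pop <- generate_population(spec)
    pm <- population_metrics(pop, level = 3, lmax = 6)
    em <- rbind(em, data.frame(f_em = pm$f, theta_em = pm$theta,
                               Da_pred = pm$Da_pred, diameter = pm$mean_diameter,
                               tortuosity = pm$mean_tortuosity))
    kern <- kernel_params(f = min(0.95, pm$f), Da = pm$Da_pred,
                          depar = min(2, pm$Da_pred + 0.1),
                          deperp = 0.4 + 0.25 * sv, fw = 0)
    sig <- simulate_signal(prot, pm$sh, kern, route = "sh", lmax = 6)
    sig$values <- pmin(sig$values, 1)
    if (is.finite(cfg$snr)) sig <- add_noise(sig, cfg$snr, "rician",
                                             seed = sample_seeds[s])
    for (m in cfg$methods) {
      fit <- sm_fit(sig, method = m, smi_model = smi_mod)
      dmri[[m]] <- rbind(dmri[[m]],
                         data.frame(f = fit$kernel$f, theta_p2 = theta_from_p2(fit$p2),
                                    Da = fit$kernel$Da))
    }
  }
  pairs <- c(f = "f_em", theta_p2 = "theta_em", Da = "Da_pred")
  reports <- lapply(dmri, function(d) specificity_report(d, em, pairs))
  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   sample_seeds = sample_seeds,
                   protocol = list(bvals = prot$bvals, n_dir = prot$n_dir,
                                   n_b0 = prot$n_b0),
                   n_samples = cfg$n_samples,
                   em_checksum = sum(unlist(em)),
                   package_version = tryCatch(
                     as.character(utils::packageVersion("axonsm")),
                     error = function(e) "dev"))
  out <- list(em = em, dmri = dmri, specificity = reports, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(em, file.path(cfg$out_dir, "em_metrics.csv"), row.names = FALSE)
    for (m in names(dmri))
      utils::write.csv(dmri[[m]], file.path(cfg$out_dir, paste0("dmri_", m, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
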