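# Nuisance regression, detrending and narrow-band filtering -------------------
#
# The stage order is fixed: (1) regress 16 nuisance series (6 motion + CSF +
# WM and their first derivatives) out of every voxel/region series, (2) remove
# a linear trend per series, (3) band-pass to 0.03-0.06 Hz with an order-4
# Butterworth filter applied forward-backward (zero phase).

#' Assemble the 16-column nuisance regressor matrix
#'
#' Eight base series (6 motion parameters, mean CSF, mean WM) followed by
#' their discrete first derivatives (backward difference, first sample
#' replicated to preserve length).
#'
#' @param motion T x 6 motion-parameter matrix.
#' @param csf,wm length-T mean confound series.
#' @return list of class `nuisance_matrix` with `values` (T x 16) and
#'   `column_labels`.
#' @export
build_nuisance_matrix <- function(motion, csf, wm) {
  assert_matrix(motion)
  if (ncol(motion) != 6L) stop("'motion' must have 6 columns", call. = FALSE)
  Tn <- nrow(motion)
  for (nm in c("csf", "wm")) {
    x <- get(nm)
    if (length(x) != Tn)
      stop(sprintf("series '%s' has length %d, expected %d", nm, length(x), Tn),
           call. = FALSE)
    if (anyNA(x)) stop(sprintf("series '%s' contains missing values", nm),
                       call. = FALSE)
  }
  base <- cbind(motion, csf, wm)
  labels <- c(paste0("motion_", 1:6), "csf", "wm")
  colnames(base) <- labels
  deriv <- apply(base, 2, function(x) c(x[2] - x[1], diff(x)))
  colnames(deriv) <- paste0("d_", labels)
  structure(list(values = cbind(base, deriv),
                 column_labels = c(labels, colnames(deriv))),
            class = "nuisance_matrix")
}

#' Regress nuisance series out of data columns
#'
#' Per-column ordinary least squares with an intercept; returns residuals.
#' Collinear nuisance columns are dropped with a logged warning.
#'
#' @param series T x V data matrix.
#' @param nuisance a `nuisance_matrix` (or plain T x p matrix).
#' @return T x V residual matrix; dropped columns noted in [run_log()].
#' @export
regress_out <- function(series, nuisance) {
  assert_matrix(series)
  X <- if (inherits(nuisance, "nuisance_matrix")) nuisance$values else nuisance
  assert_matrix(X, "nuisance")
  if (nrow(X) != nrow(series)) stop("series and nuisance lengths differ",
                                    call. = FALSE)
  if (nrow(series) < ncol(X) + 2L)
    stop("too few time points for the nuisance design", call. = FALSE)
  design <- cbind(1, X)
  qrd <- qr(design)
  note <- NULL
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- setdiff(seq_len(ncol(design)), keep)
    note <- sprintf("dropped %d collinear nuisance column(s): %s",
                    length(dropped), paste(dropped - 1L, collapse = ", "))
    warning(note, call. = FALSE)
    qrd <- qr(design[, keep, drop = FALSE])
  }
  res <- qr.resid(qrd, series)
  if (!is.null(note)) res <- log_note(res, note)
  res
}

#' Remove the best-fit line from every column
#'
#' @param series T x V matrix, T at least 3.
#' @return matrix of the same shape with zero column means and zero linear
#'   trends.
#' @export
detrend_linear <- function(series) {
  assert_matrix(series)
  if (nrow(series) < 3L) stop("need at least 3 time points to detrend",
                              call. = FALSE)
  t_idx <- seq_len(nrow(series))
  qr.resid(qr(cbind(1, t_idx)), series)
}

#' Band specification for the Butterworth filter
#'
#' @param low,high passband edges in Hz (defaults 0.03 and 0.06).
#' @param order filter order (default 4).
#' @param fs sampling rate in Hz (= 1/TR).
#' @return list of class `band_spec`.
#' @export
band_spec <- function(low = 0.03, high = 0.06, order = 4L, fs = 1 / 3) {
  if (!(0 < low && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= fs / 2)
    stop(sprintf("high edge %.4g Hz is at or above Nyquist %.4g Hz",
                 high, fs / 2), call. = FALSE)
  structure(list(low = low, high = high, order = as.integer(order), fs = fs),
            class = "band_spec")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-`order` Butterworth band-pass applied forward and backward (zero
#' phase; attenuation acts twice). Series are reflect-padded by three filter
#' orders at each end before filtering and trimmed afterwards. A single-pass
#' (phase-shifting) variant is selectable.
#'
#' @param series T x V matrix.
#' @param band a [band_spec()].
#' @param zero_phase apply forward-backward (default) or single forward pass.
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(series, band = band_spec(), zero_phase = TRUE) {
  assert_matrix(series)
  stopifnot(inherits(band, "band_spec"))
  wn <- c(band$low, band$high) / (band$fs / 2)
  bf <- signal::butter(band$order, wn, type = "pass")
  pad <- 3L * band$order
  n <- nrow(series)
  out <- series
  for (j in seq_len(ncol(series))) {
    x <- series[, j]
    p <- min(pad, n - 1L)
    xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
    y <- as.numeric(signal::filter(bf, xp))
    if (zero_phase) y <- rev(as.numeric(signal::filter(bf, rev(y))))
    out[, j] <- y[(p + 1):(p + n)]
  }
  out
}

#' Analytic magnitude response of the band-pass stage
#'
#' @param band a [band_spec()].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param zero_phase if `TRUE`, the squared (two-pass) magnitude is returned.
#' @return numeric vector of gains.
#' @export
bandpass_response <- function(band, freqs, zero_phase = TRUE) {
  wn <- c(band$low, band$high) / (band$fs / 2)
  bf <- signal::butter(band$order, wn, type = "pass")
  w <- 2 * pi * freqs / band$fs
  ew <- function(coef) vapply(w, function(wi)
    sum(coef * exp(-1i * wi * (seq_along(coef) - 1))), complex(1))
  g <- Mod(ew(bf$b) / ew(bf$a))
  if (zero_phase) g^2 else g
}

#' Preprocess one subject (regress, detrend, band-pass, in that order)
#'
#' Applies the three stages to both the voxel and the region series, using
#' the subject's own motion/CSF/WM series as nuisance regressors.
#'
#' @param subject a `subject_data`.
#' @param band a [band_spec()]; its `fs` is overridden by `1/TR` of the
#'   subject.
#' @param zero_phase passed to [bandpass()].
#' @return the subject with filtered `region_series` and `voxel_series` and
#'   a `preprocessed` flag.
#' @export
preprocess_subject <- function(subject, band = band_spec(), zero_phase = TRUE) {
  stopifnot(inherits(subject, "subject_data"))
  band <- band_spec(band$low, band$high, band$order, fs = 1 / subject$TR)
  nuis <- build_nuisance_matrix(subject$motion, subject$csf, subject$wm)
  for (field in c("region_series", "voxel_series")) {
    x <- regress_out(subject[[field]], nuis)
    x <- detrend_linear(x)
    x <- bandpass(x, band, zero_phase = zero_phase)
    colnames(x) <- colnames(subject[[field]])
    subject[[field]] <- x
  }
  subject$preprocessed <- TRUE
  subject
}

#' Preprocess every subject of a cohort
#' @param cohort an `mkl_cohort`.
#' @inheritParams preprocess_subject
#' @return the cohort with all subjects preprocessed.
#' @export
preprocess_cohort <- function(cohort, band = band_spec(), zero_phase = TRUE) {
  cohort$subjects <- lapply(cohort$subjects, preprocess_subject,
                            band = band, zero_phase = zero_phase)
  cohort
}
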