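#' Construct a peak list for one acquisition
#'
#' One direct-infusion acquisition: centroided (m/z, intensity) pairs plus
#' the metadata needed downstream (ionisation mode, acquisition method,
#' replicate, batch, QC flag).
#'
#' @param sample_id Unique acquisition identifier.
#' @param mz,intensity Numeric vectors of equal length; intensities must be
#'   positive.
#' @param mode `"positive"` or `"negative"`.
#' @param method `"ultra_small"` (65-300 m/z) or `"small"` (95-1500 m/z).
#' @param subject_id Subject the breath sample came from, or `NA` for QC pools.
#' @param replicate Replicate index within subject (1-3), `NA` for QC.
#' @param batch Batch label.
#' @param qc `TRUE` for pooled quality-control injections.
#' @return Object of class `"peak_list"`.
#' @export
peak_list <- function(sample_id, mz, intensity,
                      mode = c("positive", "negative"),
                      method = c("ultra_small", "small"),
                      subject_id = NA_character_, replicate = NA_integer_,
                      batch = "B1", qc = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) && any(intensity <= 0)) stop("intensities must be positive")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(
    sample_id = as.character(sample_id),
    subject_id = as.character(subject_id),
    replicate = as.integer(replicate),
    mode = mode, method = method,
    batch = as.character(batch), qc = isTRUE(qc),
    peaks = data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  ), class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s (%s, %s%s): %d peaks\n",
              x$sample_id, x$mode, x$method,
              if (x$qc) ", QC" else "", nrow(x$peaks)))
  invisible(x)
}

#' Recalibrate a peak list against a local calibration list
#'
#' Matches calibrant ions (formula + adduct) to observed peaks within a coarse
#' window and fits a linear m/z correction (offset + slope) by least squares;
#' with a single matched calibrant a constant relative (ppm) offset is used.
#' The correction is applied to every peak and post-correction calibrant
#' residuals are attached as attribute `"recalibration"`.
#'
#' @param peaks A `peak_list`.
#' @param calibrants `data.frame` with columns `formula` and `adduct`
#'   (adduct names from [default_adducts()]).
#' @param window_ppm Coarse matching window in ppm (default 5).
#' @return The corrected `peak_list`; attribute `"recalibration"` is a list
#'   with the matched calibrants and their residual ppm errors.
#' @export
recalibrate <- function(peaks, calibrants, window_ppm = 5) {
  stopifnot(inherits(peaks, "peak_list"))
  adducts <- default_adducts()
  cal <- calibrants[adducts$polarity[match(calibrants$adduct, adducts$name)] == peaks$mode, ,
                    drop = FALSE]
  theo <- vapply(seq_len(nrow(cal)),
                 function(i) theoretical_mz(cal$formula[i], cal$adduct[i]),
                 numeric(1))
  obs <- rep(NA_real_, length(theo))
  mzv <- peaks$peaks$mz
  for (i in seq_along(theo)) {
    if (!length(mzv)) break
    j <- which.min(abs(mzv - theo[i]))
    if (abs(ppm_error(mzv[j], theo[i])) <= window_ppm) obs[i] <- mzv[j]
  }
  ok <- !is.na(obs)
  if (!any(ok)) stop("no calibrant matched within ", window_ppm, " ppm")
  if (sum(ok) >= 2L) {
    fit <- stats::lm(obs[ok] ~ theo[ok])
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    correct <- function(x) (x - a) / b
  } else {
    ratio <- obs[ok] / theo[ok]  # single-point relative offset
    correct <- function(x) x / ratio
  }
  peaks$peaks$mz <- correct(peaks$peaks$mz)
  residuals <- ppm_error(correct(obs[ok]), theo[ok])
  attr(peaks, "recalibration") <- list(
    n_matched = sum(ok),
    matched = data.frame(formula = cal$formula[ok], adduct = cal$adduct[ok],
                         mz_theoretical = theo[ok], mz_observed = obs[ok],
                         residual_ppm = residuals),
    residual_ppm = residuals
  )
  peaks
}
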