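#' Construct an EmissionSpectrum
#'
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param intensities non-negative intensities, same length.
#' @param label luciferase x substrate identifier.
#' @return an [EmissionSpectrum-class].
#' @export
EmissionSpectrum <- function(wavelengths, intensities, label = "spectrum")
  new("EmissionSpectrum", wavelengths = as.numeric(wavelengths),
      intensities = as.numeric(intensities), label = label)

#' Read spectra from a wavelength/intensity table
#'
#' @param path CSV or TSV with columns `wavelength` and `intensity`, and
#'   optionally `label` to hold several spectra in one file.
#' @return list of [EmissionSpectrum-class].
#' @export
readSpectra <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("wavelength", "intensity") %in% names(tab)))
    stop("need columns 'wavelength' and 'intensity'")
  if (!"label" %in% names(tab)) tab$label <- "spectrum"
  lapply(split(tab, tab$label), function(g) {
    g <- g[order(g$wavelength), ]
    EmissionSpectrum(g$wavelength, g$intensity, g$label[1])
  })
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                             utils::tail(y, -1)) / 2)

#' Summarise an emission spectrum
#'
#' Computes the emission peak, full width at half maximum and red
#' spectral fractions:
#' * `lambda_max`: wavelength of maximum intensity (ties broken toward
#'   the blue, i.e. the lowest wavelength);
#' * `fwhm`: distance between the two outermost half-maximum crossings,
#'   located by linear interpolation between grid points;
#' * `fraction_above`: trapezoidal integral over `[cutoff, end]` divided
#'   by the total integral, for each requested cutoff (the "portion of
#'   emission longer than X nm" statistic).
#'
#' @param s an [EmissionSpectrum-class].
#' @param cutoffs numeric cutoffs in nm (default 600, the tissue-window
#'   threshold).
#' @param smooth optional odd window length for a running-mean smoother
#'   (default off).
#' @return list with `lambda_max`, `fwhm` and named `fraction_above`.
#' @examples
#' tri <- EmissionSpectrum(c(450, 500, 550), c(0, 1, 0))
#' spectrumSummary(tri, cutoffs = 500)
#' @export
spectrumSummary <- function(s, cutoffs = 600, smooth = 0L) {
  w <- s@wavelengths
  y <- s@intensities
  if (smooth >= 3L) {
    k <- rep(1 / smooth, smooth)
    y <- as.numeric(stats::filter(y, k, sides = 2))
    pad <- (smooth - 1L) %/% 2L
    y[seq_len(pad)] <- y[pad + 1L]
    y[(length(y) - pad + 1L):length(y)] <- y[length(y) - pad]
  }
  imax <- which.max(y)  # which.max takes the first (lowest nm) on ties
  peak <- y[imax]
  half <- peak / 2
  crossingsLeft <- function() {
    for (i in seq_len(imax - 1L)) {
      if (y[i] <= half && y[i + 1L] > half)
        return(w[i] + (half - y[i]) / (y[i + 1L] - y[i]) *
                 (w[i + 1L] - w[i]))
    }
    w[1]
  }
  crossingsRight <- function() {
    for (i in rev(seq(imax, length(y) - 1L))) {
      if (y[i + 1L] <= half && y[i] > half)
        return(w[i] + (y[i] - half) / (y[i] - y[i + 1L]) *
                 (w[i + 1L] - w[i]))
    }
    w[length(w)]
  }
  fwhm <- crossingsRight() - crossingsLeft()
  total <- trapezoid(w, y)
  frac <- vapply(cutoffs, function(cut) {
    if (cut <= w[1]) return(1)
    if (cut >= w[length(w)]) return(0)
    yi <- stats::approx(w, y, xout = cut)$y
    sel <- w > cut
    trapezoid(c(cut, w[sel]), c(yi, y[sel])) / total
  }, numeric(1))
  list(lambda_max = w[imax], fwhm = fwhm,
       fraction_above = stats::setNames(frac, as.character(cutoffs)))
}

#' Summary table for several spectra
#'
#' One row per spectrum: peak wavelength with the FWHM in parentheses
#' (the conventional "peak (FWHM)" layout) plus the red fractions.
#'
#' @param spectra list of [EmissionSpectrum-class].
#' @param cutoffs cutoffs passed to [spectrumSummary()].
#' @return data.frame.
#' @export
spectrumTable <- function(spectra, cutoffs = 600) {
  do.call(rbind, lapply(spectra, function(s) {
    sm <- spectrumSummary(s, cutoffs)
    row <- data.frame(label = s@label,
                      peak = sprintf("%.0f (%.0f)", sm$lambda_max,
                                     sm$fwhm),
                      lambda_max = sm$lambda_max, fwhm = sm$fwhm,
                      stringsAsFactors = FALSE)
    for (nm in names(sm$fraction_above))
      row[[paste0("frac_above_", nm)]] <- sm$fraction_above[[nm]]
    row
  }))
}

#' Build an intensity panel
#'
#' @param condition character vector of condition labels (one entry per
#'   replicate measurement).
#' @param intensity non-negative replicate intensities.
#' @param reference label of the reference condition.
#' @return an intensity panel (data.frame with a `reference` attribute).
#' @export
intensityPanel <- function(condition, intensity, reference) {
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!reference %in% condition)
    stop("reference condition '", reference, "' absent from panel")
  panel <- data.frame(condition = as.character(condition),
                      intensity = as.numeric(intensity),
                      stringsAsFactors = FALSE)
  attr(panel, "reference") <- reference
  panel
}

#' Fold intensity relative to the panel reference
#'
#' Ratio of condition mean to reference mean, the signal-to-background
#' (S/B) construct. The replicate standard deviations are propagated to
#' the ratio by the usual first-order formula
#' `sd = fold * sqrt((sd_c/mean_c)^2 + (sd_r/mean_r)^2)`.
#'
#' @param panel panel from [intensityPanel()].
#' @param condition condition label to compare against the reference.
#' @return list with `fold`, `sd`, and per-group means and sds.
#' @export
foldIntensity <- function(panel, condition) {
  ref <- attr(panel, "reference")
  grab <- function(lab) {
    v <- panel$intensity[panel$condition == lab]
    if (!length(v)) stop("unknown condition label: ", lab)
    v
  }
  vc <- grab(condition)
  vr <- grab(ref)
  mr <- mean(vr)
  if (mr <= 0) stop("reference mean must be positive")
  mc <- mean(vc)
  sc <- if (length(vc) > 1L) stats::sd(vc) else 0
  sr <- if (length(vr) > 1L) stats::sd(vr) else 0
  fold <- mc / mr
  relc <- if (mc > 0) (sc / mc)^2 else 0
  list(fold = fold,
       sd = fold * sqrt(relc + (sr / mr)^2),
       mean_condition = mc, sd_condition = sc,
       mean_reference = mr, sd_reference = sr)
}
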