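#' Packaged cancellous-bone optical absorption spectrum
#'
#' Analytic stand-in for a spectrophotometer measurement of ground cancellous
#' bone over the visible range. The model is a fixed sum of log-normal-shaped
#' peaked components on a gently decaying baseline, parameterised so that the
#' strongest absorption sits at 406 nm with secondary local maxima at 540 and
#' 576 nm (the haemoglobin-dominated structure that motivates a 532 nm
#' excitation source). Absorbance is relative (unitless).
#'
#' @param wavelengths numeric grid of wavelengths in nm, strictly increasing,
#'   within the instrument range 340-960 nm.
#' @return An object of class `spectrum_model`: list with `wavelength_nm` and
#'   `absorbance`.
#' @export
#' @examples
#' sp <- cancellous_absorption_spectrum(340:960)
#' find_peaks(sp)[1:3]
cancellous_absorption_spectrum <- function(wavelengths = seq(340, 960, by = 1)) {
  wl <- as.numeric(wavelengths)
  if (length(wl) < 1L || any(!is.finite(wl))) stop("empty or non-finite wavelength grid")
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  if (min(wl) < 340 || max(wl) > 960) {
    stop("wavelengths must lie within the 340-960 nm instrument range")
  }
  # log-normal-shaped components: gaussian in log-wavelength with the mode
  # pinned at the printed peak locations
  lnpeak <- function(wl, mode, width, amp) {
    s <- width / mode  # approximate sd in log space
    amp * exp(-(log(wl / mode))^2 / (2 * s^2))
  }
  ab <- lnpeak(wl, 406, 20, 1.00) +
    lnpeak(wl, 540, 11, 0.52) +
    lnpeak(wl, 576, 11, 0.46) +
    0.12 * exp(-(wl - 340) / 180)
  structure(list(wavelength_nm = wl, absorbance = ab), class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat("spectrum_model:", length(x$wavelength_nm), "samples,",
      sprintf("%.0f-%.0f nm", min(x$wavelength_nm), max(x$wavelength_nm)), "\n")
  invisible(x)
}

#' Find absorbance peaks in a spectrum
#'
#' Detects strict local maxima and ranks them by absorbance, global maximum
#' first. Peaks with topographic prominence below `min_prominence` times the
#' absorbance range are dropped, which suppresses noise ripple.
#'
#' @param spectrum a `spectrum_model` (or any list with `wavelength_nm` and
#'   `absorbance`).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   absorbance range (default 0.01).
#' @return Numeric vector of peak wavelengths in nm sorted by descending
#'   absorbance; empty when the spectrum has no local maxima (e.g. flat).
#' @export
find_peaks <- function(spectrum, min_prominence = 0.01) {
  wl <- spectrum$wavelength_nm
  ab <- spectrum$absorbance
  n <- length(ab)
  if (n < 3L) stop("need at least 3 grid points to find peaks")
  rng <- diff(range(ab))
  if (rng == 0) return(numeric(0))
  interior <- 2:(n - 1)
  is_peak <- ab[interior] > ab[interior - 1] & ab[interior] > ab[interior + 1]
  idx <- interior[is_peak]
  # endpoints count when they dominate their single neighbour
  if (ab[1] > ab[2]) idx <- c(1L, idx)
  if (ab[n] > ab[n - 1]) idx <- c(idx, n)
  if (length(idx) == 0L) return(numeric(0))
  prominence <- vapply(idx, function(i) {
    h <- ab[i]
    left <- ab[seq_len(i - 1)]
    right <- ab[seq(i + 1, n)][seq_len(max(0, n - i))]
    valley <- function(side) {
      if (length(side) == 0L) return(min(ab))
      higher <- which(side > h)
      if (length(higher) == 0L) min(side) else NA_real_
    }
    # walk outwards to the nearest higher ground; the key saddle bounds the
    # prominence on each side
    lv <- {
      s <- rev(left)
      hi <- which(s >= h)
      if (length(hi) == 0L) min(left, h) else min(s[seq_len(hi[1])])
    }
    rv <- {
      s <- right
      hi <- which(s >= h)
      if (length(hi) == 0L) min(right, h) else min(s[seq_len(hi[1])])
    }
    h - max(lv, rv)
  }, numeric(1))
  keep <- prominence >= min_prominence * rng
  idx <- idx[keep]
  if (length(idx) == 0L) return(numeric(0))
  wl[idx[order(ab[idx], decreasing = TRUE)]]
}
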