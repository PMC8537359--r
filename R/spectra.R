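#' Wavelength-intensity spectrum trace
#'
#' @param wavelength wavelengths (nm), strictly increasing.
#' @param intensity non-negative intensities (a.u.), same length.
#' @return data.frame of class `spectrum_trace` with columns
#'   `wavelength`, `intensity`.
#' @export
spectrum_trace <- function(wavelength, intensity) {
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity must have equal length")
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(data.frame(wavelength = as.numeric(wavelength),
                       intensity = as.numeric(intensity)),
            class = c("spectrum_trace", "data.frame"))
}

#' Read / write a spectrum as a two-column CSV
#'
#' Plain CSV with columns `wavelength_nm`, `intensity` — the interchange
#' format of benchtop spectrometer exports.
#'
#' @param path CSV file path.
#' @return [spectrum_trace()] (read) or the path, invisibly (write).
#' @export
read_spectrum_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(d)))
    stop("spectrum CSV needs columns wavelength_nm, intensity")
  spectrum_trace(d$wavelength_nm, d$intensity)
}

#' @rdname read_spectrum_csv
#' @param s a [spectrum_trace()].
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_trace"))
  write.csv(data.frame(wavelength_nm = s$wavelength, intensity = s$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' Peak wavelength of a spectrum, stabilised by moving-average smoothing
#'
#' Argmax of the trace after a centred moving average (default 5 points),
#' which keeps single-pixel grid noise from dictating the peak — used to
#' read emission-peak shifts (the CQD peak moves from ~440 nm toward
#' ~470 nm, roughly in proportion to cytochrome c concentration).
#'
#' @param s a [spectrum_trace()].
#' @param smooth_window odd window size in grid points; 1 disables smoothing.
#' @return peak wavelength (nm).
#' @export
peak_wavelength <- function(s, smooth_window = 5) {
  stopifnot(inherits(s, "spectrum_trace"), smooth_window >= 1,
            smooth_window %% 2 == 1)
  y <- s$intensity
  if (smooth_window > 1 && length(y) >= smooth_window) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(y, k, sides = 2)
    half <- (smooth_window - 1) / 2
    sm[seq_len(half)] <- y[seq_len(half)]              # keep edges unsmoothed
    n <- length(y)
    sm[(n - half + 1):n] <- y[(n - half + 1):n]
    y <- as.numeric(sm)
  }
  s$wavelength[which.max(y)]
}
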