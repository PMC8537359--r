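#' Integrated emission area under a spectrum
#'
#' Trapezoidal area under the trace over a wavelength window, on the native
#' grid; the window edges are included by linear interpolation when they
#' fall between grid points. This is the "area under the fluorescence
#' curve" A entering the relative quantum-yield ratio.
#'
#' @param s a [spectrum_trace()].
#' @param window `c(lo, hi)` in nm; must lie within the trace's range.
#' @return area (a.u. * nm), non-negative for non-negative traces.
#' @export
integrate_emission <- function(s, window = range(s$wavelength)) {
  stopifnot(inherits(s, "spectrum_trace"), length(window) == 2)
  if (window[2] <= window[1]) stop("integration window is empty")
  if (window[1] < min(s$wavelength) || window[2] > max(s$wavelength))
    stop("window must lie within the trace's wavelength range")
  keep <- s$wavelength >= window[1] & s$wavelength <= window[2]
  w <- s$wavelength[keep]
  y <- s$intensity[keep]
  for (edge in window) {
    if (!any(w == edge)) {
      yi <- approx(s$wavelength, s$intensity, xout = edge)$y
      w <- c(w, edge); y <- c(y, yi)
    }
  }
  o <- order(w)
  trapz_area(w[o], y[o])
}

trapz_area <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' A quantum-yield measurement
#'
#' Bundles the three quantities entering the relative (Demas-Crosby)
#' quantum-yield ratio: integrated emission area `A`, absorbance `Abs` at
#' the excitation wavelength, and the solvent refractive index `eta`.
#' `phi` is required for the reference standard (quinine bisulphate in
#' 0.1 M H2SO4 has phi = 0.54) and NA for an unknown sample.
#'
#' @param A integrated emission area (a.u. * nm), >= 0.
#' @param Abs absorbance at the excitation wavelength, > 0. Values above
#'   0.1 leave the linear (inner-filter-free) regime and trigger a warning
#'   downstream.
#' @param eta solvent refractive index, >= 1 (water: 1.33).
#' @param phi known quantum yield (standards only).
#' @param excitation_nm excitation wavelength, recorded for provenance.
#' @return object of class `qy_measurement`.
#' @export
qy_measurement <- function(A, Abs, eta = 1.33, phi = NA_real_,
                           excitation_nm = 360) {
  if (A < 0) stop("integrated area A must be >= 0")
  if (Abs <= 0) stop("absorbance must be > 0")
  if (eta < 1) stop("refractive index must be >= 1")
  structure(list(A = A, Abs = Abs, eta = eta, phi = phi,
                 excitation_nm = excitation_nm),
            class = "qy_measurement")
}

#' Relative quantum yield (Demas-Crosby ratio method)
#'
#' phi_x = phi_st * (A_x / A_st) * (Abs_st / Abs_x) * (eta_x / eta_st)^2,
#' the standard single-point relative method against a reference of known
#' quantum yield. A warning (not an error) is raised when either
#' absorbance exceeds 0.1, the conventional ceiling for the linear regime
#' free of inner filter effects.
#'
#' @param sample [qy_measurement()] for the unknown.
#' @param standard [qy_measurement()] for the reference; `phi` must be set.
#' @return quantum yield of the sample (fraction).
#' @export
quantum_yield <- function(sample, standard) {
  stopifnot(inherits(sample, "qy_measurement"),
            inherits(standard, "qy_measurement"))
  if (is.na(standard$phi)) stop("standard must have a known phi")
  if (sample$Abs > 0.1 || standard$Abs > 0.1)
    warning("absorbance above 0.1: outside the linear regime, ",
            "inner filter effects may bias the quantum yield")
  standard$phi * (sample$A / standard$A) * (standard$Abs / sample$Abs) *
    (sample$eta / standard$eta)^2
}

#' Fit a monotone quench model to a concentration series
#'
#' Least-squares fit of relative intensity I(c)/I(0) over a concentration
#' grid to either the Stern-Volmer form 1 / (1 + K c) or the
#' inner-filter-effect exponential 10^(-k c). The series must include the
#' c = 0 reference point, which defines I(0).
#'
#' @param concentrations µM, >= 3 values including 0.
#' @param intensities measured intensities (a.u.), same length.
#' @param model `"stern_volmer"` or `"ife_exponential"`.
#' @return a [quench_calibration()] carrying the fitted parameter, the
#'   grid, the fitted relative intensities and the residuals.
#' @export
fit_quench_curve <- function(concentrations, intensities,
                             model = c("stern_volmer", "ife_exponential")) {
  model <- match.arg(model)
  if (length(concentrations) != length(intensities))
    stop("concentrations and intensities must have equal length")
  if (length(concentrations) < 3)
    stop("need at least 3 concentration points")
  if (!any(concentrations == 0))
    stop("the series must include the c = 0 reference point")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (any(intensities <= 0)) stop("intensities must be positive")
  o <- order(concentrations)
  conc <- concentrations[o]
  I0 <- mean(intensities[o][conc == 0])
  y <- intensities[o] / I0

  if (model == "stern_volmer") {
    # linearisation I0/I - 1 = K c gives the exact least-squares start
    K0 <- max(0, sum(conc * (1 / y - 1)) / sum(conc^2))
    fit <- minpack.lm::nlsLM(y ~ 1 / (1 + K * conc), start = list(K = K0),
                             lower = 0, control = nls.control(maxiter = 200))
    par <- c(K = unname(coef(fit)[["K"]]))
    pred <- 1 / (1 + par[["K"]] * conc)
  } else {
    k0 <- max(0, sum(conc * (-log10(pmax(y, 1e-12)))) / sum(conc^2))
    fit <- minpack.lm::nlsLM(y ~ 10^(-k * conc), start = list(k = k0),
                             lower = 0, control = nls.control(maxiter = 200))
    par <- c(k = unname(coef(fit)[["k"]]))
    pred <- 10^(-par[["k"]] * conc)
  }
  cal <- quench_calibration(model, K = if (model == "stern_volmer") par[["K"]] else 0.04,
                            k = if (model == "ife_exponential") par[["k"]] else 0.012)
  cal$params <- par
  cal$concentration <- conc
  cal$rel_intensity <- pred
  cal$residuals <- y - pred
  cal
}

#' @export
print.quench_calibration <- function(x, ...) {
  cat(sprintf("quench_calibration [%s]: %s\n", x$model,
              paste(names(x$params), signif(x$params, 6),
                    sep = " = ", collapse = ", ")))
  if (!is.null(x$residuals))
    cat(sprintf("  fitted on %d points, RMS residual %.3g\n",
                length(x$residuals), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Save / load a quench calibration as JSON
#' @param cal a [quench_calibration()].
#' @param path JSON file path.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "quench_calibration"))
  jsonlite::write_json(list(model = cal$model, params = as.list(cal$params),
                            concentration = cal$concentration,
                            rel_intensity = cal$rel_intensity),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal <- quench_calibration(d$model,
                            K = if (d$model == "stern_volmer") d$params$K else 0.04,
                            k = if (d$model == "ife_exponential") d$params$k else 0.012)
  cal$concentration <- d$concentration
  cal$rel_intensity <- d$rel_intensity
  cal
}

#' Segment means and step drops of a stepwise quench time course
#'
#' For a recording during which quencher aliquots are added at known times
#' (e.g. cytochrome c to 10, 20 and 30 µM at 5, 10 and 15 min), splits the
#' trace into segments between additions, reports each segment's mean
#' intensity and the successive drops (differences of consecutive segment
#' means; expected <= 0 for a quencher).
#'
#' @param times sample times (s), non-decreasing.
#' @param intensities intensities (a.u.), same length.
#' @param addition_times times of quencher additions (s), sorted, within
#'   the recording window.
#' @return list with `segment_means`, `drops`, `segments` (per-segment
#'   time ranges and point counts).
#' @export
stepwise_quench_timecourse <- function(times, intensities,
                                       addition_times = numeric(0)) {
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (is.unsorted(times)) stop("times must be sorted")
  if (length(addition_times)) {
    if (is.unsorted(addition_times, strictly = TRUE))
      stop("addition times must be strictly increasing")
    if (min(addition_times) <= min(times) || max(addition_times) >= max(times))
      stop("addition times must fall inside the recording window")
  }
  breaks <- c(-Inf, addition_times, Inf)
  seg <- cut(times, breaks, labels = FALSE, right = FALSE)
  means <- tapply(intensities, seg, mean)
  counts <- tapply(intensities, seg, length)
  lo <- tapply(times, seg, min)
  hi <- tapply(times, seg, max)
  list(segment_means = as.numeric(means),
       drops = diff(as.numeric(means)),
       segments = data.frame(segment = seq_along(means),
                             t_start = as.numeric(lo), t_end = as.numeric(hi),
                             n = as.integer(counts)))
}

#' Spectral overlap between an emission and an absorbance spectrum
#'
#' Shape overlap on the traces' common wavelength grid: both curves are
#' normalised and the cross integral is rescaled so that identical shapes
#' score exactly 1 and disjoint supports score 0 (the cosine similarity of
#' the two curves under the L2 inner product). A large overlap between the
#' fluorophore's emission and the quencher's absorption is the signature
#' of inner-filter-effect quenching.
#'
#' @param emission,absorbance [spectrum_trace()] objects; each must be
#'   non-zero somewhere.
#' @return overlap fraction in `[0, 1]`; symmetric in its arguments.
#' @export
spectral_overlap <- function(emission, absorbance) {
  stopifnot(inherits(emission, "spectrum_trace"),
            inherits(absorbance, "spectrum_trace"))
  if (all(emission$intensity == 0) || all(absorbance$intensity == 0))
    stop("spectral_overlap: all-zero input trace")
  lo <- max(min(emission$wavelength), min(absorbance$wavelength))
  hi <- min(max(emission$wavelength), max(absorbance$wavelength))
  if (lo >= hi) return(0)
  grid <- sort(unique(c(
    emission$wavelength[emission$wavelength >= lo & emission$wavelength <= hi],
    absorbance$wavelength[absorbance$wavelength >= lo & absorbance$wavelength <= hi],
    lo, hi)))
  e <- approx(emission$wavelength, emission$intensity, xout = grid)$y
  a <- approx(absorbance$wavelength, absorbance$intensity, xout = grid)$y
  cross <- trapz_area(grid, e * a)
  # normalisation uses each trace's full support, so truncation to the
  # common window penalises partial overlap
  ee <- trapz_area(emission$wavelength, emission$intensity^2)
  aa <- trapz_area(absorbance$wavelength, absorbance$intensity^2)
  if (ee == 0 || aa == 0) return(0)
  min(1, max(0, cross / sqrt(ee * aa)))
}

#' Photostability drift of a fluorescence time series
#'
#' Ordinary least-squares slope of intensity against time, the two-sided p
#' for slope = 0, and the relative change of the fitted line across the
#' recording window — the standard summary for a photostability run (e.g.
#' 1 h at 10-s sampling: stable dots show a slope indistinguishable from
#' zero).
#'
#' @param times times (s), at least 3 distinct values.
#' @param intensities intensities (a.u.), same length.
#' @return list with `slope` (a.u./s), `p_value`, `relative_change`
#'   (fitted end minus fitted start over fitted start), `intercept`.
#' @export
photostability_drift <- function(times, intensities) {
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (length(times) < 3) stop("need at least 3 time points")
  if (length(unique(times)) < 2) stop("time vector is constant")
  fit <- lm(intensities ~ times)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  slope <- unname(coef(fit)[2])
  p <- if (nrow(sm$coefficients) >= 2 && !is.nan(sm$coefficients[2, 4]))
    sm$coefficients[2, 4] else 1
  f0 <- unname(coef(fit)[1] + slope * min(times))
  f1 <- unname(coef(fit)[1] + slope * max(times))
  list(slope = slope, p_value = unname(p),
       relative_change = if (f0 != 0) (f1 - f0) / f0 else 0,
       intercept = unname(coef(fit)[1]))
}
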