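# Spectral bookkeeping: spectrum containers and file dialect, attenuation
# conversions, the chord-subtended blood-filling index, and the synthetic
# clinical-spectrum generator.

#' Construct a spectrum
#'
#' @param wavelengths Strictly ascending wavelength grid, nm.
#' @param values Nonnegative intensities (counts or normalized units).
#' @param kind `"sample"` (measured intensity I) or `"reference"` (the
#'   reference-reflector intensity I0).
#' @return A data.frame of class `drs_spectrum` with columns
#'   `wavelength_nm` and `intensity`.
#' @export
spectrum <- function(wavelengths, values, kind = c("sample", "reference")) {
  kind <- match.arg(kind)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  }
  if (any(values < 0)) stop("intensities must be nonnegative", call. = FALSE)
  out <- data.frame(wavelength_nm = as.numeric(wavelengths),
                    intensity = as.numeric(values))
  attr(out, "kind") <- kind
  class(out) <- c("drs_spectrum", "data.frame")
  out
}

#' Read / write the two-column spectrum dialect
#'
#' Spectrum files are plain delimited text with header
#' `wavelength_nm,intensity`.
#'
#' @param path File path.
#' @param kind Passed to [spectrum()].
#' @return `read_spectrum()` returns a `drs_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, kind = c("sample", "reference")) {
  d <- read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(d))) {
    stop("spectrum file must have columns wavelength_nm,intensity",
         call. = FALSE)
  }
  spectrum(d$wavelength_nm, d$intensity, kind = match.arg(kind))
}

#' @rdname read_spectrum
#' @param x A `drs_spectrum`.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "drs_spectrum"))
  write.csv(as.data.frame(x)[, c("wavelength_nm", "intensity")], path,
            row.names = FALSE)
  invisible(path)
}

#' Attenuation from paired sample and reference spectra
#'
#' Pointwise attenuation `A = ln(I0 / I)` of a sample spectrum against the
#' reference-reflector spectrum recorded with the same probe.
#'
#' @param sample,reference `drs_spectrum` objects on identical grids with
#'   strictly positive intensities.
#' @return A data.frame of class `drs_attenuation` with columns
#'   `wavelength_nm` and `A`.
#' @export
attenuation_from_intensities <- function(sample, reference) {
  stopifnot(inherits(sample, "drs_spectrum"),
            inherits(reference, "drs_spectrum"))
  if (!isTRUE(all.equal(sample$wavelength_nm, reference$wavelength_nm))) {
    stop("sample and reference wavelength grids differ", call. = FALSE)
  }
  bad <- which(sample$intensity <= 0 | reference$intensity <= 0)
  if (length(bad)) {
    stop("nonpositive intensity at ", sample$wavelength_nm[bad[1]], " nm",
         call. = FALSE)
  }
  out <- data.frame(wavelength_nm = sample$wavelength_nm,
                    A = log(reference$intensity / sample$intensity))
  class(out) <- c("drs_attenuation", "data.frame")
  out
}

#' Attenuation from simulated diffuse reflectance
#'
#' Converts detected diffuse reflectance to `ln(1/Rd)`, the form in which
#' simulated spectra are compared with measured attenuation (equivalent to
#' [attenuation_from_intensities()] with unit reference).
#'
#' @param x A `drs_tally` (its detected `Rd` column is used) or a numeric
#'   vector of reflectance values in (0, 1\].
#' @param wavelengths Wavelengths in nm when `x` is numeric.
#' @return A `drs_attenuation` data.frame.
#' @export
attenuation_from_reflectance <- function(x, wavelengths = NULL) {
  if (inherits(x, "drs_tally")) {
    wavelengths <- x$wavelength_nm
    rd <- x$Rd
  } else {
    rd <- as.numeric(x)
    if (is.null(wavelengths)) wavelengths <- seq_along(rd)
  }
  if (any(rd <= 0)) {
    stop("reflectance must be positive to form ln(1/Rd)", call. = FALSE)
  }
  out <- data.frame(wavelength_nm = wavelengths, A = log(1 / rd))
  class(out) <- c("drs_attenuation", "data.frame")
  out
}

#' Blood-filling index of a diffuse-reflectance spectrum
#'
#' Relative perfusion index: the area between the recorded spectrum and
#' the straight line subtending it over the analysis band (default
#' 500--600 nm). The line is the chord through the spectrum's values at
#' the band endpoints; for a concave-down hemoglobin absorption dip it
#' touches the spectrum at the endpoints, and the enclosed area grows with
#' the amount of blood in the probed volume. The integrand is clipped at
#' zero so that noise excursions above the chord do not contribute.
#'
#' @param sample A `drs_spectrum`.
#' @param band Length-2 numeric, analysis band in nm (default
#'   `c(500, 600)`).
#' @param normalize Divide the spectrum by its value at the band's left
#'   endpoint before integrating (area in relative units); default `FALSE`
#'   integrates raw intensities. Units are arbitrary either way.
#' @return Nonnegative area (nm times intensity units).
#' @export
blood_filling_area <- function(sample, band = c(500, 600),
                               normalize = FALSE) {
  stopifnot(inherits(sample, "drs_spectrum"), length(band) == 2)
  wl <- sample$wavelength_nm
  v <- sample$intensity
  if (band[1] < min(wl) || band[2] > max(wl)) {
    stop("band lies outside the spectrum grid", call. = FALSE)
  }
  inb <- wl >= band[1] & wl <= band[2]
  if (sum(inb) < 3) stop("need at least 3 grid points inside the band",
                         call. = FALSE)
  wl <- wl[inb]; v <- v[inb]
  if (normalize) v <- v / v[1]
  chord <- v[1] + (v[length(v)] - v[1]) * (wl - wl[1]) /
    (wl[length(wl)] - wl[1])
  f <- pmax(chord - v, 0)
  # trapezoid rule
  sum(diff(wl) * (f[-1] + f[-length(f)]) / 2)
}

#' Synthesize a clinical-style diffuse reflectance spectrum
#'
#' Forward-models a recorded spectrum from the attenuation model: a
#' polynomial baseline plus hemoglobin basis attenuation, exponentiated
#' against a reference-reflector spectrum, with i.i.d. multiplicative
#' Gaussian noise:
#' `I(lambda) = I0(lambda) * exp(-A_model(lambda)) * (1 + eps)`.
#' With `noise_sd = 0` the forward model is reproduced exactly, so the
#' attenuation/inversion chain recovers the generating parameters.
#'
#' @param params Named list or vector with baseline coefficients `c0`,
#'   `c1`, `c2` (on raw nm wavelengths; missing terms default to 0) and
#'   nonnegative lumped amplitudes `amp_Hb`, `amp_HbO2` multiplying the
#'   chromophore basis rows.
#' @param reference A `drs_spectrum` used as I0.
#' @param noise_sd Relative (multiplicative) noise standard deviation.
#' @param seed Integer seed for the noise.
#' @param table Chromophore basis, a [chromophore_table()]; its grid must
#'   contain the reference grid.
#' @return A `drs_spectrum` of kind `"sample"`.
#' @export
synthesize_clinical_spectrum <- function(params, reference, noise_sd = 0,
                                         seed = 1,
                                         table = chromophore_table()) {
  stopifnot(inherits(reference, "drs_spectrum"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  p <- as.list(params)
  for (k in c("c0", "c1", "c2")) if (is.null(p[[k]])) p[[k]] <- 0
  if (is.null(p$amp_Hb) || is.null(p$amp_HbO2)) {
    stop("params must include amp_Hb and amp_HbO2", call. = FALSE)
  }
  if (p$amp_Hb < 0 || p$amp_HbO2 < 0) {
    stop("chromophore amplitudes must be nonnegative", call. = FALSE)
  }
  wl <- reference$wavelength_nm
  A <- model_attenuation(wl, p$c0, p$c1, p$c2, p$amp_Hb, p$amp_HbO2, table)
  I <- reference$intensity * exp(-A)
  if (noise_sd > 0) {
    set.seed(seed %% .Machine$integer.max)
    I <- I * (1 + rnorm(length(I), 0, noise_sd))
    I <- pmax(I, .Machine$double.eps)
  }
  spectrum(wl, I, kind = "sample")
}

#' Evaluate the attenuation forward model
#'
#' `A(lambda) = c0 + c1*lambda + c2*lambda^2 + amp_Hb*mu_a_Hb(lambda) +
#' amp_HbO2*mu_a_HbO2(lambda)`, with the mean photon pathlength and molar
#' extinction scaling lumped into the amplitudes.
#'
#' @param wavelengths Wavelengths in nm, on the chromophore grid.
#' @param c0,c1,c2 Polynomial baseline coefficients (raw nm scale).
#' @param amp_Hb,amp_HbO2 Lumped chromophore amplitudes.
#' @param table A [chromophore_table()].
#' @return Numeric attenuation values.
#' @export
model_attenuation <- function(wavelengths, c0 = 0, c1 = 0, c2 = 0,
                              amp_Hb = 0, amp_HbO2 = 0,
                              table = chromophore_table()) {
  idx <- match(wavelengths, table$wavelengths_nm)
  if (anyNA(idx)) {
    stop("wavelength(s) not on the chromophore grid", call. = FALSE)
  }
  c0 + c1 * wavelengths + c2 * wavelengths^2 +
    amp_Hb * table$mu_a_Hb[idx] + amp_HbO2 * table$mu_a_HbO2[idx]
}
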