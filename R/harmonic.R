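#' Harmonic vibrational mode set
#'
#' Discrete Raman-active vibrational modes from a harmonic (double-harmonic)
#' calculation: frequencies in cm^-1 with Raman activities (A^4 amu^-1) and,
#' once converted, intensities.
#'
#' @param frequency Numeric vector of positive mode frequencies, cm^-1.
#' @param activity Numeric vector of non-negative Raman activities, same
#'   length (may be NULL if `intensity` is supplied directly).
#' @param intensity Optional numeric vector of intensities.
#' @param scale_factor Dimensionless frequency scaling factor already applied
#'   (bookkeeping only; 1 for unscaled).
#' @return An object of class `harmonic_modes`.
#' @export
harmonic_modes <- function(frequency, activity = NULL, intensity = NULL,
                           scale_factor = 1) {
  frequency <- as.numeric(frequency)
  if (length(frequency) && (!all(is.finite(frequency)) || any(frequency <= 0))) {
    stop("mode frequencies must be positive and finite", call. = FALSE)
  }
  if (!is.null(activity)) {
    activity <- as.numeric(activity)
    if (length(activity) != length(frequency)) {
      stop("activity must match frequency in length", call. = FALSE)
    }
    if (any(activity < 0)) stop("activities must be non-negative", call. = FALSE)
  }
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != length(frequency)) {
      stop("intensity must match frequency in length", call. = FALSE)
    }
  }
  if (!is.finite(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be positive", call. = FALSE)
  }
  structure(list(frequency = frequency, activity = activity,
                 intensity = intensity, scale_factor = scale_factor),
            class = "harmonic_modes")
}

#' @export
print.harmonic_modes <- function(x, ...) {
  cat(sprintf("<harmonic_modes: %d modes%s%s, scale_factor %.6g>\n",
              length(x$frequency),
              if (!is.null(x$activity)) " +activities" else "",
              if (!is.null(x$intensity)) " +intensities" else "",
              x$scale_factor))
  invisible(x)
}

#' Read a harmonic mode table from CSV
#'
#' Expects a header `frequency_cm1,activity` (or `frequency_cm1,intensity`).
#'
#' @param path CSV file path.
#' @return A [harmonic_modes()] object.
#' @export
read_modes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"frequency_cm1" %in% names(df)) {
    stop("mode table must have a 'frequency_cm1' column", call. = FALSE)
  }
  harmonic_modes(df$frequency_cm1,
                 activity = if ("activity" %in% names(df)) df$activity,
                 intensity = if ("intensity" %in% names(df)) df$intensity)
}

#' @rdname read_modes
#' @param modes A [harmonic_modes()] object.
#' @export
write_modes <- function(modes, path) {
  df <- data.frame(frequency_cm1 = modes$frequency)
  if (!is.null(modes$activity)) df$activity <- modes$activity
  if (!is.null(modes$intensity)) df$intensity <- modes$intensity
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Conversion parameters for the activity-to-intensity step
#'
#' Holds the excitation laser wavelength and sample temperature, and derives
#' the excitation wavenumber nu0 = 1e7 / lambda(nm) cm^-1 and the second
#' radiation constant c2 = h*c/k_B in cm*K.
#'
#' @param laser_nm Excitation wavelength in nm (default 532).
#' @param temperature_K Sample temperature in K (default 293).
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(laser_nm = 532, temperature_K = 293) {
  if (laser_nm <= 0 || temperature_K <= 0) {
    stop("laser wavelength and temperature must be positive", call. = FALSE)
  }
  structure(list(
    laser_nm = laser_nm,
    temperature_K = temperature_K,
    nu0_cm1 = 1e7 / laser_nm,
    # h * c / k_B in cm K (2018 CODATA)
    c2_cmK = 1.4387768775039337
  ), class = "conversion_params")
}

#' Broadening parameters for line-shape synthesis
#'
#' @param fwhm Lorentzian full width at half maximum, cm^-1 (default 5).
#' @param lo,hi,step Synthesis grid in cm^-1. Defaults cover the 600-1600
#'   cm^-1 experimental window at 0.5 cm^-1; `step` must not exceed `fwhm/2`
#'   so that the line is sampled adequately.
#' @return An object of class `broadening_params`.
#' @export
broadening_params <- function(fwhm = 5, lo = 600, hi = 1600, step = 0.5) {
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  if (step <= 0 || lo >= hi) stop("invalid grid specification", call. = FALSE)
  if (step > fwhm / 2) {
    stop("grid step must be <= fwhm/2 to resolve the line", call. = FALSE)
  }
  structure(list(fwhm = fwhm, lo = lo, hi = hi, step = step),
            class = "broadening_params")
}

#' Apply a frequency scaling factor to a harmonic mode set
#'
#' Harmonic DFT frequencies are systematically offset from experiment;
#' multiplying by an empirical scalar (typically 0.96-1.00) corrects this.
#' Activities and intensities are untouched.
#'
#' @param modes A [harmonic_modes()] object.
#' @param factor Positive dimensionless scaling factor.
#' @return A scaled `harmonic_modes` object; `scale_factor` accumulates.
#' @export
scale_frequencies <- function(modes, factor) {
  if (!inherits(modes, "harmonic_modes")) stop("expected harmonic_modes", call. = FALSE)
  if (!is.finite(factor) || factor <= 0) {
    stop("invalid parameter: scaling factor must be positive", call. = FALSE)
  }
  harmonic_modes(modes$frequency * factor, activity = modes$activity,
                 intensity = modes$intensity,
                 scale_factor = modes$scale_factor * factor)
}

#' Convert Raman activities to intensities
#'
#' Applies the standard conversion accounting for the excitation wavenumber
#' and the thermal (Boltzmann) population of the vibrational ground state:
#'
#' \deqn{I_i \propto \frac{(\tilde\nu_0-\tilde\nu_i)^4\,S_i}
#'   {\tilde\nu_i\,[1-\exp(-c_2\tilde\nu_i/T)]}}
#'
#' The overall proportionality constant is irrelevant downstream because
#' spectra are max-normalized.
#'
#' @param modes A [harmonic_modes()] with activities populated.
#' @param params A [conversion_params()] (default 532 nm, 293 K).
#' @return A `harmonic_modes` object with the `intensity` field populated.
#' @export
activity_to_intensity <- function(modes, params = conversion_params()) {
  if (!inherits(modes, "harmonic_modes")) stop("expected harmonic_modes", call. = FALSE)
  if (is.null(modes$activity)) stop("mode set has no activities", call. = FALSE)
  nu <- modes$frequency
  if (any(nu >= params$nu0_cm1)) {
    stop("unsupported mode: frequency at or above the excitation wavenumber",
         call. = FALSE)
  }
  boltz <- 1 - exp(-params$c2_cmK * nu / params$temperature_K)
  I <- (params$nu0_cm1 - nu)^4 * modes$activity / (nu * boltz)
  harmonic_modes(nu, activity = modes$activity, intensity = I,
                 scale_factor = modes$scale_factor)
}

#' Broaden a harmonic mode set with Lorentzian line shapes
#'
#' Each mode becomes an area-normalized Lorentzian scaled by its intensity,
#'
#' \deqn{I(\tilde\nu)=\sum_i I_i\,\frac{\Gamma/2\pi}
#'   {(\tilde\nu-\tilde\nu_i)^2+(\Gamma/2)^2}}
#'
#' so the integrated area of each line equals its intensity I_i. For a
#' uniform Gamma this differs from height scaling only by a global constant,
#' which max-normalization removes.
#'
#' @param modes A [harmonic_modes()] with intensities populated (run
#'   [activity_to_intensity()] first if you only have activities).
#' @param params A [broadening_params()] giving Gamma and the output grid.
#' @return A `raman_spectrum` on the requested grid.
#' @export
lorentzian_broaden <- function(modes, params = broadening_params()) {
  if (!inherits(modes, "harmonic_modes")) stop("expected harmonic_modes", call. = FALSE)
  if (length(modes$frequency) == 0L) stop("empty mode set", call. = FALSE)
  I <- modes$intensity
  if (is.null(I)) stop("mode intensities not populated; run activity_to_intensity",
                       call. = FALSE)
  grid <- seq(params$lo, params$hi, by = params$step)
  gamma <- params$fwhm
  hw2 <- (gamma / 2)^2
  y <- numeric(length(grid))
  for (k in seq_along(modes$frequency)) {
    y <- y + I[k] * (gamma / (2 * pi)) / ((grid - modes$frequency[k])^2 + hw2)
  }
  raman_spectrum(grid, y, label = "broadened")
}
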