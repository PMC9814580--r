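#' Construct a Raman spectrum
#'
#' A spectrum is the universal currency of the package: a strictly increasing
#' wavenumber grid with one intensity per grid point, plus a free-text label
#' (typically a conformer region name such as `"syn/south"`).
#'
#' @param grid Numeric vector of wavenumbers in cm^-1, strictly increasing,
#'   length >= 2.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `grid`.
#' @param label Free-text label for the spectrum.
#' @return An object of class `raman_spectrum` with fields `grid`,
#'   `intensities` and `label`.
#' @examples
#' s <- raman_spectrum(c(600, 700, 800), c(0.1, 1, 0.2), label = "example")
#' s
#' @export
raman_spectrum <- function(grid, intensities, label = "") {
  grid <- as.numeric(grid)
  intensities <- as.numeric(intensities)
  if (length(grid) < 2L) {
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  }
  if (length(grid) != length(intensities)) {
    stop("grid and intensities must have the same length", call. = FALSE)
  }
  if (anyNA(grid) || anyNA(intensities) || !all(is.finite(grid))) {
    stop("grid and intensities must be finite", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  structure(
    list(grid = grid, intensities = intensities, label = as.character(label)[1]),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum%s: %d points, %.6g-%.6g cm-1, max intensity %.6g>\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$grid), min(x$grid), max(x$grid), max(x$intensities)
  ))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "raman_spectrum")

assert_spectrum <- function(x) {
  if (!is_spectrum(x)) stop("expected a raman_spectrum object", call. = FALSE)
  x
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Cubic-spline interpolation onto `grid`. Points outside the input spectrum's
#' domain get intensity 0 rather than extrapolated spline values: shifted or
#' rescaled sub-spectra can probe abscissae beyond a sub-spectrum's measured
#' range, and extrapolated cubics diverge.
#'
#' @param spec A [raman_spectrum()].
#' @param grid Strictly increasing numeric vector of target wavenumbers.
#' @return A `raman_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spec, grid) {
  assert_spectrum(spec)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing", call. = FALSE)
  if (length(spec$grid) < 4L) {
    stop("insufficient data: cubic-spline resampling needs at least 4 input points",
         call. = FALSE)
  }
  f <- stats::splinefun(spec$grid, spec$intensities, method = "fmm")
  y <- f(grid)
  y[grid < spec$grid[1] | grid > spec$grid[length(spec$grid)]] <- 0
  raman_spectrum(grid, y, label = spec$label)
}

#' Normalize a spectrum to unit maximum
#'
#' Divides all intensities by the maximum intensity found within `window`
#' (default: the whole grid). Idempotent.
#'
#' @param spec A [raman_spectrum()].
#' @param window Optional `c(lo, hi)` in cm^-1 restricting where the maximum
#'   is taken; the division still applies to the whole spectrum.
#' @return A `raman_spectrum` whose maximum over `window` is exactly 1.
#' @export
normalize_max <- function(spec, window = NULL) {
  assert_spectrum(spec)
  sel <- rep(TRUE, length(spec$grid))
  if (!is.null(window)) {
    sel <- spec$grid >= window[1] & spec$grid <= window[2]
    if (!any(sel)) stop("normalization window contains no grid points", call. = FALSE)
  }
  m <- max(spec$intensities[sel])
  if (m <= 0) stop("degenerate spectrum: maximum intensity in window is not positive",
                   call. = FALSE)
  raman_spectrum(spec$grid, spec$intensities / m, label = spec$label)
}

#' Pointwise average of spectra sharing a common grid
#'
#' @param spectra List of `raman_spectrum` objects on one common grid
#'   (resample first otherwise).
#' @return A `raman_spectrum`: the pointwise arithmetic mean.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) < 1L) stop("need at least one spectrum", call. = FALSE)
  lapply(spectra, assert_spectrum)
  g <- spectra[[1]]$grid
  for (s in spectra) {
    if (length(s$grid) != length(g) || any(s$grid != g)) {
      stop("grid mismatch: all spectra must share one grid (resample_to_grid first)",
           call. = FALSE)
    }
  }
  y <- Reduce(`+`, lapply(spectra, `[[`, "intensities")) / length(spectra)
  raman_spectrum(g, y, label = sprintf("mean of %d spectra", length(spectra)))
}

#' Read a two-column spectrum file
#'
#' Accepts whitespace- or comma-delimited text with two columns
#' (wavenumber cm^-1, intensity); `#` starts a comment.
#'
#' @param path File path.
#' @param label Label to attach; defaults to the file name.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("spectrum file has fewer than 2 data rows: ", path,
                               call. = FALSE)
  fields <- strsplit(lines, "[,[:space:]]+")
  vals <- vapply(fields, function(f) as.numeric(f[1:2]), numeric(2))
  o <- order(vals[1, ])
  raman_spectrum(vals[1, o], vals[2, o], label = label)
}

#' Write a spectrum as two-column text
#'
#' Tab-separated wavenumber and intensity with 6 significant digits.
#'
#' @param spec A [raman_spectrum()].
#' @param path Output path.
#' @export
write_spectrum <- function(spec, path) {
  assert_spectrum(spec)
  hdr <- sprintf("# wavenumber_cm1\tintensity%s",
                 if (nzchar(spec$label)) paste0("\t# ", spec$label) else "")
  rows <- sprintf("%.6g\t%.6g", spec$grid, spec$intensities)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
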