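#' Polarizability tensor time series
#'
#' @param tensors 3D array (3 x 3 x n) of symmetric polarizability tensors
#'   in atomic units, at a fixed timestep.
#' @param dt_fs Timestep in fs (> 0).
#' @return An object of class `polarizability_trace`.
#' @export
polarizability_trace <- function(tensors, dt_fs) {
  if (!is.array(tensors) || length(dim(tensors)) != 3L ||
      any(dim(tensors)[1:2] != 3L)) {
    stop("tensors must be a 3 x 3 x n array", call. = FALSE)
  }
  if (!is.finite(dt_fs) || dt_fs <= 0) stop("dt_fs must be positive", call. = FALSE)
  asym <- max(abs(tensors - aperm(tensors, c(2, 1, 3))))
  if (asym > 1e-8) {
    stop(sprintf("tensors not symmetric (max asymmetry %.3g a.u.); symmetrize first",
                 asym), call. = FALSE)
  }
  structure(list(tensors = tensors, dt_fs = dt_fs,
                 n = dim(tensors)[3]),
            class = "polarizability_trace")
}

#' @export
print.polarizability_trace <- function(x, ...) {
  cat(sprintf("<polarizability_trace: %d frames at %.4g fs (%.4g ps)>\n",
              x$n, x$dt_fs, x$n * x$dt_fs / 1000))
  invisible(x)
}

#' Dipole-moment time series under an applied field
#'
#' @param vectors n x 3 matrix of dipole vectors, a.u.
#' @param dt_fs Timestep in fs.
#' @param field Applied-field 3-vector in a.u. (zero for the reference run).
#' @return An object of class `dipole_trace`.
#' @export
dipole_trace <- function(vectors, dt_fs, field = c(0, 0, 0)) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) stop("dipole trace must have 3 columns", call. = FALSE)
  if (!is.finite(dt_fs) || dt_fs <= 0) stop("dt_fs must be positive", call. = FALSE)
  structure(list(vectors = vectors, dt_fs = dt_fs, field = as.numeric(field)),
            class = "dipole_trace")
}

#' Read a dipole or polarizability trace from CSV
#'
#' Dipole CSV header: `t_fs,x,y,z`; polarizability CSV header:
#' `t_fs,xx,xy,xz,yy,yz,zz` (upper triangle of the symmetric tensor).
#'
#' @param path CSV file path.
#' @return A [dipole_trace()] or [polarizability_trace()], detected from the
#'   header.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  dt <- df$t_fs[2] - df$t_fs[1]
  if (all(c("x", "y", "z") %in% names(df))) {
    return(dipole_trace(cbind(df$x, df$y, df$z), dt))
  }
  comp <- c("xx", "xy", "xz", "yy", "yz", "zz")
  if (all(comp %in% names(df))) {
    n <- nrow(df)
    tens <- array(0, dim = c(3, 3, n))
    tens[1, 1, ] <- df$xx; tens[2, 2, ] <- df$yy; tens[3, 3, ] <- df$zz
    tens[1, 2, ] <- tens[2, 1, ] <- df$xy
    tens[1, 3, ] <- tens[3, 1, ] <- df$xz
    tens[2, 3, ] <- tens[3, 2, ] <- df$yz
    return(polarizability_trace(tens, dt))
  }
  stop("unrecognized trace header in ", path, call. = FALSE)
}

#' Write a trace to CSV
#'
#' @param trace A [dipole_trace()] or [polarizability_trace()].
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "dipole_trace")) {
    n <- nrow(trace$vectors)
    df <- data.frame(t_fs = (seq_len(n) - 1) * trace$dt_fs,
                     x = trace$vectors[, 1], y = trace$vectors[, 2],
                     z = trace$vectors[, 3])
  } else if (inherits(trace, "polarizability_trace")) {
    tn <- trace$tensors
    df <- data.frame(t_fs = (seq_len(trace$n) - 1) * trace$dt_fs,
                     xx = tn[1, 1, ], xy = tn[1, 2, ], xz = tn[1, 3, ],
                     yy = tn[2, 2, ], yz = tn[2, 3, ], zz = tn[3, 3, ])
  } else stop("expected a trace object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a polarizability trace from finite-field dipole traces
#'
#' Per-frame forward difference against a zero-field reference run:
#' alpha_ij(t) = \[mu_i under field along j (t) - mu_i reference(t)\] / E.
#' If traces under the opposite field are supplied, the central difference
#' \[mu(+E) - mu(-E)\] / 2E is used instead. The raw tensor is symmetrized
#' as (alpha + t(alpha))/2 and the maximum asymmetry is reported.
#'
#' @param reference Zero-field [dipole_trace()].
#' @param ex,ey,ez Dipole traces with the field applied along x, y, z.
#' @param field_strength Field magnitude in a.u. (> 0; default 5e-4).
#' @param ex_minus,ey_minus,ez_minus Optional traces under the negated
#'   field, enabling central differences.
#' @return A [polarizability_trace()] with attribute `max_asymmetry` (a.u.).
#' @export
finite_field_polarizability <- function(reference, ex, ey, ez,
                                        field_strength = 5e-4,
                                        ex_minus = NULL, ey_minus = NULL,
                                        ez_minus = NULL) {
  if (!is.finite(field_strength) || field_strength <= 0) {
    stop("invalid parameter: field strength must be positive", call. = FALSE)
  }
  plus <- list(ex, ey, ez)
  minus <- list(ex_minus, ey_minus, ez_minus)
  central <- !vapply(minus, is.null, logical(1))
  if (any(central) && !all(central)) {
    stop("supply all three negated-field traces or none", call. = FALSE)
  }
  all_tr <- c(list(reference), plus, minus[central])
  n <- nrow(reference$vectors)
  dt <- reference$dt_fs
  for (tr in all_tr) {
    if (!inherits(tr, "dipole_trace")) stop("expected dipole_trace inputs", call. = FALSE)
    if (nrow(tr$vectors) != n || tr$dt_fs != dt) {
      stop("trace mismatch: all dipole traces must share dt and length", call. = FALSE)
    }
  }
  raw <- array(0, dim = c(3, 3, n))
  for (j in 1:3) {
    if (all(central)) {
      dmu <- (plus[[j]]$vectors - minus[[j]]$vectors) / (2 * field_strength)
    } else {
      dmu <- (plus[[j]]$vectors - reference$vectors) / field_strength
    }
    raw[, j, ] <- t(dmu)   # column j: response of mu to field along j
  }
  sym <- (raw + aperm(raw, c(2, 1, 3))) / 2
  max_asym <- max(abs(raw - aperm(raw, c(2, 1, 3)))) / 2
  out <- polarizability_trace(sym, dt)
  attr(out, "max_asymmetry") <- max_asym
  out
}

#' Isotropic / anisotropic decomposition of a polarizability trace
#'
#' Splits each tensor into its isotropic mean alpha_bar(t) = tr(alpha)/3 and
#' traceless anisotropic part beta(t) = alpha - alpha_bar * I, so
#' alpha = alpha_bar I + beta exactly.
#'
#' @param trace A [polarizability_trace()].
#' @return List with `iso` (numeric series) and `aniso` (3 x 3 x n array of
#'   traceless tensors).
#' @export
tensor_invariant_series <- function(trace) {
  if (!inherits(trace, "polarizability_trace")) {
    stop("expected polarizability_trace", call. = FALSE)
  }
  tn <- trace$tensors
  iso <- (tn[1, 1, ] + tn[2, 2, ] + tn[3, 3, ]) / 3
  aniso <- tn
  for (d in 1:3) aniso[d, d, ] <- aniso[d, d, ] - iso
  list(iso = iso, aniso = aniso)
}

#' Autocorrelation with overlap-count (unbiased) normalization
#'
#' C(tau) = mean over overlapping pairs of (x(t) - xbar)(x(t+tau) - xbar),
#' i.e. the lag-tau cross sum divided by (n - tau). Computed by FFT
#' cross-correlation, which is numerically identical to the direct sum.
#' C(0) equals the (population) variance exactly.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag in samples (< length(x)).
#' @return Numeric vector C(0..max_lag).
#' @export
autocorrelation <- function(x, max_lag = length(x) - 1L) {
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the series length", call. = FALSE)
  x <- x - mean(x)
  m <- stats::nextn(2L * n, 2)
  xp <- c(x, numeric(m - n))
  f <- stats::fft(xp)
  r <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  r[seq_len(max_lag + 1L)] / (n - 0:max_lag)
}

#' Configuration for the polarizability spectrum estimator
#'
#' @param window Lag window: `"hann"` (default) or `"none"`.
#' @param max_lag Largest autocorrelation lag, as a fraction of the series
#'   length (default 0.5).
#' @param zero_pad_factor Zero-padding factor >= 1 (default 4); refines the
#'   frequency sampling to 1/(2 * max_lag * zero_pad_factor * dt * c) cm^-1.
#' @param invariant_weights Length-2 weights for the isotropic and
#'   anisotropic spectral contributions; default `c(45, 7)`, the standard
#'   orientational-averaging combination 45 alpha'^2 + 7 gamma'^2.
#' @param quantum_correction `"none"` (default) or `"harmonic"`, the latter
#'   multiplying the spectrum by the harmonic frequency-dependent factor
#'   c2 nu / T / (1 - exp(-c2 nu / T)).
#' @param temperature_K Temperature for the quantum correction (default 300).
#' @return An object of class `spectrum_estimator_config`.
#' @export
spectrum_estimator_config <- function(window = c("hann", "none"),
                                      max_lag = 0.5, zero_pad_factor = 4,
                                      invariant_weights = c(45, 7),
                                      quantum_correction = c("none", "harmonic"),
                                      temperature_K = 300) {
  window <- match.arg(window)
  quantum_correction <- match.arg(quantum_correction)
  if (max_lag <= 0 || max_lag > 1) stop("max_lag must be in (0, 1]", call. = FALSE)
  if (zero_pad_factor < 1) stop("zero_pad_factor must be >= 1", call. = FALSE)
  if (any(invariant_weights < 0) || all(invariant_weights == 0)) {
    stop("invariant weights must be non-negative and not both zero", call. = FALSE)
  }
  structure(list(window = window, max_lag = max_lag,
                 zero_pad_factor = zero_pad_factor,
                 invariant_weights = invariant_weights,
                 quantum_correction = quantum_correction,
                 temperature_K = temperature_K),
            class = "spectrum_estimator_config")
}

# speed of light in cm/fs
.c_cm_per_fs <- 2.99792458e-5

# Power spectrum of a one-sided ACF: even extension, optional Hann lag
# window, zero padding, real FFT. Mean of the returned spectrum over all
# frequency bins equals C(0) when unwindowed (discrete Parseval).
acf_power_spectrum <- function(acf, dt_fs, window = "hann",
                               zero_pad_factor = 4) {
  L <- length(acf) - 1L
  if (window == "hann") {
    acf <- acf * (0.5 + 0.5 * cos(pi * (0:L) / L))
  }
  m <- stats::nextn(2L * (L + 1L) * max(1, zero_pad_factor), 2)
  seq_full <- numeric(m)
  seq_full[1:(L + 1L)] <- acf
  if (L >= 1L) seq_full[m - (1:L) + 1L] <- acf[2:(L + 1L)]  # even extension
  s <- Re(stats::fft(seq_full))
  nu <- (0:(m - 1)) / (m * dt_fs * .c_cm_per_fs)
  keep <- seq_len(m %/% 2 + 1L)
  list(wavenumber = nu[keep], power = s[keep], full_power = s, nbins = m)
}

#' Raman spectrum from a polarizability time series
#'
#' Fourier transform of the polarizability autocorrelation function: the
#' spectrum is the weighted sum of the transforms of the isotropic ACF
#' C_iso(tau) of alpha_bar and the anisotropic correlation
#' C_gamma(tau) = (3/2) sum_ij <d beta_ij(t) d beta_ij(t+tau)>, with lag
#' window and zero padding per `config`. The frequency axis is
#' nu = k / (Nbins * dt * c) in cm^-1; output is restricted to 0-4000 cm^-1
#' and max-normalized.
#'
#' @param trace A [polarizability_trace()] of at least 64 samples.
#' @param config A [spectrum_estimator_config()].
#' @param label Label for the output spectrum.
#' @return A `raman_spectrum`.
#' @export
raman_from_polarizability <- function(trace, config = spectrum_estimator_config(),
                                      label = "aimd") {
  if (!inherits(trace, "polarizability_trace")) {
    stop("expected polarizability_trace", call. = FALSE)
  }
  if (trace$n < 64L) {
    stop("insufficient data: need at least 64 samples for spectral estimation",
         call. = FALSE)
  }
  inv <- tensor_invariant_series(trace)
  L <- max(1L, floor(config$max_lag * trace$n) - 1L)
  w <- config$invariant_weights
  spec_sum <- NULL
  if (w[1] > 0) {
    c_iso <- autocorrelation(inv$iso, L)
    ps <- acf_power_spectrum(c_iso, trace$dt_fs, config$window,
                             config$zero_pad_factor)
    spec_sum <- w[1] * ps$power
  }
  if (w[2] > 0) {
    c_gam <- numeric(L + 1L)
    for (i in 1:3) for (j in 1:3) {
      c_gam <- c_gam + autocorrelation(inv$aniso[i, j, ], L)
    }
    c_gam <- 1.5 * c_gam
    ps <- acf_power_spectrum(c_gam, trace$dt_fs, config$window,
                             config$zero_pad_factor)
    spec_sum <- if (is.null(spec_sum)) w[2] * ps$power
                else spec_sum + w[2] * ps$power
  }
  nu <- ps$wavenumber
  y <- spec_sum
  if (config$quantum_correction == "harmonic") {
    x <- 1.4387768775039337 * nu / config$temperature_K
    corr <- ifelse(nu > 0, x / (1 - exp(-x)), 1)
    y <- y * corr
  }
  keep <- nu <= 4000
  nu <- nu[keep]; y <- y[keep]
  m <- max(y)
  # total variance of the tensor components sets the scale below which any
  # "signal" is just floating-point residue of the invariant decomposition
  total_var <- sum(apply(trace$tensors, c(1, 2), stats::var))
  if (m <= 1e-10 * max(total_var, .Machine$double.xmin)) {
    stop("degenerate spectrum: no power above numerical noise in 0-4000 cm^-1",
         call. = FALSE)
  }
  raman_spectrum(nu, y / m, label = label)
}
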