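#' Subtract a (water) background spectrum
#'
#' @param sample A `raman_spectrum`.
#' @param background A `raman_spectrum`; resampled to the sample grid if the
#'   grids differ.
#' @param scale Background scale factor (default 1, an identically acquired
#'   background). `scale = "optimal"` uses the least-squares-optimal scalar.
#' @return A `raman_spectrum`: sample minus scaled background.
#' @export
subtract_background <- function(sample, background, scale = 1) {
  assert_spectrum(sample); assert_spectrum(background)
  if (length(background$grid) != length(sample$grid) ||
      any(background$grid != sample$grid)) {
    if (background$grid[1] > sample$grid[length(sample$grid)] ||
        background$grid[length(background$grid)] < sample$grid[1]) {
      stop("grid mismatch: background does not overlap the sample grid",
           call. = FALSE)
    }
    background <- resample_to_grid(background, sample$grid)
  }
  if (identical(scale, "optimal")) {
    scale <- sum(sample$intensities * background$intensities) /
      sum(background$intensities^2)
  }
  raman_spectrum(sample$grid, sample$intensities - scale * background$intensities,
           label = sample$label)
}

#' Baseline-correction configuration
#'
#' @param p Asymmetry parameter in (0, 1) (default 0.001): weight given to
#'   points above the running baseline; points below get 1 - p. Small p
#'   makes the baseline hug the valleys under the peaks.
#' @param lambda Smoothness of the Whittaker smoother (second-difference
#'   penalty; default 3e4, sized for ~1000-point spectra sampled at
#'   1 cm^-1 with bands a few cm^-1 wide).
#' @param iterations Reweighting iterations (default 10).
#' @param method `"whittaker"` (default) or `"polynomial"` (asymmetrically
#'   reweighted polynomial of degree `degree`).
#' @param degree Polynomial degree for `method = "polynomial"` (default 3).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(p = 0.001, lambda = 3e4, iterations = 10L,
                            method = c("whittaker", "polynomial"), degree = 3L) {
  method <- match.arg(method)
  if (p <= 0 || p >= 1) stop("asymmetry p must be in (0, 1)", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (iterations < 1L) stop("need at least one iteration", call. = FALSE)
  structure(list(p = p, lambda = lambda, iterations = as.integer(iterations),
                 method = method, degree = as.integer(degree)),
            class = "baseline_config")
}

#' Asymmetric-least-squares baseline estimation
#'
#' Iteratively reweighted penalized least squares: each iteration solves
#' (W + lambda D'D) z = W y, where D is the second-difference operator and
#' the weights are p for points above the current baseline and 1 - p below,
#' so peaks (which stick up) barely pull the baseline while the smooth
#' underlying background is followed. The polynomial variant replaces the
#' Whittaker smoother with a weighted polynomial fit of the configured
#' degree under the same asymmetric reweighting.
#'
#' @param spec A `raman_spectrum` with at least 10 points.
#' @param config A [baseline_config()].
#' @return List with `baseline` and `corrected` (both `raman_spectrum`).
#' @export
asls_baseline <- function(spec, config = baseline_config()) {
  assert_spectrum(spec)
  y <- spec$intensities
  n <- length(y)
  if (n < 10L) stop("need at least 10 points for baseline estimation", call. = FALSE)
  if (!all(is.finite(y))) stop("invalid input: non-finite intensities", call. = FALSE)
  w <- rep(1, n)
  if (config$method == "whittaker") {
    D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                            diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                             rep(1, n - 2L)))
    DtD <- config$lambda * Matrix::crossprod(D)
    for (it in seq_len(config$iterations)) {
      W <- Matrix::Diagonal(n, w)
      z <- as.vector(Matrix::solve(W + DtD, w * y))
      w <- ifelse(y > z, config$p, 1 - config$p)
    }
  } else {
    x <- spec$grid - mean(spec$grid)
    X <- stats::poly(x, degree = config$degree, raw = TRUE)
    X <- cbind(1, X)
    for (it in seq_len(config$iterations)) {
      beta <- stats::lm.wfit(X, y, w)$coefficients
      z <- as.vector(X %*% beta)
      w <- ifelse(y > z, config$p, 1 - config$p)
    }
  }
  list(baseline = raman_spectrum(spec$grid, z, label = "baseline"),
       corrected = raman_spectrum(spec$grid, y - z, label = spec$label))
}

#' Truncate a spectrum to a wavenumber window
#'
#' @param spec A `raman_spectrum`.
#' @param lo,hi Window bounds, cm^-1 (points with lo <= nu <= hi retained).
#' @return A `raman_spectrum` on the retained points.
#' @export
truncate_window <- function(spec, lo = 600, hi = 1600) {
  assert_spectrum(spec)
  if (lo >= hi) stop("lo must be below hi", call. = FALSE)
  keep <- spec$grid >= lo & spec$grid <= hi
  if (sum(keep) < 2L) {
    stop("window error: fewer than 2 points in [", lo, ", ", hi, "] cm^-1",
         call. = FALSE)
  }
  raman_spectrum(spec$grid[keep], spec$intensities[keep], label = spec$label)
}
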