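#' Seeded synthetic-data generators
#'
#' Every generator in this file is a pure function of (parameters, seed): it
#' sets the RNG from `sim$seed`, restores the caller's RNG state on exit,
#' and attaches a machine-readable ground-truth record (attribute `truth`,
#' convertible to JSON with [write_truth()]) sufficient to score any
#' downstream recovery test.
#'
#' @param seed Integer RNG seed.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param lo,hi,step Synthesis grid, cm^-1.
#' @return `sim_config()` returns an object of class `sim_config`.
#' @name synthetic-data
NULL

#' @rdname synthetic-data
#' @export
sim_config <- function(seed = 1L, noise_sigma = 0, lo = 600, hi = 1600,
                       step = 0.5) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 lo = lo, hi = hi, step = step),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Peak specification for synthetic sub-spectra
#'
#' @param center Peak center, cm^-1.
#' @param height Peak height (>= 0).
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @export
peak_spec <- function(center, height = 1, fwhm = 10,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0 || height < 0) stop("fwhm must be > 0 and height >= 0", call. = FALSE)
  structure(list(center = center, height = height, fwhm = fwhm, shape = shape),
            class = "peak_spec")
}

peak_profile <- function(pk, x) {
  if (pk$shape == "lorentzian") {
    hw2 <- (pk$fwhm / 2)^2
    pk$height * hw2 / ((x - pk$center)^2 + hw2)
  } else {
    sd <- pk$fwhm / (2 * sqrt(2 * log(2)))
    pk$height * exp(-(x - pk$center)^2 / (2 * sd^2))
  }
}

#' Generate a synthetic conformer sub-spectrum
#'
#' Sum of analytic line shapes on the grid, normalized so the noise-free
#' shape has maximum 1, plus Gaussian noise of sd `noise_sigma`. The truth
#' record carries the peak list and the analytic normalized curve, so
#' recovery tests can compare against the exact noise-free shape.
#'
#' @param peaks List of [peak_spec()]s (at least one).
#' @param sim A [sim_config()].
#' @param label Spectrum label.
#' @return A `raman_spectrum` with attribute `truth`.
#' @export
gen_subspectrum <- function(peaks, sim = sim_config(), label = "synthetic") {
  if (length(peaks) < 1L) stop("need at least one peak", call. = FALSE)
  x <- seq(sim$lo, sim$hi, by = sim$step)
  shape <- Reduce(`+`, lapply(peaks, peak_profile, x = x))
  shape <- shape / max(shape)
  y <- with_seed(sim$seed, shape + stats::rnorm(length(x), 0, sim$noise_sigma))
  out <- raman_spectrum(x, y, label = label)
  attr(out, "truth") <- list(
    kind = "subspectrum",
    peaks = lapply(peaks, unclass),
    noise_sigma = sim$noise_sigma, seed = sim$seed,
    analytic = list(grid = x, intensities = shape)
  )
  out
}

#' Generate a synthetic mixture observation
#'
#' Forward model of the mixture fit: y_i = sum_j w_j f_j(r_j x_i + s) plus
#' noise, where f_j is the cubic-spline model of sub-spectrum j (0 outside
#' its domain). The generating (w, r, s) are recorded in the truth record.
#'
#' @param subs List of `raman_spectrum` sub-spectra (or a
#'   [subspectrum_set()]).
#' @param w Generating weights.
#' @param r Generating rescaling factors (default all 1).
#' @param s Generating global shift, cm^-1 (default 0).
#' @param sim A [sim_config()]; the observation grid is the first
#'   sub-spectrum's grid.
#' @return A `raman_spectrum` with attribute `truth`.
#' @export
gen_mixture_observation <- function(subs, w, r = rep(1, length(w)), s = 0,
                                    sim = sim_config()) {
  if (!inherits(subs, "subspectrum_set")) subs <- subspectrum_set(subs)
  if (length(w) != subs$n_conf || length(r) != subs$n_conf) {
    stop("w and r must have one entry per sub-spectrum", call. = FALSE)
  }
  grid <- subs$spectra[[1]]$grid
  pred <- prediction_matrix(subs, r, s, grid)
  clean <- as.vector(pred %*% w)
  y <- with_seed(sim$seed, clean + stats::rnorm(length(grid), 0, sim$noise_sigma))
  out <- raman_spectrum(grid, y, label = "synthetic mixture")
  attr(out, "truth") <- list(kind = "mixture", w = w, r = r, s = s,
                             labels = subs$labels,
                             noise_sigma = sim$noise_sigma, seed = sim$seed)
  out
}

#' Simulate a conformer label chain (optionally with torsion series)
#'
#' Discrete-time Markov chain over conformer labels with per-frame hop
#' probabilities 1 - exp(-k dt) from the given exchange-rate matrix.
#' Optionally synthesizes continuous chi and nu0..nu4 series per frame from
#' label-dependent means (P near 162 deg for south, 18 deg for north via
#' the inverse pseudorotation relation; chi near 0 for syn, 180 for anti)
#' plus wrapped-Gaussian angular noise.
#'
#' @param rates_ns Square rate matrix in ns^-1, dimnames giving the labels
#'   (diagonal ignored).
#' @param frame_interval_ps Frame interval, ps.
#' @param n_frames Number of frames (>= 2).
#' @param sim A [sim_config()].
#' @param torsions If TRUE, also return per-frame `chi` and `nu` series.
#' @param angular_noise_sd Wrapped-Gaussian sd in degrees (default 8).
#' @param tau_m Pucker amplitude for the torsion synthesis (default 40).
#' @return A [conformer_labels()] series with attribute `truth`; if
#'   `torsions`, also fields `chi_series` and `nu_series` (5 x n matrix).
#' @export
gen_conformer_chain <- function(rates_ns, frame_interval_ps, n_frames,
                                sim = sim_config(), torsions = FALSE,
                                angular_noise_sd = 8, tau_m = 40) {
  if (n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  labels <- rownames(rates_ns)
  if (is.null(labels)) stop("rates_ns needs dimnames giving the labels", call. = FALSE)
  K <- nrow(rates_ns)
  dt_ns <- frame_interval_ps / 1000
  P <- matrix(0, K, K, dimnames = dimnames(rates_ns))
  for (a in 1:K) for (b in 1:K) {
    if (a != b) P[a, b] <- 1 - exp(-rates_ns[a, b] * dt_ns)
  }
  if (any(rowSums(P) > 1)) {
    stop("timestep error: per-frame hop probabilities exceed 1; reduce the frame interval",
         call. = FALSE)
  }
  diag(P) <- 1 - rowSums(P)
  out <- with_seed(sim$seed, {
    state <- integer(n_frames)
    state[1] <- 1L
    u <- stats::runif(n_frames)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:n_frames) {
      state[t] <- which(u[t] <= cum[state[t - 1L], ])[1]
    }
    res <- list(state = state)
    if (torsions) {
      lab <- labels[state]
      base <- ifelse(grepl("^syn", lab), 0, 180)
      ringP <- ifelse(grepl("south$", lab), 162, 18)
      res$chi <- wrap180(base + stats::rnorm(n_frames, 0, angular_noise_sd))
      Pn <- wrap360(ringP + stats::rnorm(n_frames, 0, angular_noise_sd))
      res$nu <- vapply(Pn, pucker_torsions, numeric(5), tau_m = tau_m)
    }
    res
  })
  series <- conformer_labels(labels[out$state], frame_interval_ps)
  attr(series, "truth") <- list(kind = "conformer_chain",
                                rates_ns = rates_ns,
                                frame_interval_ps = frame_interval_ps,
                                seed = sim$seed)
  if (torsions) {
    series$chi_series <- out$chi
    series$nu_series <- out$nu
  }
  series
}

#' Generate a synthetic polarizability trace
#'
#' alpha(t) = sum_k A_k cos(2 pi c nu_k t) exp(-t / tau_k) M_k + noise,
#' where each M_k is a fixed symmetric unit-normalized tensor. Stands in
#' for the polarizability output of an ab initio trajectory.
#'
#' @param modes Data frame or list of rows with `wavenumber` (cm^-1),
#'   `amplitude` (a.u.), `damping_fs` (Inf for undamped) and optionally
#'   `kind` = `"iso"` (M = I/sqrt(3)) or `"aniso"` (a fixed traceless unit
#'   tensor); default iso.
#' @param dt_fs Timestep, fs.
#' @param n Number of samples.
#' @param sim A [sim_config()]; noise_sigma is applied per tensor component.
#' @return A [polarizability_trace()] with attribute `truth`.
#' @export
gen_polarizability_trace <- function(modes, dt_fs = 0.5, n = 35000,
                                     sim = sim_config()) {
  if (dt_fs <= 0) stop("dt_fs must be positive", call. = FALSE)
  modes <- as.data.frame(modes)
  if (is.null(modes$damping_fs)) modes$damping_fs <- Inf
  if (is.null(modes$kind)) modes$kind <- "iso"
  t_fs <- (seq_len(n) - 1) * dt_fs
  m_iso <- diag(3) / sqrt(3)
  m_aniso <- matrix(c(1, 1, 0, 1, -1, 0, 0, 0, 0), 3, 3) / 2  # traceless, unit norm
  tens <- array(0, dim = c(3, 3, n))
  for (k in seq_len(nrow(modes))) {
    osc <- modes$amplitude[k] *
      cos(2 * pi * .c_cm_per_fs * modes$wavenumber[k] * t_fs) *
      exp(-t_fs / modes$damping_fs[k])
    M <- if (modes$kind[k] == "aniso") m_aniso else m_iso
    tens <- tens + outer(M, osc)
  }
  if (sim$noise_sigma > 0) {
    tens <- tens + with_seed(sim$seed, {
      eps <- array(stats::rnorm(6 * n, 0, sim$noise_sigma), dim = c(6, n))
      sym <- array(0, dim = c(3, 3, n))
      sym[1, 1, ] <- eps[1, ]; sym[2, 2, ] <- eps[2, ]; sym[3, 3, ] <- eps[3, ]
      sym[1, 2, ] <- sym[2, 1, ] <- eps[4, ]
      sym[1, 3, ] <- sym[3, 1, ] <- eps[5, ]
      sym[2, 3, ] <- sym[3, 2, ] <- eps[6, ]
      sym
    })
  }
  out <- polarizability_trace(tens, dt_fs)
  attr(out, "truth") <- list(kind = "polarizability_trace",
                             modes = modes, dt_fs = dt_fs, n = n,
                             noise_sigma = sim$noise_sigma, seed = sim$seed)
  out
}

#' Generate a synthetic electron-density cube
#'
#' Sum of normalized 3D Gaussians ("blobs") sampled on a voxel grid; the
#' analytic total charge and first moment of each blob are recorded in the
#' truth record.
#'
#' @param blobs List of lists with `center` (bohr 3-vector), `width`
#'   (isotropic sd, bohr) and `charge` (electrons).
#' @param origin Grid origin, bohr.
#' @param counts Voxels per axis (length 3).
#' @param step Voxel edge length, bohr (cubic voxels).
#' @param atoms Data frame with `z`, `charge`, `x`, `y`, `z_pos` (defaults
#'   to a single hydrogen at the first blob center).
#' @return A `cube_grid` with attribute `truth`.
#' @export
gen_density_cube <- function(blobs, origin = c(0, 0, 0), counts = c(40, 40, 40),
                             step = 0.25, atoms = NULL) {
  for (b in blobs) {
    if (b$width <= 0) stop("blob widths must be positive", call. = FALSE)
    box_hi <- origin + counts * step
    if (any(b$center - 5 * b$width < origin) || any(b$center + 5 * b$width > box_hi)) {
      warning("blob extends beyond the box by > 5 sigma; integrated charge will be short")
    }
  }
  if (is.null(atoms)) {
    atoms <- data.frame(z = 1L, charge = 1, x = blobs[[1]]$center[1],
                        y = blobs[[1]]$center[2], z_pos = blobs[[1]]$center[3])
  }
  axes <- diag(3) * step
  cx <- origin[1] + (seq_len(counts[1]) - 1) * step
  cy <- origin[2] + (seq_len(counts[2]) - 1) * step
  cz <- origin[3] + (seq_len(counts[3]) - 1) * step
  vals <- array(0, dim = counts)
  for (b in blobs) {
    gx <- exp(-(cx - b$center[1])^2 / (2 * b$width^2))
    gy <- exp(-(cy - b$center[2])^2 / (2 * b$width^2))
    gz <- exp(-(cz - b$center[3])^2 / (2 * b$width^2))
    norm <- b$charge / (2 * pi * b$width^2)^1.5
    vals <- vals + norm * outer(outer(gx, gy), gz)
  }
  out <- structure(list(
    origin = origin, axes = axes, counts = as.integer(counts), atoms = atoms,
    values = vals, voxel_volume = step^3,
    total_density = sum(vals) * step^3
  ), class = "cube_grid")
  attr(out, "truth") <- list(
    kind = "density_cube",
    blobs = blobs,
    total_charge = sum(vapply(blobs, `[[`, numeric(1), "charge")),
    first_moment = Reduce(`+`, lapply(blobs, function(b) b$charge * b$center))
  )
  out
}

#' Write a generator's ground-truth sidecar as JSON
#'
#' @param x Any generator output carrying a `truth` attribute.
#' @param path Output JSON path.
#' @export
write_truth <- function(x, path) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("object carries no truth record", call. = FALSE)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
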