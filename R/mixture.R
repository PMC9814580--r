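#' Sub-spectrum basis set for mixture fitting
#'
#' Wraps one spectrum per conformer region into cubic-spline models
#' f^fit,j that can be evaluated at arbitrary (rescaled, shifted)
#' wavenumbers. Outside a sub-spectrum's measured domain the model returns
#' 0 (extrapolated cubics diverge).
#'
#' @param spectra List of `raman_spectrum` objects with unique labels (at
#'   least 4 points each).
#' @return An object of class `subspectrum_set`.
#' @export
subspectrum_set <- function(spectra) {
  if (length(spectra) < 1L) stop("need at least one sub-spectrum", call. = FALSE)
  lapply(spectra, assert_spectrum)
  labels <- vapply(spectra, `[[`, character(1), "label")
  labels[!nzchar(labels)] <- paste0("conformer", which(!nzchar(labels)))
  if (anyDuplicated(labels)) stop("sub-spectrum labels must be unique", call. = FALSE)
  models <- lapply(spectra, function(s) {
    if (length(s$grid) < 4L) {
      stop("sub-spectra need at least 4 points for spline fitting", call. = FALSE)
    }
    list(f = stats::splinefun(s$grid, s$intensities, method = "fmm"),
         lo = s$grid[1], hi = s$grid[length(s$grid)])
  })
  structure(list(spectra = spectra, labels = labels, models = models,
                 n_conf = length(spectra)),
            class = "subspectrum_set")
}

#' @export
print.subspectrum_set <- function(x, ...) {
  cat(sprintf("<subspectrum_set: %d conformer sub-spectra: %s>\n",
              x$n_conf, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Restrict an experimental grid to the analysis window
#'
#' The common grid for the fit is the experimental grid itself, restricted
#' to `window`, so the data term is a plain sum over experimental points.
#'
#' @param experimental A `raman_spectrum`.
#' @param window `c(lo, hi)` in cm^-1 (default `c(600, 1600)`).
#' @return Numeric vector of retained wavenumbers.
#' @export
build_common_grid <- function(experimental, window = c(600, 1600)) {
  assert_spectrum(experimental)
  g <- experimental$grid[experimental$grid >= window[1] &
                           experimental$grid <= window[2]]
  if (length(g) == 0L) {
    stop("window error: no experimental points in [", window[1], ", ",
         window[2], "] cm^-1", call. = FALSE)
  }
  g
}

#' Evaluate one conformer's sub-spectrum model on the common grid
#'
#' y_i = f^fit,j(r_j x_i + s): the spline of sub-spectrum j evaluated at the
#' rescaled and globally shifted abscissae, 0 outside the spline's domain.
#'
#' @param model One element of a [subspectrum_set()]'s `models` list (fields
#'   `f`, `lo`, `hi`).
#' @param r_j Rescaling factor for this conformer.
#' @param s Global shift, cm^-1.
#' @param grid Common-grid wavenumbers.
#' @return Intensity vector on `grid`.
#' @export
conformer_prediction <- function(model, r_j, s, grid) {
  x <- r_j * grid + s
  y <- model$f(x)
  y[x < model$lo | x > model$hi] <- 0
  y
}

prediction_matrix <- function(subs, r, s, grid) {
  vapply(seq_len(subs$n_conf), function(j) {
    conformer_prediction(subs$models[[j]], r[j], s, grid)
  }, numeric(length(grid)))
}

#' Mixture-fit configuration
#'
#' Hyperparameters of the regularized mixture loss and the multi-start
#' optimization. Defaults are a working set with penalties sized
#' against a data term of order 1e2 so that constraint violations dominate.
#'
#' @param c_weight Weight-penalty constant (default 1.0e8); with the default
#'   variant it pins the weight sum to 1 to ~1e-3.
#' @param c_rescaling Rescaling-penalty constant (default 1.0e2).
#' @param c_shift Shift-penalty constant (default 5.0e8).
#' @param r_eq Equilibrium rescaling deviation (default 0.05): the penalty
#'   attracts |r_j - 1| toward r_eq, i.e. rescalings of about +/-5%. Set 0
#'   to attract r_j to exactly 1.
#' @param s_min,s_max Allowed global-shift interval, cm^-1 (default 0-200).
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Integer seed making the restarts reproducible.
#' @param weight_penalty_variant `"sum"` (default): c_weight (sum w_j - 1)^2,
#'   which makes the weights interpretable as populations;
#'   `"literal_sum_of_squares"`: c_weight (sum w_j^2 - 1)^2.
#' @param nonnegative_weights If TRUE, optimize w = v^2 so weights cannot go
#'   negative (default FALSE: weights unconstrained, negatives flagged).
#' @param shift_penalty `"step"` (default, the literal discontinuous
#'   penalty) or `"smooth"` (logistic walls of width `shift_width` cm^-1,
#'   more robust for gradient-based steps that land outside the bounds).
#' @param shift_width Logistic width for `shift_penalty = "smooth"`.
#' @param window Analysis window passed to [build_common_grid()].
#' @return An object of class `mixture_fit_config`.
#' @export
mixture_fit_config <- function(c_weight = 1.0e8, c_rescaling = 1.0e2,
                               c_shift = 5.0e8, r_eq = 0.05,
                               s_min = 0.0, s_max = 200.0,
                               n_restarts = 50L, seed = 1L,
                               weight_penalty_variant = c("sum", "literal_sum_of_squares"),
                               nonnegative_weights = FALSE,
                               shift_penalty = c("step", "smooth"),
                               shift_width = 1.0,
                               window = c(600, 1600)) {
  weight_penalty_variant <- match.arg(weight_penalty_variant)
  shift_penalty <- match.arg(shift_penalty)
  if (c_weight < 0 || c_rescaling < 0 || c_shift < 0) {
    stop("penalty constants must be non-negative", call. = FALSE)
  }
  if (s_min > s_max) stop("s_min must not exceed s_max", call. = FALSE)
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  structure(list(c_weight = c_weight, c_rescaling = c_rescaling,
                 c_shift = c_shift, r_eq = r_eq, s_min = s_min, s_max = s_max,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 weight_penalty_variant = weight_penalty_variant,
                 nonnegative_weights = nonnegative_weights,
                 shift_penalty = shift_penalty, shift_width = shift_width,
                 window = window),
            class = "mixture_fit_config")
}

shift_penalty_value <- function(s, config) {
  if (config$shift_penalty == "step") {
    if (s < config$s_min || s > config$s_max) config$c_shift else 0
  } else {
    config$c_shift * (stats::plogis((config$s_min - s) / config$shift_width) +
                        stats::plogis((s - config$s_max) / config$shift_width))
  }
}

#' Regularized mixture loss and its decomposition
#'
#' Total loss = data + weight + scaling + shift, where
#' data = sum_i (y_i^exp - sum_j w_j y_i^conf,j)^2,
#' weight = c_weight (sum_j w_j - 1)^2 (default variant) or
#' c_weight (sum_j w_j^2 - 1)^2 (literal variant),
#' scaling = c_rescaling sum_j (|r_j - 1| - r_eq)^2,
#' shift = c_shift outside \[s_min, s_max\], else 0.
#'
#' @param w Weights (length N_conf).
#' @param r Rescaling factors (length N_conf).
#' @param s Global shift, cm^-1.
#' @param y_exp Experimental intensities on the common grid.
#' @param predictions N_grid x N_conf matrix of conformer predictions at
#'   (r, s) (see [conformer_prediction()]).
#' @param config A [mixture_fit_config()].
#' @return List with `total`, `data`, `weight`, `scaling`, `shift`.
#' @export
mixture_loss <- function(w, r, s, y_exp, predictions, config = mixture_fit_config()) {
  if (!is.matrix(predictions) || nrow(predictions) != length(y_exp) ||
      ncol(predictions) != length(w)) {
    stop("shape error: predictions must be N_grid x N_conf", call. = FALSE)
  }
  resid <- y_exp - as.vector(predictions %*% w)
  data_term <- sum(resid^2)
  weight_term <- if (config$weight_penalty_variant == "sum") {
    config$c_weight * (sum(w) - 1)^2
  } else {
    config$c_weight * (sum(w^2) - 1)^2
  }
  scaling_term <- config$c_rescaling * sum((abs(r - 1) - config$r_eq)^2)
  shift_term <- shift_penalty_value(s, config)
  list(total = data_term + weight_term + scaling_term + shift_term,
       data = data_term, weight = weight_term, scaling = scaling_term,
       shift = shift_term)
}

draw_restarts <- function(n_restarts, n_conf, config) {
  lapply(seq_len(n_restarts), function(i) {
    e <- stats::rexp(n_conf)          # Dirichlet(1): uniform on the simplex
    list(w = e / sum(e),
         r = stats::runif(n_conf, 1 - 2 * config$r_eq, 1 + 2 * config$r_eq),
         s = stats::runif(1, config$s_min, config$s_max))
  })
}

#' Fit an experimental spectrum as a mixture of conformer sub-spectra
#'
#' Minimizes the regularized loss of [mixture_loss()] over the weights w,
#' per-conformer rescalings r and the global shift s, by BFGS quasi-Newton
#' descent from `n_restarts` seeded random starting points (w uniform on the
#' simplex, r uniform in 1 +/- 2 r_eq, s uniform in \[s_min, s_max\]),
#' keeping the lowest-loss solution. Deterministic given the config seed.
#'
#' Experimental and sub-spectra are expected max-normalized on the analysis
#' window; the fitted weights, normalized to sum 1, are interpreted as
#' relative conformer populations (see [populations_from_fit()]).
#'
#' @param experimental A `raman_spectrum` (max-normalized on the window).
#' @param subs A [subspectrum_set()].
#' @param config A [mixture_fit_config()].
#' @param r_fixed Optional length-N_conf vector freezing the rescalings.
#' @param s_fixed Optional scalar freezing the global shift.
#' @return An object of class `mixture_fit` with fields `w`, `r`, `s`,
#'   `loss` (decomposed), `populations` (w normalized to sum 1),
#'   `predicted` (combined spectrum on the common grid), `restart_losses`,
#'   `converged`, `negative_weights` flag, `grid`, `labels`.
#' @export
fit_mixture <- function(experimental, subs, config = mixture_fit_config(),
                        r_fixed = NULL, s_fixed = NULL) {
  assert_spectrum(experimental)
  if (!inherits(subs, "subspectrum_set")) stop("expected subspectrum_set", call. = FALSE)
  grid <- build_common_grid(experimental, config$window)
  y_exp <- experimental$intensities[experimental$grid %in% grid]
  J <- subs$n_conf
  free_r <- is.null(r_fixed)
  free_s <- is.null(s_fixed)
  if (!free_r && length(r_fixed) != J) stop("r_fixed must have length N_conf", call. = FALSE)

  unpack <- function(theta) {
    w <- theta[seq_len(J)]
    if (config$nonnegative_weights) w <- w^2
    idx <- J
    if (free_r) { r <- theta[idx + seq_len(J)]; idx <- idx + J } else r <- r_fixed
    s <- if (free_s) theta[idx + 1L] else s_fixed
    list(w = w, r = r, s = s)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    pred <- prediction_matrix(subs, p$r, p$s, grid)
    mixture_loss(p$w, p$r, p$s, y_exp, pred, config)$total
  }
  # analytic gradient: the 1e8-scale weight penalty makes finite-difference
  # gradients unreliable. Spline derivative via splinefun(..., deriv = 1);
  # the step shift penalty is flat almost everywhere, |r - 1| uses the
  # subgradient sign(r - 1).
  gradient <- function(theta) {
    p <- unpack(theta)
    pred <- prediction_matrix(subs, p$r, p$s, grid)
    resid <- y_exp - as.vector(pred %*% p$w)
    dw <- -2 * as.vector(crossprod(pred, resid))
    dw <- dw + if (config$weight_penalty_variant == "sum") {
      rep(2 * config$c_weight * (sum(p$w) - 1), J)
    } else {
      4 * config$c_weight * (sum(p$w^2) - 1) * p$w
    }
    dpred_dx <- function(j) {
      x <- p$r[j] * grid + p$s
      d <- subs$models[[j]]$f(x, deriv = 1)
      d[x < subs$models[[j]]$lo | x > subs$models[[j]]$hi] <- 0
      d
    }
    dr <- ds <- NULL
    if (free_r || free_s) {
      deriv <- vapply(seq_len(J), dpred_dx, numeric(length(grid)))
      if (free_r) {
        dr <- vapply(seq_len(J), function(j) {
          -2 * p$w[j] * sum(resid * grid * deriv[, j])
        }, numeric(1))
        dr <- dr + 2 * config$c_rescaling * (abs(p$r - 1) - config$r_eq) *
          sign(p$r - 1)
      }
      if (free_s) {
        ds <- -2 * sum(resid * (deriv %*% p$w))
        if (config$shift_penalty == "smooth") {
          wd <- config$shift_width
          ds <- ds + config$c_shift / wd *
            (stats::dlogis((p$s - config$s_max) / wd) -
               stats::dlogis((config$s_min - p$s) / wd))
        }
      }
    }
    if (config$nonnegative_weights) dw <- dw * 2 * theta[seq_len(J)]
    c(dw, dr, ds)
  }

  # draw all restart initializations reproducibly, restoring the caller's RNG
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(config$seed)
  inits <- draw_restarts(config$n_restarts, J, config)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  best <- NULL
  restart_losses <- numeric(0)
  for (init in inits) {
    w0 <- if (config$nonnegative_weights) sqrt(init$w) else init$w
    theta0 <- c(w0, if (free_r) init$r, if (free_s) init$s)
    fit <- tryCatch(
      stats::optim(theta0, objective, gradient, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    restart_losses <- c(restart_losses, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("non-convergence: all ", config$n_restarts, " restarts failed",
         call. = FALSE)
  }
  # polish: re-run quasi-Newton from the best restart until no further
  # improvement (the squared-weight parametrization in particular flattens
  # near w_j = 0 and benefits from a second pass)
  repeat {
    polish <- tryCatch(
      stats::optim(best$par, objective, gradient, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(polish) || polish$value >= best$value * (1 - 1e-10)) break
    best <- polish
  }
  p <- unpack(best$par)
  pred <- prediction_matrix(subs, p$r, p$s, grid)
  loss <- mixture_loss(p$w, p$r, p$s, y_exp, pred, config)
  names(p$w) <- names(p$r) <- subs$labels
  structure(list(
    w = p$w, r = p$r, s = p$s, loss = loss,
    populations = p$w / sum(p$w),
    predicted = raman_spectrum(grid, as.vector(pred %*% p$w), label = "mixture fit"),
    restart_losses = restart_losses,
    converged = best$convergence == 0,
    negative_weights = any(p$w < 0),
    grid = grid, labels = subs$labels, config = config
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>\n")
  cat(sprintf("  total loss %.6g (data %.6g, weight %.6g, scaling %.6g, shift %.6g)\n",
              x$loss$total, x$loss$data, x$loss$weight, x$loss$scaling,
              x$loss$shift))
  cat(sprintf("  s = %.4g cm-1; converged: %s%s\n", x$s, x$converged,
              if (x$negative_weights) "; NOTE: negative raw weights" else ""))
  tab <- rbind(weight = x$w, rescaling = x$r,
               `population %` = 100 * x$populations)
  print(round(tab, 4))
  invisible(x)
}

#' Combine sub-spectra with fixed (e.g. simulation-derived) weights
#'
#' Weights are renormalized over the supplied sub-spectra (population
#' weights over the simulated regions need not sum to 1 when low-population
#' regions were not simulated), the sub-spectra are resampled to a common
#' grid, combined as sum_j w_j f_j, and max-normalized.
#'
#' @param subs A [subspectrum_set()].
#' @param weights Non-negative weights, one per sub-spectrum (any scale,
#'   e.g. percentages).
#' @param grid Optional common grid; default the first sub-spectrum's grid.
#' @return A `raman_spectrum`: the weighted, max-normalized combination.
#' @export
combine_fixed_weights <- function(subs, weights, grid = NULL) {
  if (!inherits(subs, "subspectrum_set")) stop("expected subspectrum_set", call. = FALSE)
  if (length(weights) != subs$n_conf) {
    stop("need one weight per sub-spectrum", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("invalid parameter: weights must be non-negative and not all zero",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  if (is.null(grid)) grid <- subs$spectra[[1]]$grid
  pred <- prediction_matrix(subs, rep(1, subs$n_conf), 0, grid)
  normalize_max(raman_spectrum(grid, as.vector(pred %*% w), label = "combined"))
}

#' Conformer populations from a mixture fit
#'
#' Normalizes the fitted weights to sum 1 and reports them as percentages.
#' Small negative raw weights are tolerated but flagged.
#'
#' @param result A `mixture_fit`.
#' @return Named numeric vector of populations in percent (attribute
#'   `negative_weights` flags fits with any raw weight < 0).
#' @export
populations_from_fit <- function(result) {
  if (!inherits(result, "mixture_fit")) stop("expected mixture_fit", call. = FALSE)
  if (!result$converged) {
    warning("fit did not formally converge; populations may be unreliable")
  }
  if (sum(result$w) <= 0) {
    stop("degenerate fit: weights sum to a non-positive value", call. = FALSE)
  }
  p <- 100 * result$w / sum(result$w)
  attr(p, "negative_weights") <- any(result$w < 0)
  p
}
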