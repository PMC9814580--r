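test_that("the common grid is the experimental grid restricted to the window", {
  ex <- raman_spectrum(seq(500, 1700, by = 3), rep(1, length(seq(500, 1700, by = 3))))
  g <- build_common_grid(ex, c(600, 1600))
  expect_true(all(g >= 600 & g <= 1600))
  expect_setequal(g, ex$grid[ex$grid >= 600 & ex$grid <= 1600])

  expect_identical(build_common_grid(ex, c(500, 1700)), ex$grid)
  expect_error(build_common_grid(ex, c(2000, 2100)), "window error")
})

test_that("conformer predictions evaluate the spline at rescaled, shifted abscissae", {
  sub <- gen_subspectrum(list(peak_spec(1000, 1, 12)), sim_config(seed = 2),
                         label = "one peak")
  subs <- subspectrum_set(list(sub))
  m <- subs$models[[1]]

  # identity case reproduces the sub-spectrum exactly
  expect_equal(conformer_prediction(m, 1, 0, sub$grid), sub$intensities,
               tolerance = 1e-12)

  # s = 10: prediction at x equals the sub-spectrum at x + 10
  g <- seq(700, 1500, by = 0.5)
  expect_equal(conformer_prediction(m, 1, 10, g),
               conformer_prediction(m, 1, 0, g + 10), tolerance = 1e-12)

  # r = 1.05 moves the apparent peak to ~1000/1.05
  p <- conformer_prediction(m, 1.05, 0, g)
  expect_equal(g[which.max(p)], 1000 / 1.05, tolerance = 1e-3)

  # zero outside the sub-spectrum's domain
  expect_identical(conformer_prediction(m, 1, 300, seq(1400, 1600, 10)),
                   rep(0, 21))
})

test_that("loss terms match hand arithmetic at the default constants", {
  cfg <- mixture_fit_config()
  y <- rep(0.5, 10)
  pred <- matrix(0.25, 10, 2)

  # default weight penalty vanishes at sum(w) = 1
  l <- mixture_loss(c(0.5, 0.5), c(1, 1), 50, y, pred, cfg)
  expect_identical(l$weight, 0)
  # literal variant: 1e8 * (0.25 + 0.25 - 1)^2 = 2.5e7
  cfg_lit <- mixture_fit_config(weight_penalty_variant = "literal_sum_of_squares")
  expect_identical(mixture_loss(c(0.5, 0.5), c(1, 1), 50, y, pred, cfg_lit)$weight,
                   2.5e7)
  # scaling at r = (1, 1): 1e2 * 2 * (0 - 0.05)^2 = 0.5
  expect_equal(l$scaling, 0.5, tolerance = 1e-12)
  # step shift penalty
  expect_identical(mixture_loss(c(0.5, 0.5), c(1, 1), 250, y, pred, cfg)$shift, 5.0e8)
  expect_identical(l$shift, 0)
  # decomposition adds up
  expect_equal(l$total, l$data + l$weight + l$scaling + l$shift, tolerance = 1e-9)
  # data term is the plain residual sum of squares: y - pred %*% w = 0.25
  expect_equal(l$data, sum((y - 0.25)^2), tolerance = 1e-12)

  expect_error(mixture_loss(c(0.5, 0.5), c(1, 1), 0, y, matrix(0, 3, 2), cfg),
               "shape error")
})

test_that("a spectrum fits itself with unit weight and near-zero data term", {
  sub <- gen_subspectrum(fixture_peaks$A, sim_config(seed = 41, step = 3),
                         label = "self")
  subs <- subspectrum_set(list(sub))

  # with (r, s) frozen at the identity the data term collapses to zero
  frozen <- fit_mixture(sub, subs, mixture_fit_config(seed = 5, n_restarts = 5),
                        r_fixed = 1, s_fixed = 0)
  expect_equal(unname(frozen$w), 1, tolerance = 1e-6)
  expect_lt(frozen$loss$data, 1e-6)

  # free fit: the scaling penalty prefers |r - 1| = r_eq, so the optimum
  # trades a small data residual against the penalty; w stays at 1
  fit <- fit_mixture(sub, subs, mixture_fit_config(seed = 5))
  expect_equal(unname(fit$w), 1, tolerance = 1e-3)
  expect_lt(fit$loss$data, 1e-2)
  expect_lt(abs(fit$s), 5)
  expect_true(fit$converged)
})

test_that("mixture fits recover generating weights from noisy synthetic data", {
  subs <- fixture_subspectra(c("A", "B"), step = 3)
  obs <- gen_mixture_observation(subs, w = c(0.7, 0.3),
                                 sim = sim_config(seed = 13, noise_sigma = 0.01,
                                                  step = 3))
  fit <- fit_mixture(obs, subs, mixture_fit_config(seed = 42))
  expect_lt(max(abs(unname(fit$populations) - c(0.7, 0.3))), 0.03)
  expect_lt(abs(sum(fit$w) - 1), 1e-3)
})

test_that("the noise-free truth zeroes the data term and the loss decomposes exactly", {
  subs <- fixture_subspectra(c("A", "B"))
  w_true <- c(0.6, 0.4)
  obs <- gen_mixture_observation(subs, w = w_true, sim = sim_config(seed = 3))
  g <- build_common_grid(obs)
  pred <- sapply(subs$models, conformer_prediction, r_j = 1, s = 0, grid = g)
  cfg <- mixture_fit_config()
  l <- mixture_loss(w_true, c(1, 1), 0, obs$intensities, pred, cfg)
  expect_equal(l$data, 0, tolerance = 1e-18)
  expect_equal(l$total, l$weight + l$scaling, tolerance = 1e-12)
})

test_that("fitting is deterministic given the seed and improves with restarts", {
  subs <- fixture_subspectra(c("A", "B"))
  obs <- gen_mixture_observation(subs, w = c(0.7, 0.3),
                                 sim = sim_config(seed = 13, noise_sigma = 0.01))
  cfg <- mixture_fit_config(seed = 9, n_restarts = 6)
  f1 <- fit_mixture(obs, subs, cfg)
  f2 <- fit_mixture(obs, subs, cfg)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$restart_losses, f2$restart_losses)

  # best-of-k restart loss is non-increasing in k
  expect_true(all(diff(cummin(f1$restart_losses)) <= 0))
})

test_that("frozen-(r, s) single-spectrum fits match the penalized least-squares closed form", {
  subs <- fixture_subspectra("A")
  obs <- gen_mixture_observation(subs, w = 0.9,
                                 sim = sim_config(seed = 19, noise_sigma = 0.02))
  g <- build_common_grid(obs)
  p <- conformer_prediction(subs$models[[1]], 1, 0, g)
  y <- obs$intensities
  cw <- 1e8
  w_closed <- (sum(p * y) + cw) / (sum(p * p) + cw)
  fit <- fit_mixture(obs, subs, mixture_fit_config(seed = 7, n_restarts = 5),
                     r_fixed = 1, s_fixed = 0)
  expect_equal(unname(fit$w), w_closed, tolerance = 1e-6)
})

test_that("the nonnegative parametrization keeps weights at or above zero", {
  subs <- fixture_subspectra(c("A", "B"), step = 3)
  obs <- gen_mixture_observation(subs, w = c(1, 0),
                                 sim = sim_config(seed = 23, noise_sigma = 0.02,
                                                  step = 3))
  # frozen (r, s) isolates the parametrization from rescale/shift aliasing
  fit <- fit_mixture(obs, subs,
                     mixture_fit_config(seed = 3, nonnegative_weights = TRUE),
                     r_fixed = c(1, 1), s_fixed = 0)
  expect_true(all(fit$w >= 0))
  expect_false(fit$negative_weights)
  expect_equal(unname(fit$w[1]), 1, tolerance = 0.05)
})

test_that("fixed-weight combination renormalizes simulation weights", {
  subs <- fixture_subspectra(c("A", "B"))
  comb <- combine_fixed_weights(subs, c(53, 31))
  w <- c(53, 31) / 84
  expect_equal(w, c(0.631, 0.369), tolerance = 1e-3)
  manual <- w[1] * subs$spectra[[1]]$intensities + w[2] * subs$spectra[[2]]$intensities
  expect_equal(comb$intensities, manual / max(manual), tolerance = 1e-9)

  # single sub-spectrum: any positive weight returns the (normalized) spectrum
  one <- combine_fixed_weights(subspectrum_set(subs$spectra[1]), 5)
  expect_equal(one$intensities,
               normalize_max(subs$spectra[[1]])$intensities, tolerance = 1e-9)

  # equal weights on identical sub-spectra reproduce the spectrum
  twin <- subs$spectra[[1]]; twin$label <- "twin"
  same <- combine_fixed_weights(subspectrum_set(list(subs$spectra[[1]], twin)),
                                c(1, 1))
  expect_equal(same$intensities,
               normalize_max(subs$spectra[[1]])$intensities, tolerance = 1e-9)

  expect_error(combine_fixed_weights(subs, c(0, 0)), "invalid parameter")
})

test_that("fit weights convert to percentage populations with negative flagging", {
  fake <- structure(list(w = c(a = 0.67, b = 0.33), converged = TRUE),
                    class = "mixture_fit")
  p <- populations_from_fit(fake)
  expect_equal(unname(p), c(67, 33), ignore_attr = TRUE)
  expect_false(attr(p, "negative_weights"))

  fake$w <- c(a = 1.02, b = 0.02)
  p <- populations_from_fit(fake)
  expect_equal(unname(p), 100 * c(1.02, 0.02) / 1.04, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_false(attr(p, "negative_weights"))

  fake$w <- c(a = 1.1, b = -0.1)
  expect_true(attr(populations_from_fit(fake), "negative_weights"))

  fake$w <- c(a = -0.5, b = 0.2)
  expect_error(populations_from_fit(fake), "degenerate fit")
})
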