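bump_curve <- function(centre = -0.5, tau = seq(-2.5, 2.5, length.out = 81),
                       height = 1, base = 2, width = 0.08,
                       se = rep(0.02, length(tau))) {
  mi <- base + height * exp(-(tau - centre)^2 / (2 * width))
  misep:::new_mi_curve(tau, mi, se, rep(250L, length(tau)),
                       convention = "test", k = 4L)
}

test_that("local regression reproduces polynomials and matches stats::loess", {
  x <- seq(0, 10, length.out = 60)
  y_lin <- 2 + 3 * x
  expect_equal(loess_smooth(x, y_lin, f = 0.3, degree = 1), y_lin,
               tolerance = 1e-8)
  y_quad <- 1 - x + 0.5 * x^2
  expect_equal(loess_smooth(x, y_quad, f = 0.4, degree = 2), y_quad,
               tolerance = 1e-8)

  # f = 1, degree 1 on linear-plus-noise ~ the global least-squares line
  y_noise <- withr::with_seed(1, y_lin + rnorm(60, 0, 0.5))
  fit_all <- loess_smooth(x, y_noise, f = 1, degree = 1)
  ols <- unname(cbind(1, x) %*% coef(lm(y_noise ~ x)))[, 1]
  expect_lt(max(abs(fit_all - ols)), 0.2)

  # smoothing reduces variance on white noise
  wn <- withr::with_seed(2, rnorm(100))
  expect_lt(var(loess_smooth(seq_len(100), wn, f = 0.5)), var(wn))

  # independent cross-check against stats::loess at matched span
  sm_ours <- loess_smooth(x, y_noise, f = 0.5, degree = 2)
  sm_stats <- predict(stats::loess(y_noise ~ x, span = 0.5, degree = 2,
                                   family = "gaussian", surface = "direct"))
  expect_lt(max(abs(sm_ours - sm_stats)), 0.05)

  expect_error(loess_smooth(x, y_lin, f = 0.02), "too few points")
  expect_error(loess_smooth(x, y_lin[-1], f = 0.5), "equal length")
})

test_that("peak localisation recovers a known bump and flags boundary maxima", {
  curve <- bump_curve(centre = -0.5)
  pk <- peak_per_fraction(curve, "negative", f_grid = seq(0.05, 0.5, 0.05))
  kept <- pk[pk$f <= 0.5, ]
  grid_step <- diff(curve$tau_s)[1]
  expect_true(all(abs(kept$peak_tau_s - (-0.5)) <= grid_step + 1e-9))

  # preservation is monotone in f on this fixture: if a fraction keeps the
  # interior peak, every smaller fraction does too
  interior_f <- pk$f[pk$interior]
  if (length(interior_f) > 0)
    expect_true(all(pk$f[pk$f <= max(interior_f)] %in% interior_f))

  # monotone branch: every fraction lands on the boundary
  tau <- seq(-2.5, 0, length.out = 41)
  mono <- misep:::new_mi_curve(tau, 1 + 0.3 * tau, rep(0.01, 41),
                               rep(250L, 41), "test", 4L)
  pk_mono <- peak_per_fraction(mono, "negative", f_grid = c(0.1, 0.3, 0.5))
  expect_false(any(pk_mono$interior))

  expect_error(peak_per_fraction(bump_curve(), "negative",
                                 f_grid = 0.01), "smallest f")
})

test_that("peak location is invariant to affine rescaling of the information", {
  curve <- bump_curve(centre = 0.75)
  scaled <- curve
  scaled$mi_nats <- 3.7 * curve$mi_nats + 11
  f_grid <- seq(0.1, 0.5, by = 0.1)
  expect_equal(peak_per_fraction(scaled, "positive", f_grid)$peak_tau_s,
               peak_per_fraction(curve, "positive", f_grid)$peak_tau_s)
})

test_that("reaction-time averaging handles the no-peak case gracefully", {
  pk <- tibble::tibble(branch = "negative", f = c(0.1, 0.2, 0.3),
                       peak_tau_s = c(-0.5, -0.5, -0.5),
                       interior = TRUE)
  est <- estimate_reaction_time(pk)
  expect_equal(est$t_hat_s, 0.5)
  expect_equal(est$band_s, 0)

  none <- estimate_reaction_time(dplyr::mutate(pk, interior = FALSE))
  expect_true(is.na(none$t_hat_s))
  expect_equal(none$n_retained, 0L)
})

test_that("significance rule separates real peaks from flat curves", {
  curve <- bump_curve(centre = -0.5, height = 1, se = rep(0.02, 81))
  sig <- peak_significance(curve, -0.5)
  expect_true(sig$significant)
  expect_gt(sig$z_score, 2)

  flat <- bump_curve(height = 0)
  nsig <- peak_significance(flat, -0.5)
  expect_false(nsig$significant)

  no_se <- flat
  no_se$se_nats <- NA_real_
  expect_error(peak_significance(no_se, -0.5), "standard errors")
})

test_that("the full fit reports tidy peaks and a one-row summary", {
  curve <- bump_curve(centre = -0.5)
  fit <- fit_reaction_time(curve)
  td <- tidy(fit)
  expect_true(all(c("branch", "f", "peak_tau_s", "interior") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$branch, "negative")
  expect_equal(gl$t_hat_s, 0.5, tolerance = 0.07)
  expect_true(gl$any_significant)

  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_csv(fit, path)
  expect_true(any(grepl("T_hat_s", readLines(path))))
})
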