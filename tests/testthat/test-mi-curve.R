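make_curve <- function(tau, mi, se = rep(0.01, length(tau))) {
  misep:::new_mi_curve(tau, mi, se, rep(250L, length(tau)),
                       convention = "test", k = 4L)
}

test_that("mirror_combine reflects the swapped ordering onto negative tau", {
  pos <- seq(0, 1, by = 0.25)
  c01 <- make_curve(pos, c(1, 2, 3, 2, 1))
  c10 <- make_curve(pos, c(1, 5, 6, 7, 8))
  comb <- mirror_combine(c01, c10)
  expect_equal(comb$tau_s, seq(-1, 1, by = 0.25))
  # negative branch is the swapped curve reversed; tau = 0 keeps c01
  expect_equal(comb$mi_nats, c(8, 7, 6, 5, 1, 2, 3, 2, 1))

  # degenerate grid: a single shared point
  single <- mirror_combine(make_curve(0, 2), make_curve(0, 3))
  expect_equal(nrow(single), 1L)
  expect_equal(single$mi_nats, 2)

  expect_error(mirror_combine(c01, make_curve(seq(0, 2, by = 0.5), 1:5)),
               "grid")
  expect_error(mirror_combine(make_curve(c(-1, 0, 1), 1:3),
                              make_curve(c(-1, 0, 1), 1:3)), "non-negative")
})

test_that("ensemble estimation validates its inputs", {
  reps <- simulate_lf_ensemble(study_config(n_steps = 300), 20, seed = 1)
  expect_error(mi_curve_ensemble(reps, c(0, 0.5), 300, subset_size = 250),
               "shortfall 230")
  expect_error(mi_curve_ensemble(reps, c(0, 10), 300, subset_size = 10),
               "outside the simulated range")
  expect_error(mi_curve_ensemble(reps, c(0.5, 0.25), 300, subset_size = 10),
               "increasing")
})

test_that("single-trajectory estimation drops masked frames and flags sparse grid points", {
  cfg <- study_config(n_steps = 4000, seed = 21)
  d <- simulate_lf_dyad(cfg)
  d$theta0[sample(nrow(d), 200)] <- NA # masked frames
  grid <- seq(-0.5, 0.5, by = 0.25)
  curve <- mi_curve_single(d, grid, W = 40, seed = 3)
  expect_s3_class(curve, "mi_curve")
  expect_true(all(curve$n < 100)) # pairs lost to masking and truncation
  expect_false(anyNA(curve$mi_nats))

  # far too few windows for k + 2 pairs: flagged as NA with a warning
  short <- d[1:200, ]
  attr(short, "dt") <- attr(d, "dt")
  expect_warning(mi_curve_single(short, grid, W = 50, seed = 4),
                 "too few valid pairs")
})

test_that("seeded curve estimation is reproducible", {
  cfg <- study_config(n_steps = 4000, seed = 22)
  d <- simulate_lf_dyad(cfg)
  grid <- seq(-0.5, 0.5, by = 0.25)
  expect_identical(mi_curve_single(d, grid, W = 50, seed = 5),
                   mi_curve_single(d, grid, W = 50, seed = 5))
  reps <- simulate_lf_ensemble(study_config(n_steps = 500), 60, seed = 2)
  expect_identical(
    mi_curve_ensemble(reps, c(0, 0.25), 400, subset_size = 50, seed = 6),
    mi_curve_ensemble(reps, c(0, 0.25), 400, subset_size = 50, seed = 6))
})

test_that("information decays monotonically away from the reaction delay", {
  # with noise strong enough to kill the periodic long-time correlations,
  # the smoothed ensemble curve must be non-increasing in |tau - T|
  cfg <- lf_config(omega = 0.0067, sigma = 0.2, delay = 20, n_steps = 8000,
                   phi = 0.5, fps = 40)
  reps <- simulate_lf_ensemble(cfg, 300, seed = 31)
  pos <- seq(0, 2.5, length.out = 21)
  curve <- mirrored_ensemble_curve(reps, pos, 8000, seed = 7)
  sm <- loess_smooth(curve$tau_s, curve$mi_nats, f = 0.2)
  t_peak <- 0.5
  right <- curve$tau_s >= t_peak
  left <- curve$tau_s <= t_peak
  tol <- curve$se_nats
  expect_true(all(diff(sm[right]) <= tol[right][-1]))
  expect_true(all(diff(sm[left]) >= -tol[left][-1]))
})

test_that("curves round-trip through CSV with their conventions", {
  curve <- make_curve(seq(-1, 1, by = 0.5), c(1, 2, 5, 2, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mi_curve(curve, path)
  back <- read_mi_curve(path)
  expect_equal(back$tau_s, curve$tau_s)
  expect_equal(back$mi_nats, curve$mi_nats)
  expect_equal(back$se_nats, curve$se_nats)
  expect_equal(attr(back, "convention"), "test")
  expect_equal(attr(back, "k"), 4)
})

test_that("autoplot returns a ggplot for curves and fits", {
  curve <- make_curve(seq(-1, 1, by = 0.1),
                      exp(-((seq(-1, 1, by = 0.1) + 0.5)^2) / 0.02))
  expect_s3_class(autoplot(curve), "ggplot")
  fit <- fit_reaction_time(curve, f_grid = c(0.2, 0.3))
  expect_s3_class(autoplot(fit), "ggplot")
})
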