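test_that("configuration invariants are enforced", {
  expect_error(lf_config(0.01, -1, 20, 1000), "sigma")
  expect_error(lf_config(0.01, 0.1, 20, 1000, alpha = 1.5), "alpha")
  expect_error(lf_config(0.01, 0.1, -3, 1000), "delay")
  expect_error(lf_config(0.01, 0.1, 20, 20), "n_steps")
  expect_error(lf_config(0.01, 0.1, 20, 1000, fps = 0), "fps")
  expect_error(simulate_walker(100, sigma2 = 0), "sigma2")
  expect_error(analytic_free_walker_mi(10, 0), "tau")
})

test_that("noise-free follower reproduces the leader delayed by T exactly", {
  cfg <- lf_config(omega = 0.0123, sigma = 0, delay = 20, n_steps = 500,
                   phi = 0.5, seed = 7)
  d <- simulate_lf_dyad(cfg)
  t_idx <- 21:500
  expect_equal(d$theta1[t_idx + 1L], d$theta0[t_idx - 20L + 1L])
  # before the delay elapses the follower tracks the leader's start
  expect_equal(d$theta1[2:20], rep(d$theta0[1], 19))
  # every angle wrapped
  expect_true(all(d$theta0 >= 0 & d$theta0 < 2 * pi))
  expect_true(all(d$theta1 >= 0 & d$theta1 < 2 * pi))
})

test_that("same seed reproduces a run bit-for-bit and streams are separated", {
  cfg <- study_config(n_steps = 2000, seed = 42)
  expect_identical(simulate_lf_dyad(cfg), simulate_lf_dyad(cfg))
  # swap draws use their own sub-stream: changing alpha to a value that
  # still realises zero swaps leaves the noise sequences untouched
  cfg_eps <- study_config(n_steps = 2000, seed = 42)
  cfg_eps$alpha <- 1e-12
  d0 <- simulate_lf_dyad(cfg)
  d1 <- simulate_lf_dyad(cfg_eps)
  expect_equal(d0$theta0, d1$theta0)
  expect_equal(d0$theta1, d1$theta1)
})

test_that("leader increments match the configured drift and noise", {
  cfg <- study_config(n_steps = 72000, seed = 9)
  d <- simulate_lf_dyad(cfg)
  inc <- ang_diff(d$theta0[-1], d$theta0[-nrow(d)])
  se_mean <- 0.0039 / sqrt(length(inc))
  expect_lt(abs(mean(inc) - 0.0067), 3 * se_mean)
  se_sd <- 0.0039 / sqrt(2 * length(inc))
  expect_lt(abs(sd(inc) - 0.0039), 3 * se_sd)
})

test_that("leadership swaps are Bernoulli per step with the configured rate", {
  n_steps <- 20000
  alpha <- 0.001
  counts <- vapply(1:200, function(i) {
    cfg <- study_config(alpha = alpha, n_steps = n_steps, seed = 1000 + i)
    d <- simulate_lf_dyad(cfg)
    sum(diff(d$leader_id) != 0)
  }, numeric(1))
  mu <- n_steps * alpha
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu * (1 - alpha) / 200))
  # chi-square goodness of fit against Binomial(n_steps, alpha)
  qs <- unique(qbinom(seq(0.1, 0.9, by = 0.2), n_steps, alpha))
  edges <- c(-Inf, qs, Inf)
  obs <- table(cut(counts, edges))
  pr <- diff(pbinom(c(-Inf, qs, Inf), n_steps, alpha))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("a swap hands the follower equation to the new leader's history", {
  # force a single swap mid-run with sigma = 0: after the swap, the new
  # follower (agent 0) must read agent 1's history at t - T
  cfg <- lf_config(omega = 0.02, sigma = 0, delay = 10, n_steps = 200,
                   phi = 0.3, seed = 5, alpha = 0)
  base <- simulate_lf_dyad(cfg)
  cfg1 <- cfg
  cfg1$alpha <- 1 # swap every step: labels alternate deterministically
  d <- simulate_lf_dyad(cfg1)
  expect_true(all(diff(d$leader_id) != 0))
  expect_true(all(d$theta0 >= 0 & d$theta0 < 2 * pi))
  # both agents' series are defined at every step despite constant swaps
  expect_false(anyNA(d$theta0) || anyNA(d$theta1))
  expect_identical(nrow(d), nrow(base))
})

test_that("non-interacting pair drifts rigidly without noise and apart with it", {
  cfg <- lf_config(omega = 0.0067, sigma = 0, delay = 20, n_steps = 1000,
                   phi = 0.25, theta0_init = 1, seed = 3)
  d <- simulate_independent_pair(cfg)
  expect_equal(ang_diff(d$theta0, d$theta1), rep(0.25, nrow(d)),
               tolerance = 1e-12)
  expect_true(all(is.na(d$leader_id)))

  # with noise, the angular separation variance grows in time
  seps <- vapply(1:150, function(i) {
    cfg <- lf_config(omega = 0.0067, sigma = 0.00039, delay = 20,
                     n_steps = 10000, phi = 0.1, seed = 400 + i)
    di <- simulate_independent_pair(cfg)
    ang_diff(di$theta1[c(1001, 10001)], di$theta0[c(1001, 10001)])
  }, numeric(2))
  expect_gt(var(seps[2, ]), var(seps[1, ]))
})

test_that("free walker variance grows linearly; ring walker mixes to uniform", {
  xs <- vapply(1:1000, function(i) {
    simulate_walker(50, sigma2 = 0.04, seed = 2000 + i)$x[51]
  }, numeric(1))
  expect_lt(abs(var(xs) - 0.04 * 50), 5 * 0.04 * 50 * sqrt(2 / 999))

  # sigma2 -> 0 limit: ring walker stays put
  w0 <- simulate_walker(100, sigma2 = 1e-30, confined = TRUE, seed = 1)
  expect_equal(w0$theta, rep(w0$theta[1], 101), tolerance = 1e-6)

  # stationary marginal uniform for t >> 2*pi/sigma
  th <- vapply(1:500, function(i) {
    simulate_walker(500, sigma2 = 0.1, confined = TRUE, seed = 3000 + i)$theta[501]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(th, "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.001)
})

test_that("free-walker self-information follows the closed form", {
  expect_equal(analytic_free_walker_mi(0, 10), 0)
  expect_equal(analytic_free_walker_mi(10, 10), 0.5 * log(2))
  expect_equal(analytic_free_walker_mi(10, 10, units = "bits"), 0.5)
  t_grid <- seq(0, 100, by = 5)
  expect_true(all(diff(analytic_free_walker_mi(t_grid, 7)) > 0))
})

test_that("dyad tracks round-trip through CSV with their metadata", {
  cfg <- study_config(n_steps = 500, seed = 11)
  d <- simulate_lf_dyad(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(d, path)
  d2 <- read_track_csv(path)
  expect_equal(d2$theta0, d$theta0)
  expect_equal(d2$theta1, d$theta1)
  expect_equal(d2$leader_id, d$leader_id)
  expect_equal(attr(d2, "dt"), attr(d, "dt"))
  expect_equal(attr(d2, "config")$omega, 0.0067)
})
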