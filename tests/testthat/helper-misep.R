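# Shared helpers: independent oracles and small fixture builders.

# Histogram plug-in MI with equiprobable bins and Miller-Madow bias
# correction. Independent of the kNN estimation path; used as a
# brute-force oracle on moderate sample sizes.
hist_mi <- function(x, y, bins = 20) {
  n <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") / n * bins)
  by <- ceiling(rank(y, ties.method = "first") / n * bins)
  joint <- table(factor(bx, 1:bins), factor(by, 1:bins)) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  ratio <- joint / outer(px, py)
  mi <- sum(joint[joint > 0] * log(ratio[joint > 0]))
  # Miller-Madow: plug-in MI is biased up by (K_xy - K_x - K_y + 1)/(2n)
  mi - (sum(joint > 0) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
}

# Correlated bivariate normal sample.
rbinorm <- function(n, rho, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    list(x = x, y = y)
  })
}

# CDF of the symmetric triangular distribution on [a, a + W].
tri_cdf <- function(t, a, W) {
  b <- a + W
  mid <- (a + b) / 2
  ifelse(t <= a, 0,
         ifelse(t <= mid, 2 * ((t - a) / W)^2,
                ifelse(t < b, 1 - 2 * ((b - t) / W)^2, 1)))
}

# Study-conditions dyad configuration (ring leader-follower at 40 fps).
study_config <- function(delay = 20, alpha = 0, n_steps = 24000, phi = 0.5,
                         sigma = 0.0039, seed = NULL) {
  lf_config(omega = 0.0067, sigma = sigma, delay = delay, alpha = alpha,
            n_steps = n_steps, fps = 40, phi = phi, seed = seed)
}

# Two-sided ensemble MI curve via the mirror convention.
mirrored_ensemble_curve <- function(reps, pos_grid, t_star, seed) {
  c01 <- mi_curve_ensemble(reps, pos_grid, t_star, seed = seed)
  c10 <- mi_curve_ensemble(reps, pos_grid, t_star, x = "theta0",
                           y = "theta1", seed = seed + 1L)
  mirror_combine(c01, c10)
}

# Wrapped angular difference helper for assertions.
ang_diff <- function(a, b) atan2(sin(a - b), cos(a - b))
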