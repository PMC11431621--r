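#' Configuration for the ring leader-follower dyad
#'
#' Bundles every parameter of the discrete-time leader-follower model on a
#' ring. At each step the current leader advances by a fixed angular drift
#' `omega` plus Gaussian noise; the current follower copies the leader's
#' angular position `delay` steps earlier, plus its own Gaussian noise, and
#' all angles are wrapped modulo \eqn{2\pi}. With probability `alpha` per
#' step the leader/follower labels are exchanged.
#'
#' @param omega Angular drift of the leader, radians per step.
#' @param sigma Standard deviation of the per-step Gaussian noise, radians.
#' @param delay Follower reaction delay \eqn{T}, in integer steps (>= 0).
#' @param n_steps Number of simulation steps (must exceed `delay`).
#' @param alpha Per-step probability of a leadership swap, in \[0, 1\].
#' @param fps Steps per second; sets the physical duration of one step
#'   (default 40, i.e. 0.025 s per step).
#' @param phi Initial angular offset: agent 1 starts at
#'   \eqn{\theta_0(0) - \phi} (mod \eqn{2\pi}).
#' @param theta0_init Optional fixed initial angle of agent 0; when `NULL`
#'   (default) it is drawn uniformly on \[0, 2\eqn{\pi}).
#' @param seed Integer seed. Leader noise, follower noise, swap draws and
#'   the initial angle use four independent sub-streams derived from it, so
#'   e.g. changing `alpha` leaves the noise sequences untouched.
#'
#' @return A list of class `"lf_config"`.
#' @seealso [simulate_lf_dyad()], [simulate_independent_pair()]
#' @export
#' @examples
#' cfg <- lf_config(omega = 0.0067, sigma = 0.0039, delay = 20,
#'                  n_steps = 2000, phi = 0.5, seed = 1)
#' dyad <- simulate_lf_dyad(cfg)
lf_config <- function(omega, sigma, delay, n_steps, alpha = 0, fps = 40,
                      phi = 0, theta0_init = NULL, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    abort("`sigma` must be a single non-negative number.")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    abort("`alpha` must lie in [0, 1].")
  if (!is.numeric(delay) || delay < 0 || delay != round(delay))
    abort("`delay` must be a non-negative integer number of steps.")
  if (!is.numeric(fps) || fps <= 0)
    abort("`fps` must be positive.")
  if (!is.numeric(n_steps) || n_steps != round(n_steps) || n_steps <= delay)
    abort("`n_steps` must be an integer greater than `delay`.")
  structure(
    list(omega = omega, sigma = sigma, delay = as.integer(delay),
         alpha = alpha, n_steps = as.integer(n_steps), fps = fps,
         phi = phi, theta0_init = theta0_init, seed = seed),
    class = "lf_config"
  )
}

#' @export
print.lf_config <- function(x, ...) {
  cat("<lf_config>\n")
  cat(sprintf("  omega = %g rad/step, sigma = %g rad/step\n", x$omega, x$sigma))
  cat(sprintf("  delay = %d steps (%.3f s at %g fps), alpha = %g\n",
              x$delay, x$delay / x$fps, x$fps, x$alpha))
  cat(sprintf("  n_steps = %d, phi = %g, seed = %s\n",
              x$n_steps, x$phi, if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

new_dyad_track <- function(t, theta0, theta1, leader_id, dt, config) {
  out <- tibble::tibble(t = t, theta0 = theta0, theta1 = theta1,
                        leader_id = leader_id)
  attr(out, "dt") <- dt
  attr(out, "config") <- config
  class(out) <- c("dyad_track", class(out))
  out
}

#' Simulate a leader-follower dyad on a ring
#'
#' Iterates the ring leader-follower model: the agent currently labelled
#' leader performs a drift-diffusion step
#' \eqn{\theta_L(t) = \theta_L(t-1) + \Omega + W_\sigma(t)}, the follower
#' copies the leader's history,
#' \eqn{\theta_F(t) = \theta_L(t-T) + W'_\sigma(t)}, and both are wrapped
#' onto \[0, 2\eqn{\pi}). Before step \eqn{T} the follower reads the
#' leader's initial position (the agents are taken to be immobile before
#' the start). Labels swap as independent Bernoulli(`alpha`) events per
#' step; after a swap the follower equation reads the *new* leader agent's
#' recorded history at \eqn{t - T}, which can produce a position jump of up
#' to the current separation.
#'
#' @param config An [lf_config()].
#' @return A `dyad_track` tibble with columns `t` (step index, starting at
#'   0), `theta0`, `theta1` (wrapped angles, radians) and `leader_id` (0 or
#'   1: which agent is the leader in effect at that step). The step
#'   duration (s) is stored in attribute `"dt"` and the generating
#'   configuration in `"config"`.
#' @export
simulate_lf_dyad <- function(config) {
  stopifnot(inherits(config, "lf_config"))
  n <- config$n_steps
  d <- config$delay
  seeds <- derive_seeds(config$seed, 4L)
  noise_l <- with_seed_if(seeds[1], rnorm(n, 0, config$sigma))
  noise_f <- with_seed_if(seeds[2], rnorm(n, 0, config$sigma))
  swapped <- with_seed_if(seeds[3], runif(n) < config$alpha)
  theta00 <- if (is.null(config$theta0_init)) {
    with_seed_if(seeds[4], runif(1, 0, 2 * pi))
  } else {
    wrap_2pi(config$theta0_init)
  }

  th <- matrix(NA_real_, n + 1L, 2L)
  th[1L, 1L] <- theta00
  th[1L, 2L] <- wrap_2pi(theta00 - config$phi)
  leader <- integer(n)

  # Swap events split 1..n into segments with a constant leader; within a
  # segment the leader path is a cumulative sum and the follower reads the
  # already-filled leader history, so each segment vectorises.
  swap_at <- which(swapped)
  starts <- unique(c(1L, swap_at))
  ends <- c(starts[-1L] - 1L, n)
  lead_of_seg <- cumsum(starts %in% swap_at) %% 2L
  for (s in seq_along(starts)) {
    a <- starts[s]; b <- ends[s]
    lc <- lead_of_seg[s] + 1L  # column of the leader agent
    fc <- 3L - lc
    th[(a + 1L):(b + 1L), lc] <-
      wrap_2pi(th[a, lc] + cumsum(config$omega + noise_l[a:b]))
    # Leader history at t - delay; clamped to the agent's initial position
    # for t < delay (covers both initialization and a swap before step T).
    src <- pmax((a:b) - d, 0L) + 1L
    th[(a + 1L):(b + 1L), fc] <- wrap_2pi(th[src, lc] + noise_f[a:b])
    leader[a:b] <- lead_of_seg[s]
  }

  new_dyad_track(t = 0:n, theta0 = th[, 1L], theta1 = th[, 2L],
                 leader_id = c(0L, leader), dt = 1 / config$fps,
                 config = config)
}

#' Simulate two non-interacting drift-diffusion agents on a ring
#'
#' Control case: both agents independently obey the leader dynamics
#' \eqn{\theta_i(t) = \theta_i(t-1) + \Omega + W_\sigma(t)} (wrapped), with
#' no following behaviour. `leader_id` is set to `NA` throughout as the
#' "no leader" sentinel.
#'
#' @inheritParams simulate_lf_dyad
#' @return A `dyad_track` tibble; see [simulate_lf_dyad()].
#' @export
simulate_independent_pair <- function(config) {
  stopifnot(inherits(config, "lf_config"))
  n <- config$n_steps
  seeds <- derive_seeds(config$seed, 4L)
  noise0 <- with_seed_if(seeds[1], rnorm(n, 0, config$sigma))
  noise1 <- with_seed_if(seeds[2], rnorm(n, 0, config$sigma))
  theta00 <- if (is.null(config$theta0_init)) {
    with_seed_if(seeds[4], runif(1, 0, 2 * pi))
  } else {
    wrap_2pi(config$theta0_init)
  }
  theta0 <- wrap_2pi(theta00 + c(0, cumsum(config$omega + noise0)))
  theta1 <- wrap_2pi(theta00 - config$phi + c(0, cumsum(config$omega + noise1)))
  new_dyad_track(t = 0:n, theta0 = theta0, theta1 = theta1,
                 leader_id = rep(NA_integer_, n + 1L), dt = 1 / config$fps,
                 config = config)
}

#' Simulate an ensemble of replicate dyads
#'
#' Runs `simulate` once per replicate with independent sub-seeds derived
#' from `seed` (each replicate also redraws its uniform initial angle).
#'
#' @param config An [lf_config()]; its `seed` is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param n_replicates Number of replicate simulations.
#' @param seed Master seed for the ensemble.
#' @param simulate Simulator to replicate, e.g. [simulate_lf_dyad()]
#'   (default) or [simulate_independent_pair()].
#' @return A list of `dyad_track` tibbles.
#' @export
simulate_lf_ensemble <- function(config, n_replicates, seed = NULL,
                                 simulate = simulate_lf_dyad) {
  seeds <- derive_seeds(seed, n_replicates)
  purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    simulate(cfg)
  })
}

#' Simulate a one-dimensional Gaussian random walker
#'
#' Free walker: \eqn{x(t+1) = x(t) + N(0, \sigma^2)} with \eqn{x(0) = 0}.
#' Ring walker (`confined = TRUE`): the same increments wrapped onto
#' \[0, 2\eqn{\pi}) (perimeter of a unit-radius disk), with
#' \eqn{\theta(0)} uniform unless `theta_init` is given. The confined
#' walker's angular distribution approaches uniformity for times much
#' longer than \eqn{2\pi/\sigma}.
#'
#' @param n_steps Number of steps.
#' @param sigma2 Step variance \eqn{\sigma^2} (> 0).
#' @param confined Logical: wrap onto the ring?
#' @param seed Integer seed.
#' @param theta_init Optional fixed initial angle for the ring case.
#' @return A `walker_track` tibble with columns `t` and `x` (free) or
#'   `theta` (ring); attributes `"sigma2"`, `"confined"`, `"dt"` (= 1).
#' @export
#' @examples
#' w <- simulate_walker(1000, sigma2 = 0.1, confined = TRUE, seed = 7)
simulate_walker <- function(n_steps, sigma2, confined = FALSE, seed = NULL,
                            theta_init = NULL) {
  if (!is.numeric(sigma2) || sigma2 <= 0) abort("`sigma2` must be > 0.")
  seeds <- derive_seeds(seed, 2L)
  inc <- with_seed_if(seeds[1], rnorm(n_steps, 0, sqrt(sigma2)))
  if (confined) {
    th0 <- if (is.null(theta_init)) with_seed_if(seeds[2], runif(1, 0, 2 * pi))
           else wrap_2pi(theta_init)
    out <- tibble::tibble(t = 0:n_steps, theta = wrap_2pi(th0 + c(0, cumsum(inc))))
  } else {
    out <- tibble::tibble(t = 0:n_steps, x = c(0, cumsum(inc)))
  }
  attr(out, "sigma2") <- sigma2
  attr(out, "confined") <- confined
  attr(out, "dt") <- 1
  class(out) <- c("walker_track", class(out))
  out
}

#' Exact time-separated self-information of the free Gaussian walker
#'
#' For a free one-dimensional Gaussian random walker the mutual information
#' between \eqn{x(t)} and \eqn{x(t+\tau)} has the closed form
#' \deqn{MI = \frac{1}{2}\,\ln\!\left(1 + t/\tau\right)}
#' in nats. It grows logarithmically with absolute time \eqn{t} because the
#' walker's positional variance grows linearly, which is why an unconfined
#' walker never reaches the stationarity needed for single-trajectory
#' estimation.
#'
#' @param t Absolute time, steps (>= 0).
#' @param tau Time separation, steps (> 0).
#' @param units `"nats"` (default) or `"bits"`.
#' @return Mutual information (vectorised over `t`).
#' @export
#' @examples
#' analytic_free_walker_mi(10, 10)  # 0.5 * log(2)
analytic_free_walker_mi <- function(t, tau, units = c("nats", "bits")) {
  units <- match.arg(units)
  if (any(tau <= 0)) abort("`tau` must be > 0.")
  if (any(t < 0)) abort("`t` must be >= 0.")
  mi <- 0.5 * log(1 + t / tau)
  if (units == "bits") mi / log(2) else mi
}

#' Write / read a dyad track as CSV
#'
#' Columns `t, theta0, theta1, leader_id`; the step duration and generating
#' configuration are carried as `# key=value` header comments so a run can
#' be replayed from its output alone.
#'
#' @param track A `dyad_track` tibble.
#' @param path File path.
#' @param extra_header Additional `# key=value` comment lines to embed.
#' @return `write_track_csv()` returns `path` invisibly; `read_track_csv()`
#'   returns a `dyad_track` tibble.
#' @export
write_track_csv <- function(track, path, extra_header = character()) {
  cfg <- attr(track, "config")
  hdr <- c(extra_header, sprintf("# dt=%.17g", attr(track, "dt")))
  if (!is.null(cfg)) {
    keep <- !vapply(cfg, is.null, logical(1))
    hdr <- c(hdr, sprintf("# %s=%.17g", names(cfg)[keep],
                          as.numeric(unlist(cfg[keep]))))
  }
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(track)[c("t", "theta0", "theta1", "leader_id")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  meta <- read_header_meta(path)
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  dt <- if (!is.null(meta$dt)) as.numeric(meta$dt) else 1 / 40
  new_dyad_track(t = dat$t, theta0 = dat$theta0, theta1 = dat$theta1,
                 leader_id = dat$leader_id, dt = dt, config = meta)
}

# Parse leading "# key=value" comment lines into a named list.
read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1L, eq - 1L)
      val <- substr(kv, eq + 1L, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  meta
}
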