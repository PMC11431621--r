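new_mi_curve <- function(tau_s, mi_nats, se_nats, n, convention, k) {
  out <- tibble::tibble(tau_s = tau_s, mi_nats = mi_nats,
                        se_nats = se_nats, n = n)
  attr(out, "convention") <- convention
  attr(out, "k") <- k
  class(out) <- c("mi_curve", class(out))
  out
}

#' Default time-separation grid for dyad analyses
#'
#' A uniform grid of `n` points on `[-tau_max, tau_max]` seconds (81
#' points on \[-2.5, 2.5\] by default, spanning the range over which dyad
#' MI curves decay towards their plateau at typical fish reaction
#' timescales).
#'
#' @param tau_max Half-range, seconds.
#' @param n Number of grid points (odd keeps 0 on the grid).
#' @export
default_tau_grid <- function(tau_max = 2.5, n = 81L) {
  seq(-tau_max, tau_max, length.out = n)
}

track_dt <- function(track) {
  dt <- attr(track, "dt")
  if (is.null(dt)) 1 else dt
}

# Convert tau (seconds) to integer step lags given the step duration.
tau_to_lag <- function(tau, dt) as.integer(round(tau / dt))

#' Ensemble estimate of the time-separated mutual information curve
#'
#' For each time separation \eqn{\tau} on `tau_grid`, forms one sample
#' pair per replicate, \eqn{(\theta_1(t^*),\ \theta_0(t^* - \tau))},
#' draws `n_subsets` random subsets of `subset_size` pairs (each without
#' replacement), runs the KSG estimator on every subset, and reports the
#' subset mean with its standard error. The sampling step \eqn{t^*} must
#' be late enough that every replicate has reached its stationary state.
#'
#' Because the subsets overlap heavily (each retains `subset_size` of the
#' `length(replicates)` pairs), a naive `sd/sqrt(m)` across subsets would
#' shrink towards zero with the subset count while the true uncertainty
#' does not. The reported `se_nats` therefore uses the delete-d jackknife
#' variance estimator,
#' \eqn{SE^2 = \frac{n - d}{d}\,\overline{(\widehat{MI}_i - \overline{MI})^2}}
#' with \eqn{d = n - } `subset_size`, which is calibrated against the
#' spread between fully independent ensembles.
#'
#' By the package's sign convention, positive \eqn{\tau} presumes agent 0
#' is the leader (agent 1 now vs agent 0 in the past). Negative \eqn{\tau}
#' values are allowed only when `t_star - tau` stays inside the simulated
#' range; the usual way to build a full two-sided curve is to estimate
#' both index orderings on a positive grid and join them with
#' [mirror_combine()].
#'
#' @param replicates List of replicate tracks (e.g. from
#'   [simulate_lf_ensemble()]); each must contain the columns named by
#'   `x` and `y` and share the same step duration.
#' @param tau_grid Time separations, seconds (strictly increasing).
#' @param t_star Sampling step index (in steps, counting from 0).
#' @param n_subsets,subset_size Jackknife subset count and size
#'   (defaults 10 and 250).
#' @param k KSG neighbour count.
#' @param x,y Column names of the "now" and "past" series (defaults
#'   `"theta1"` and `"theta0"`).
#' @param metric `"linear"` treats wrapped angles as points on the line
#'   (the default, matching a naive application); `"chord"` embeds
#'   \eqn{\theta \to (\cos\theta, \sin\theta)} before estimation.
#' @param seed Optional seed for the subset draws.
#' @return An `mi_curve` tibble with columns `tau_s`, `mi_nats`,
#'   `se_nats`, `n` (pairs per estimate).
#' @export
mi_curve_ensemble <- function(replicates, tau_grid, t_star,
                              n_subsets = 10L, subset_size = 250L, k = 4L,
                              x = "theta1", y = "theta0",
                              metric = c("linear", "chord"), seed = NULL) {
  metric <- match.arg(metric)
  n_rep <- length(replicates)
  if (n_rep < subset_size)
    abort(sprintf(
      "insufficient replicates: %d supplied but subsets of %d requested (shortfall %d).",
      n_rep, subset_size, subset_size - n_rep))
  if (is.unsorted(tau_grid, strictly = TRUE))
    abort("`tau_grid` must be strictly increasing.")
  dt <- track_dt(replicates[[1L]])
  lags <- tau_to_lag(tau_grid, dt)
  n_len <- nrow(replicates[[1L]])
  idx <- t_star - lags + 1L
  if (any(idx < 1L | idx > n_len))
    abort("`t_star - tau` falls outside the simulated range for some tau.")

  xs <- vapply(replicates, function(tr) tr[[x]][t_star + 1L], numeric(1))
  ymat <- vapply(replicates, function(tr) tr[[y]][idx], numeric(length(idx)))
  if (length(idx) == 1L) ymat <- matrix(ymat, nrow = 1L)

  with_seed_if(seed, {
    res <- purrr::map(seq_along(tau_grid), function(ti) {
      ys <- ymat[ti, ]
      subs <- jackknife_subsets(n_rep, n_subsets, subset_size)
      est <- vapply(subs, function(s) {
        ksg_pair_mi(xs[s], ys[s], k, metric)
      }, numeric(1))
      d_del <- n_rep - subset_size
      se <- if (d_del > 0) {
        sqrt((subset_size / d_del) * mean((est - mean(est))^2))
      } else {
        sd(est) / sqrt(length(est)) # subsets = full set: plain spread
      }
      c(mean(est), se)
    })
  })
  m <- do.call(rbind, res)
  new_mi_curve(tau_s = tau_grid, mi_nats = m[, 1L], se_nats = m[, 2L],
               n = rep(as.integer(subset_size), length(tau_grid)),
               convention = paste0(y, " presumed leader on tau > 0"), k = k)
}

ksg_pair_mi <- function(xv, yv, k, metric) {
  if (metric == "chord") {
    ksg_mi(chord_embed(xv), chord_embed(yv), k = k)
  } else {
    ksg_mi(xv, yv, k = k)
  }
}

#' Single-trajectory estimate of the time-separated mutual information
#'
#' Estimates \eqn{MI(\theta_1(t);\ \theta_0(t-\tau))} from one long
#' trajectory by decorrelated subsampling: the \eqn{\theta_1} series is
#' divided into windows of `W` steps and one time point per window is
#' drawn from a symmetric triangular distribution
#' ([windowed_indices()]), so consecutive samples are `W` steps apart on
#' average while the full data range is retained. The random selection is
#' repeated `n_resamples` times and the mean estimate is reported per
#' \eqn{\tau} with the standard deviation across resamples as its error
#' bar: the resamples all share the one trajectory, so dividing by
#' \eqn{\sqrt{m}} as if they were independent would understate the
#' uncertainty.
#'
#' Pairs whose shifted index falls outside the series, or whose members
#' are `NA` (masked frames), are dropped. A grid point left with fewer
#' than `k + 2` valid pairs is reported as `NA` with a warning rather
#' than silently omitted.
#'
#' @param dyad A data frame holding both angle series (columns named by
#'   `x` and `y`), e.g. a `dyad_track` or the output of
#'   [bind_dyad()]. The step duration is taken from its `"dt"` attribute
#'   (1 s if absent).
#' @param W Window length, steps.
#' @param n_resamples Number of repeated random selections (default 10).
#' @inheritParams mi_curve_ensemble
#' @return An `mi_curve` tibble.
#' @export
mi_curve_single <- function(dyad, tau_grid, W, n_resamples = 10L, k = 4L,
                            x = "theta1", y = "theta0",
                            metric = c("linear", "chord"), seed = NULL) {
  metric <- match.arg(metric)
  if (W < 1) abort("`W` must be >= 1.")
  if (is.unsorted(tau_grid, strictly = TRUE))
    abort("`tau_grid` must be strictly increasing.")
  dt <- track_dt(dyad)
  lags <- tau_to_lag(tau_grid, dt)
  xv <- dyad[[x]]
  yv <- dyad[[y]]
  n_len <- length(xv)

  with_seed_if(seed, {
    est <- matrix(NA_real_, n_resamples, length(tau_grid))
    npairs <- matrix(0L, n_resamples, length(tau_grid))
    for (r in seq_len(n_resamples)) {
      idx <- windowed_indices(n_len, W)
      for (ti in seq_along(lags)) {
        j <- idx - lags[ti]
        keep <- j >= 1L & j <= n_len
        xi <- xv[idx[keep]]
        yi <- yv[j[keep]]
        ok <- !is.na(xi) & !is.na(yi)
        npairs[r, ti] <- sum(ok)
        if (sum(ok) >= k + 2L)
          est[r, ti] <- ksg_pair_mi(xi[ok], yi[ok], k, metric)
      }
    }
  })
  bad <- apply(est, 2L, function(col) anyNA(col))
  if (any(bad))
    warn(sprintf("too few valid pairs at tau = %s; reported as NA.",
                 paste(signif(tau_grid[bad], 4), collapse = ", ")))
  mi <- colMeans(est)
  se <- if (n_resamples > 1L) {
    apply(est, 2L, sd)
  } else {
    rep(NA_real_, length(tau_grid))
  }
  new_mi_curve(tau_s = tau_grid, mi_nats = mi, se_nats = se,
               n = as.integer(round(colMeans(npairs))),
               convention = paste0(y, " presumed leader on tau > 0"), k = k)
}

#' Self mutual information of a single series
#'
#' Convenience wrapper: pairs a series with itself so that
#' \eqn{MI(s(t);\ s(t-\tau))} can be estimated with the machinery of
#' [mi_curve_single()]. With `W = 1` and `n_resamples = 1` this is the
#' naive estimate that treats every time point as an independent sample;
#' with `W` of the order of the decorrelation time (e.g. 300 steps for a
#' ring walker with \eqn{\sigma^2 = 0.1}) the estimate matches the
#' ensemble ground truth.
#'
#' @param track A `walker_track` (column `theta` or `x`) or any data
#'   frame with a single series column named by `col`.
#' @param col Series column; defaults to `theta` if present, else `x`.
#' @inheritParams mi_curve_single
#' @export
mi_curve_self <- function(track, tau_grid, W, n_resamples = 10L, k = 4L,
                          col = NULL, seed = NULL) {
  if (is.null(col)) col <- if ("theta" %in% names(track)) "theta" else "x"
  d <- tibble::tibble(theta0 = track[[col]], theta1 = track[[col]])
  attr(d, "dt") <- track_dt(track)
  mi_curve_single(d, tau_grid, W, n_resamples = n_resamples, k = k,
                  seed = seed)
}

#' Join the two presumed-leader orderings into one two-sided curve
#'
#' At steady state the index-swapped information
#' \eqn{MI(\theta_0(t);\ \theta_1(t-\tau))} is the reflection of
#' \eqn{MI(\theta_1(t);\ \theta_0(t-\tau))} across \eqn{\tau = 0}, so the
#' two one-sided estimates can be plotted on a single axis: the positive
#' branch presumes agent 0 leads, the negative branch (the `curve_10`
#' estimates placed at \eqn{-\tau}) presumes agent 1 leads. Both curves
#' must be computed on the same non-negative grid; at \eqn{\tau = 0} the
#' `curve_01` estimate is kept.
#'
#' @param curve_01 `mi_curve` for pairs \eqn{(\theta_1(t), \theta_0(t-\tau))}.
#' @param curve_10 `mi_curve` for the index-swapped pairs.
#' @return An `mi_curve` on the symmetric grid.
#' @export
mirror_combine <- function(curve_01, curve_10) {
  if (length(curve_01$tau_s) != length(curve_10$tau_s) ||
      any(abs(curve_01$tau_s - curve_10$tau_s) > 1e-9))
    abort("`curve_01` and `curve_10` must share the same tau grid.")
  if (any(curve_01$tau_s < 0))
    abort("mirror_combine() expects curves on a non-negative tau grid.")
  neg <- curve_10$tau_s > 0
  new_mi_curve(
    tau_s = c(-rev(curve_10$tau_s[neg]), curve_01$tau_s),
    mi_nats = c(rev(curve_10$mi_nats[neg]), curve_01$mi_nats),
    se_nats = c(rev(curve_10$se_nats[neg]), curve_01$se_nats),
    n = c(rev(curve_10$n[neg]), curve_01$n),
    convention = "theta0 presumed leader on tau > 0; theta1 on tau < 0",
    k = attr(curve_01, "k")
  )
}

#' Write / read an MI curve as CSV
#'
#' Columns `tau_s, mi_nats, se_nats, n`; the sign convention and neighbour
#' count are recorded as `# key=value` header comments.
#'
#' @param curve An `mi_curve`.
#' @param path File path.
#' @param extra_header Additional `# key=value` comment lines to embed.
#' @export
write_mi_curve <- function(curve, path, extra_header = character()) {
  hdr <- c(extra_header,
           sprintf("# convention=%s", attr(curve, "convention")),
           sprintf("# k=%s", attr(curve, "k")))
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(curve), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_mi_curve
#' @export
read_mi_curve <- function(path) {
  meta <- read_header_meta(path)
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  new_mi_curve(dat$tau_s, dat$mi_nats, dat$se_nats, dat$n,
               convention = meta$convention, k = meta$k)
}

#' Plot an MI curve
#'
#' Line plot of the mean mutual information against time separation with
#' a +/- 1 SE ribbon. Positive time separations presume agent 0 is the
#' leader.
#'
#' @param object An `mi_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mi_curve
#' @export
autoplot.mi_curve <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau_s, y = .data$mi_nats))
  if (!all(is.na(dat$se_nats))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mi_nats - .data$se_nats,
                   ymax = .data$mi_nats + .data$se_nats),
      fill = "grey70", alpha = 0.6)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = "MI (nats)")
}
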