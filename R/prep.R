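#' Construct a planar track
#'
#' Per-frame centroid and head positions of one tracked animal, in cm, as
#' produced by top-view video tracking. Missing frames (tracking
#' failures) are encoded as `NA` coordinates; downstream operations treat
#' them as masked and never interpolate across them.
#'
#' @param frame Strictly increasing integer frame indices.
#' @param x,y Centroid coordinates, cm.
#' @param hx,hy Head coordinates, cm.
#' @param fps Frames per second (default 40).
#' @return A `planar_track` tibble with columns `frame, x, y, hx, hy` and
#'   attribute `"fps"`.
#' @export
planar_track <- function(frame, x, y, hx, hy, fps = 40) {
  if (is.unsorted(frame, strictly = TRUE))
    abort("`frame` must be strictly increasing.")
  out <- tibble::tibble(frame = as.integer(frame), x = x, y = y,
                        hx = hx, hy = hy)
  attr(out, "fps") <- fps
  class(out) <- c("planar_track", class(out))
  out
}

track_fps <- function(track) {
  fps <- attr(track, "fps")
  if (is.null(fps)) 40 else fps
}

#' Transform a planar track to polar coordinates about the tank centre
#'
#' Shifts the origin to `center` and computes the radius `r` (cm), the
#' wrapped angular position `theta` in \[0, 2\eqn{\pi}) and the unwrapped
#' angle `theta_unwrapped`, which accumulates full laps by summing wrapped
#' frame-to-frame differences across valid frames. A frame whose centroid
#' coincides exactly with the centre has no defined angle and is masked.
#'
#' @param track A [planar_track()].
#' @param center Tank centre `c(x, y)`, cm.
#' @return The track with columns `r`, `theta`, `theta_unwrapped` added.
#' @export
to_polar <- function(track, center = c(0, 0)) {
  if (!all(is.finite(center)) || length(center) != 2L)
    abort("`center` must be two finite coordinates.")
  dx <- track$x - center[1L]
  dy <- track$y - center[2L]
  r <- sqrt(dx^2 + dy^2)
  theta <- wrap_2pi(atan2(dy, dx))
  theta[!is.na(r) & r == 0] <- NA_real_
  out <- dplyr::mutate(track, r = r, theta = theta,
                       theta_unwrapped = unwrap_angles(theta))
  class(out) <- unique(c("planar_track", class(out)))
  attr(out, "fps") <- track_fps(track)
  out
}

# Accumulate wrapped angle differences across valid frames; NA frames stay
# NA and do not break continuity of the surrounding laps.
unwrap_angles <- function(theta) {
  out <- rep(NA_real_, length(theta))
  v <- which(!is.na(theta))
  if (length(v) == 0L) return(out)
  out[v] <- theta[v[1L]] + c(0, cumsum(wrap_pi(diff(theta[v]))))
  out
}

#' Compute the heading angle of a tracked animal
#'
#' The heading \eqn{\psi} is the angle between the positive x-axis and the
#' vector from the centroid to the head, wrapped to \[0, 2\eqn{\pi}).
#' Frames where the head coincides with the centroid are masked.
#'
#' @param track A [planar_track()].
#' @return The track with a `psi` column added.
#' @export
heading <- function(track) {
  dx <- track$hx - track$x
  dy <- track$hy - track$y
  psi <- wrap_2pi(atan2(dy, dx))
  psi[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  out <- dplyr::mutate(track, psi = psi)
  class(out) <- unique(c("planar_track", class(out)))
  attr(out, "fps") <- track_fps(track)
  out
}

#' Repair head/tail identification flips in a heading series
#'
#' Video trackers occasionally mistake the tail for the head, making the
#' heading jump by nearly 180 degrees between consecutive frames. Scanning
#' forward, whenever the wrapped angular jump from the (already corrected)
#' previous valid heading exceeds `threshold` (default \eqn{\pi - 0.6}
#' rad), the new value is overwritten with that previous heading.
#' Corrections cascade, so a run of consecutive flipped frames is repaired
#' as a block, and the transform is idempotent.
#'
#' @param psi A numeric heading series (radians), or a data frame with a
#'   `psi` column (in which case `psi` is replaced and the raw series kept
#'   as `psi_raw`).
#' @param threshold Jump threshold in radians, in (0, \eqn{\pi}\].
#' @return Corrected series (or data frame).
#' @export
#' @examples
#' fix_heading_flips(c(0.1, 0.12, 3.25, 0.15))
fix_heading_flips <- function(psi, threshold = pi - 0.6) {
  if (threshold <= 0 || threshold > pi)
    abort("`threshold` must lie in (0, pi].")
  if (is.data.frame(psi)) {
    out <- dplyr::mutate(psi, psi_raw = .data$psi,
                         psi = fix_heading_flips(.data$psi, threshold))
    return(out)
  }
  out <- psi
  last <- NA_real_
  for (i in seq_along(out)) {
    if (is.na(out[i])) next
    if (!is.na(last) && abs(wrap_pi(out[i] - last)) > threshold)
      out[i] <- last
    last <- out[i]
  }
  out
}

#' Alignment angle between one animal's heading and its partner
#'
#' \eqn{A_{ij}(t)} is the unsigned angle in \[0, \eqn{\pi}\] between the
#' heading vector of animal \eqn{i} and the vector from \eqn{i}'s centroid
#' to \eqn{j}'s centroid: near 0 when \eqn{i} swims directly towards
#' \eqn{j} (chasing), near \eqn{\pi} when it swims directly away
#' (leading). Intervals of leader-follower behaviour show
#' \eqn{A_{ij} \approx 0} with \eqn{A_{ji} \approx \pi} (or vice versa).
#'
#' @param track_i Track of animal \eqn{i}; must carry a `psi` column (see
#'   [heading()]).
#' @param track_j Track of animal \eqn{j} (centroids only are used).
#' @return A tibble with columns `frame`, `t_s` (seconds) and `alignment`
#'   (radians); frames with coincident centroids or masked data are `NA`.
#' @export
alignment <- function(track_i, track_j) {
  if (!"psi" %in% names(track_i))
    abort("`track_i` must have a `psi` column; call heading() first.")
  if (nrow(track_i) != nrow(track_j))
    abort("tracks must cover the same frames.")
  dx <- track_j$x - track_i$x
  dy <- track_j$y - track_i$y
  sep_ang <- atan2(dy, dx)
  coincident <- !is.na(dx) & !is.na(dy) & dx == 0 & dy == 0
  a <- abs(wrap_pi(sep_ang - track_i$psi))
  a[coincident] <- NA_real_
  fps <- track_fps(track_i)
  tibble::tibble(frame = track_i$frame, t_s = track_i$frame / fps,
                 alignment = a)
}

#' Mask-aware centred rolling mean
#'
#' Moving average over a centred time window, excluding masked (`NA`)
#' frames from both numerator and denominator; edge windows average over
#' the frames available. A `window` of 15 s at 40 fps averages over
#' exactly 600 frames.
#'
#' @param x Numeric series (may contain `NA`).
#' @param window Window length in seconds (> 0).
#' @param fps Frames per second.
#' @return Smoothed series; points whose window holds no valid frame are
#'   `NA`.
#' @export
rolling_mean <- function(x, window = 15, fps = 40) {
  if (window <= 0) abort("`window` must be > 0.")
  n <- length(x)
  nf <- max(1L, as.integer(round(window * fps)))
  lo <- -(ceiling(nf / 2) - 1L)
  hi <- nf %/% 2L
  valid <- !is.na(x)
  vals <- ifelse(valid, x, 0)
  S <- c(0, cumsum(vals))
  C <- c(0, cumsum(as.integer(valid)))
  i <- seq_len(n)
  a <- pmax(1L, i + lo)
  b <- pmin(n, i + hi)
  cnt <- C[b + 1L] - C[a]
  out <- (S[b + 1L] - S[a]) / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Estimate the drift and noise of the angular dynamics
#'
#' Computes per-frame angular increments
#' \eqn{\Delta\theta_i(t) = \theta_i(t+1) - \theta_i(t)}, wrapped into
#' \eqn{(-\pi, \pi]} so that lap boundaries do not corrupt the estimate,
#' pooled over both animals across the whole series. The drift
#' \eqn{\Omega} is their mean and the noise \eqn{\sigma} their standard
#' deviation, both in radians per step. Increments spanning a masked
#' frame are dropped.
#'
#' @param theta0 First wrapped angle series, or a data frame with columns
#'   `theta0` and `theta1`.
#' @param theta1 Second series (ignored when `theta0` is a data frame).
#' @return A one-row tibble with columns `omega`, `sigma` and `n` (number
#'   of increments used).
#' @export
estimate_drift_noise <- function(theta0, theta1 = NULL) {
  if (is.data.frame(theta0)) {
    theta1 <- theta0$theta1
    theta0 <- theta0$theta0
  }
  d <- c(wrap_pi(diff(theta0)),
         if (!is.null(theta1)) wrap_pi(diff(theta1)))
  d <- d[!is.na(d)]
  if (length(d) < 2L)
    abort("need at least two valid consecutive frames to estimate drift and noise.")
  tibble::tibble(omega = mean(d), sigma = sd(d), n = length(d))
}

#' Pair two polar tracks into a dyad table
#'
#' Joins the wrapped angle series of two animals into the two-column form
#' expected by [mi_curve_single()] and [estimate_drift_noise()].
#'
#' @param polar0,polar1 Tracks with a `theta` column (see [to_polar()]),
#'   covering the same frames.
#' @return A tibble with columns `t`, `theta0`, `theta1` and a `"dt"`
#'   attribute (seconds per frame).
#' @export
bind_dyad <- function(polar0, polar1) {
  if (nrow(polar0) != nrow(polar1))
    abort("tracks must cover the same frames.")
  out <- tibble::tibble(t = polar0$frame, theta0 = polar0$theta,
                        theta1 = polar1$theta)
  attr(out, "dt") <- 1 / track_fps(polar0)
  out
}
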