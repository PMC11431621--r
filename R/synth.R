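#' Configuration for rendering a dyad as tracking-style planar data
#'
#' Parameters controlling how an angular dyad simulation is rendered into
#' per-frame centroid/head positions of two fish in an annular tank, in
#' the tabular format produced by video tracking software, including the
#' two realistic artifacts the preprocessing must repair: head/tail
#' identification flips and missing frames.
#'
#' @param r_mean Mean swimming radius, cm (default 30).
#' @param r_jitter_sd Stationary standard deviation of the AR(1) radial
#'   jitter, cm (default 2).
#' @param body_length Fish body length, cm (default 6); the head sits half
#'   a body length ahead of the centroid.
#' @param p_flip Per-frame probability that the tail is mistaken for the
#'   head (heading vector negated).
#' @param p_miss Per-frame probability that tracking fails and the frame
#'   is blank.
#' @param fps Frames per second (default 40).
#' @param outer_diameter,inner_diameter Tank annulus, cm (defaults 125.1
#'   and 26.2).
#' @param ar_coef AR(1) coefficient of the radial jitter (default 0.95),
#'   keeping the radius smooth between frames.
#' @param seed Integer seed.
#' @return A list of class `"render_config"`.
#' @export
render_config <- function(r_mean = 30, r_jitter_sd = 2, body_length = 6,
                          p_flip = 0, p_miss = 0, fps = 40,
                          outer_diameter = 125.1, inner_diameter = 26.2,
                          ar_coef = 0.95, seed = NULL) {
  if (p_flip < 0 || p_flip > 1 || p_miss < 0 || p_miss > 1)
    abort("`p_flip` and `p_miss` must lie in [0, 1].")
  inner_r <- inner_diameter / 2
  outer_r <- outer_diameter / 2
  if (r_mean <= inner_r || r_mean >= outer_r)
    abort("`r_mean` must lie strictly inside the annulus.")
  if (r_mean - 3 * r_jitter_sd < inner_r || r_mean + 3 * r_jitter_sd > outer_r)
    warn("radial jitter reaches within 3 SD of a tank wall; radii will be clipped.")
  structure(
    list(r_mean = r_mean, r_jitter_sd = r_jitter_sd,
         body_length = body_length, p_flip = p_flip, p_miss = p_miss,
         fps = fps, outer_r = outer_r, inner_r = inner_r,
         ar_coef = ar_coef, seed = seed),
    class = "render_config"
  )
}

#' Render an angular dyad as two planar tracking-style tracks
#'
#' Converts the wrapped angle series of a simulated dyad into per-frame
#' centroid and head positions: the centroid of each fish sits at radius
#' \eqn{r_i(t)} (mean radius plus smooth AR(1) jitter, clipped to the
#' annulus) and angle \eqn{\theta_i(t)}; the head sits half a body length
#' from the centroid along the instantaneous direction of angular motion
#' (the tangent, signed by the wrapped angular increment). With
#' probability `p_flip` the head vector is negated, emulating head/tail
#' confusion by the tracker; with probability `p_miss` the frame is
#' blanked entirely.
#'
#' @param dyad A `dyad_track` (see [simulate_lf_dyad()]).
#' @param cfg A [render_config()].
#' @return A list with elements `fish0` and `fish1`, each a
#'   [planar_track()].
#' @export
render_planar <- function(dyad, cfg) {
  stopifnot(inherits(cfg, "render_config"))
  seeds <- derive_seeds(cfg$seed, 6L)
  list(
    fish0 = render_one(dyad$theta0, cfg, seeds[1:3]),
    fish1 = render_one(dyad$theta1, cfg, seeds[4:6])
  )
}

render_one <- function(theta, cfg, seeds) {
  n <- length(theta)
  r <- if (cfg$r_jitter_sd > 0) {
    innov <- with_seed_if(seeds[1], rnorm(n, 0, cfg$r_jitter_sd * sqrt(1 - cfg$ar_coef^2)))
    dev0 <- with_seed_if(seeds[1] + 1L, rnorm(1, 0, cfg$r_jitter_sd))
    dev <- as.numeric(stats::filter(innov, cfg$ar_coef, method = "recursive",
                                    init = dev0))
    cfg$r_mean + dev
  } else {
    rep(cfg$r_mean, n)
  }
  bl2 <- cfg$body_length / 2
  r <- pmin(pmax(r, cfg$inner_r + bl2), cfg$outer_r - bl2)

  x <- r * cos(theta)
  y <- r * sin(theta)

  # Direction of angular motion: sign of the wrapped increment smoothed
  # over ~0.5 s (a fish's body orientation cannot flip on a single noisy
  # frame), carried forward through zero frames (CCW at the start).
  inc <- wrap_pi(c(theta[2] - theta[1], diff(theta)))
  s <- sign(rolling_mean(inc, window = 0.5, fps = cfg$fps))
  last_nz <- cummax(ifelse(s != 0, seq_along(s), 0L))
  s <- ifelse(last_nz == 0L, 1, s[pmax(last_nz, 1L)])
  psi <- theta + s * pi / 2

  flip <- with_seed_if(seeds[2], runif(n) < cfg$p_flip)
  sgn <- ifelse(flip, -1, 1)
  hx <- x + sgn * bl2 * cos(psi)
  hy <- y + sgn * bl2 * sin(psi)

  miss <- with_seed_if(seeds[3], runif(n) < cfg$p_miss)
  x[miss] <- y[miss] <- hx[miss] <- hy[miss] <- NA_real_

  planar_track(frame = seq_len(n) - 1L, x = x, y = y, hx = hx, hy = hy,
               fps = cfg$fps)
}

#' Write / read a two-fish track table in tracking-software CSV dialect
#'
#' Columns `frame, x0, y0, hx0, hy0, x1, y1, hx1, hy1` (cm), blank cells
#' for missing frames, and the frame rate carried as a `# fps=...` header
#' comment. The round trip is lossless, including masked frames.
#'
#' @param tracks A list with elements `fish0` and `fish1`
#'   ([planar_track()]s covering the same frames).
#' @param path File path.
#' @param fps Frame rate override for `read_trex_csv()`; by default the
#'   header value (or 40 if absent) is used.
#' @return `write_trex_csv()` returns `path` invisibly; `read_trex_csv()`
#'   a list with elements `fish0`, `fish1`.
#' @export
write_trex_csv <- function(tracks, path) {
  t0 <- tracks$fish0
  t1 <- tracks$fish1
  if (nrow(t0) != nrow(t1) || any(t0$frame != t1$frame))
    abort("the two tracks must cover the same frames.")
  dat <- tibble::tibble(frame = t0$frame,
                        x0 = t0$x, y0 = t0$y, hx0 = t0$hx, hy0 = t0$hy,
                        x1 = t1$x, y1 = t1$y, hx1 = t1$hx, hy1 = t1$hy)
  writeLines(sprintf("# fps=%.17g", track_fps(t0)), path)
  readr::write_csv(dat, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_trex_csv
#' @export
read_trex_csv <- function(path, fps = NULL) {
  meta <- read_header_meta(path)
  if (is.null(fps)) fps <- if (!is.null(meta$fps)) as.numeric(meta$fps) else 40
  cols <- c("frame", "x0", "y0", "hx0", "hy0", "x1", "y1", "hx1", "hy1")
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0L)
    abort(sprintf("malformed rows in %s (first at line %d): %s",
                  path, probs$row[1L], probs$expected[1L]))
  if (!all(cols %in% names(dat)))
    abort(sprintf("missing columns: %s",
                  paste(setdiff(cols, names(dat)), collapse = ", ")))
  list(
    fish0 = planar_track(dat$frame, dat$x0, dat$y0, dat$hx0, dat$hy0, fps = fps),
    fish1 = planar_track(dat$frame, dat$x1, dat$y1, dat$hx1, dat$hy1, fps = fps)
  )
}
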