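#' Draw indices from a symmetric triangular distribution on an interval
#'
#' One time point is drawn from the symmetric triangular density
#' \deqn{f(t) = 4 (t - t_i) / W^2 \quad (t \le \mathrm{mid}), \qquad
#'       f(t) = 4 (t_{i+1} - t) / W^2 \quad (t > \mathrm{mid})}
#' on the interval \eqn{[t_i, t_{i+1})} of length \eqn{W}, so points near
#' the middle of the interval are much more likely than points near its
#' ends. The continuous draw is rounded to the nearest integer index
#' within the interval; with \eqn{W = 1} the single index is returned
#' deterministically.
#'
#' @param lower Interval start \eqn{t_i} (integer index).
#' @param width Interval length \eqn{W} (>= 1).
#' @param n Number of draws.
#' @return Integer indices in `[lower, lower + width - 1]`.
#' @export
triangular_sample <- function(lower, width, n = 1L) {
  if (width < 1) abort("interval length `width` must be >= 1.")
  u <- runif(n)
  x <- ifelse(u < 0.5,
              lower + width * sqrt(u / 2),
              lower + width * (1 - sqrt((1 - u) / 2)))
  pmin(pmax(as.integer(round(x)), as.integer(lower)),
       as.integer(lower) + as.integer(width) - 1L)
}

#' One decorrelated index per window of a time series
#'
#' Divides `1..n_steps` into consecutive intervals of length `W` (a
#' trailing partial interval is discarded) and draws one index per
#' interval from the symmetric triangular distribution of
#' [triangular_sample()]. Consecutive draws are `W` steps apart on
#' average, which is what decorrelates samples taken from a single
#' trajectory. `W = 1` degenerates to selecting every index.
#'
#' @param n_steps Series length.
#' @param W Window length in steps (>= 1).
#' @return A strictly increasing integer vector of length
#'   `floor(n_steps / W)`.
#' @export
windowed_indices <- function(n_steps, W) {
  if (n_steps < W) abort("`n_steps` must be at least `W`.")
  W <- as.integer(W)
  n_win <- n_steps %/% W
  starts <- (seq_len(n_win) - 1L) * W + 1L
  triangular_sample(starts, W, n = n_win)
}

#' Random subsets for jackknife-style error bars
#'
#' Draws `n_subsets` index subsets of size `subset_size`, each sampled
#' without replacement from `1..N` and independently of the others. Used
#' to attach standard errors to mutual information estimates (e.g. ten
#' subsets of 250 pairs from a 300-replicate ensemble).
#'
#' @param N Population size.
#' @param n_subsets Number of subsets.
#' @param subset_size Size of each subset (<= N).
#' @return A list of integer vectors.
#' @export
jackknife_subsets <- function(N, n_subsets, subset_size) {
  if (subset_size > N)
    abort(sprintf("`subset_size` (%d) exceeds N (%d).", subset_size, N))
  purrr::map(seq_len(n_subsets), function(i) sample.int(N, subset_size))
}
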