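# Multi-tau software correlator and correlation-curve utilities.

#' Multi-tau correlator configuration
#'
#' Defaults resolve phantom and tissue decays at both source-detector
#' distances: 200 ns base bin, 16 points per octave, 20 octaves
#' (lags ~200 ns to ~20 ms).
#'
#' @param base_bin_s smallest bin width, s (>= 1e-12)
#' @param m points per octave (even, >= 2); level 0 evaluates lags `1..m`
#'   in base-bin units, deeper levels `m/2+1..m` at doubled widths
#' @param octaves number of bin-doubling levels
#' @param normalization `"symmetric"` (window-restricted mean rates at both
#'   ends of the lag; the default and recommended scheme)
#' @param window_s optional analysis window length for [windowed_g2()], s
#' @return object of class `correlator_config`
#' @export
correlator_config <- function(base_bin_s = 200e-9, m = 16, octaves = 20,
                              normalization = "symmetric", window_s = NULL) {
  .assert(base_bin_s >= 1e-12, "base bin must be >= 1 ps")
  .assert(m >= 2 && m %% 2 == 0, "m must be even and >= 2")
  .assert(octaves >= 1, "octaves must be >= 1")
  normalization <- match.arg(normalization, "symmetric")
  structure(list(base_bin_s = base_bin_s, m = m, octaves = octaves,
                 normalization = normalization, window_s = window_s),
            class = "correlator_config")
}

max_lag_s <- function(cfg) cfg$m * cfg$base_bin_s * 2^(cfg$octaves - 1)

new_corr_curve <- function(lag_s, g2, count_rate_hz, window_start_s,
                           window_s, channels) {
  structure(list(lag_s = lag_s, g2 = g2, count_rate_hz = count_rate_hz,
                 window_start_s = window_start_s, window_s = window_s,
                 channels = channels),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("corr_curve: %d lags (%.3g s - %.3g s), %.3g kHz, channels %s\n",
              length(x$lag_s), min(x$lag_s), max(x$lag_s),
              x$count_rate_hz / 1e3, paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Intensity autocorrelation of a photon tag stream (multi-tau)
#'
#' Estimates `g2(tau) = <n(t) n(t+tau)> / (<n(t)> <n(t+tau)>)` on a
#' quasi-logarithmic lag grid by multi-tau binning with symmetric
#' normalization. Binning is by integer division of picosecond timestamps;
#' only complete bins inside the window enter the estimate.
#'
#' @param s a [tag_stream()]
#' @param cfg a [correlator_config()]
#' @param t_start_s,t_end_s analysis window (defaults to the full stream)
#' @return a `corr_curve` with fields `lag_s`, `g2`, `count_rate_hz`
#' @export
multitau_g2 <- function(s, cfg = correlator_config(), t_start_s = 0,
                        t_end_s = s$duration_s) {
  .assert(inherits(s, "tag_stream"), "s must be a tag_stream")
  .assert(length(s$times_ps) > 0, "empty stream")
  .assert(t_end_s > t_start_s, "empty window")
  .assert(t_end_s <= s$duration_s + 1e-12, "window longer than the data")
  res <- .multitau_cpp(s$times_ps, t_start_s * 1e12, t_end_s * 1e12,
                       cfg$base_bin_s * 1e12, cfg$m, cfg$octaves)
  new_corr_curve(res$lag_ps * 1e-12, res$g2,
                 count_rate_hz = res$n_photons / (t_end_s - t_start_s),
                 window_start_s = t_start_s,
                 window_s = t_end_s - t_start_s,
                 channels = s$channel)
}

#' Sequence of autocorrelations over contiguous windows
#'
#' Tiles the stream with non-overlapping windows of `cfg$window_s` seconds
#' (half-open: a photon belongs to the window containing its timestamp) and
#' estimates one curve per window, e.g. 30 ms windows for 33 Hz sampling of
#' pulsatile flow.
#'
#' @param s a [tag_stream()]
#' @param cfg a [correlator_config()] with `window_s` set; the window must
#'   be at least 10x the largest requested lag
#' @return list of `corr_curve`
#' @export
windowed_g2 <- function(s, cfg) {
  .assert(inherits(cfg, "correlator_config") && !is.null(cfg$window_s),
          "cfg$window_s must be set")
  .assert(cfg$window_s <= s$duration_s + 1e-12,
          "window longer than the data")
  .assert(cfg$window_s >= 10 * max_lag_s(cfg),
          sprintf("incompatible window/lag configuration: window %.3g s < 10 x max lag %.3g s",
                  cfg$window_s, max_lag_s(cfg)))
  nw <- floor(s$duration_s / cfg$window_s + 1e-9)
  lapply(seq_len(nw) - 1, function(k)
    multitau_g2(s, cfg, t_start_s = k * cfg$window_s,
                t_end_s = (k + 1) * cfg$window_s))
}

#' Average correlation curves across detectors or repetitions
#'
#' Count-rate-weighted mean of `g2 - 1`, re-offset to g2. All curves must
#' share the lag grid; the result records the contributing channels.
#'
#' @param curves list of `corr_curve` on one lag grid
#' @return a `corr_curve`
#' @export
average_curves <- function(curves) {
  .assert(length(curves) >= 1, "need at least one curve")
  lag <- curves[[1]]$lag_s
  for (cv in curves)
    .assert(length(cv$lag_s) == length(lag) &&
              max(abs(cv$lag_s - lag)) < 1e-15, "mismatched lag grids")
  w <- vapply(curves, function(cv) cv$count_rate_hz, numeric(1))
  if (all(w == 0)) w <- rep(1, length(curves))
  g2m <- Reduce(`+`, Map(function(cv, wi) wi * (cv$g2 - 1), curves, w)) /
    sum(w)
  new_corr_curve(lag, 1 + g2m,
                 count_rate_hz = mean(w),
                 window_start_s = curves[[1]]$window_start_s,
                 window_s = curves[[1]]$window_s,
                 channels = unlist(lapply(curves, function(cv) cv$channels)))
}

#' Running median filter over a sequence of correlation curves
#'
#' Pointwise-in-lag moving median over `k` consecutive curves (the standard
#' pre-fit conditioning for fast DCS acquisitions); edges use shrinking
#' windows so the output sequence has the input length.
#'
#' @param curves list of `corr_curve` on one grid
#' @param k window length (odd, default 5)
#' @return list of filtered `corr_curve`
#' @export
median_filter_curves <- function(curves, k = 5) {
  .assert(k %% 2 == 1, "k must be odd")
  n <- length(curves)
  if (k == 1 || n == 1) return(curves)
  G <- vapply(curves, function(cv) cv$g2, numeric(length(curves[[1]]$g2)))
  h <- (k - 1) / 2
  lapply(seq_len(n), function(i) {
    j <- max(1, i - h):min(n, i + h)
    out <- curves[[i]]
    out$g2 <- apply(G[, j, drop = FALSE], 1, median)
    out
  })
}

#' Root-sum-of-variances noise statistic of repeated curves
#'
#' `sqrt(sum over lags of Var(g2(tau)))` with the sample (n-1) variance
#' across repetitions -- a raw-signal noise figure that decreases with count
#' rate.
#'
#' @param curves list of at least two `corr_curve` on one grid
#' @return scalar
#' @export
g2_variance_stat <- function(curves) {
  .assert(length(curves) >= 2, "need at least two curves")
  G <- vapply(curves, function(cv) cv$g2, numeric(length(curves[[1]]$g2)))
  sqrt(sum(apply(G, 1, var)))
}
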