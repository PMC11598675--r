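# DTOF / IRF containers, CSV I/O and BIP descriptor operations.

#' Distribution of times of flight (TCSPC histogram)
#'
#' @param counts non-negative integer counts per time channel
#' @param dt_ps channel width in ps (default 9.77, the TCSPC board value)
#' @param t0_ps time of the first channel center, ps
#' @param T_rep_ps laser repetition period, ps (default 12.5 ns, 80 MHz class)
#' @param acq_time_s acquisition time, s
#' @param wavelength_nm laser wavelength, nm
#' @param rho_cm source-detector distance, cm
#' @return object of class `dtof`
#' @export
dtof <- function(counts, dt_ps = 9.77, t0_ps = 0, T_rep_ps = 12500,
                 acq_time_s = NA_real_, wavelength_nm = NA_real_,
                 rho_cm = NA_real_) {
  .assert(all(counts >= 0), "counts must be >= 0")
  .assert(dt_ps > 0, "dt must be > 0")
  .assert(length(counts) * dt_ps <= T_rep_ps + 1e-9,
          "histogram span exceeds the laser period")
  structure(list(counts = as.numeric(counts), dt_ps = dt_ps, t0_ps = t0_ps,
                 T_rep_ps = T_rep_ps, acq_time_s = acq_time_s,
                 wavelength_nm = wavelength_nm, rho_cm = rho_cm),
            class = "dtof")
}

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("dtof: %d channels x %.2f ps, %.3g counts, lambda = %s nm, rho = %s cm\n",
              length(x$counts), x$dt_ps, sum(x$counts),
              format(x$wavelength_nm), format(x$rho_cm)))
  invisible(x)
}

# channel center times, ps
dtof_times <- function(h) h$t0_ps + (seq_along(h$counts) - 1) * h$dt_ps

#' Read / write a DTOF (or IRF histogram) as annotated CSV
#'
#' Format: '#'-prefixed `key=value` metadata lines (dt_ps, t0_ps, T_rep_ps,
#' wavelength_nm, rho_cm, acq_time_s) followed by a single `counts` column.
#' The round trip is lossless.
#'
#' @param h a [dtof()]
#' @param path file path
#' @return `read_dtof` returns a [dtof()]; `write_dtof` returns `path`
#'   invisibly
#' @export
write_dtof <- function(h, path) {
  .assert(inherits(h, "dtof"), "h must be a dtof")
  meta <- c(dt_ps = h$dt_ps, t0_ps = h$t0_ps, T_rep_ps = h$T_rep_ps,
            wavelength_nm = h$wavelength_nm, rho_cm = h$rho_cm,
            acq_time_s = h$acq_time_s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta),
                     vapply(meta, function(v) format(v, digits = 17),
                            character(1))), con)
  writeLines("counts", con)
  writeLines(format(h$counts, digits = 17, scientific = FALSE, trim = TRUE),
             con)
  invisible(path)
}

#' @rdname write_dtof
#' @export
read_dtof <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- suppressWarnings(as.numeric(sub("^[^=]*=", "", kv)))
  meta <- setNames(vals, keys)
  body <- lines[!grepl("^#", lines)]
  .assert(body[1] == "counts", "malformed DTOF CSV: missing counts header")
  counts <- as.numeric(body[-1])
  dtof(counts, dt_ps = meta[["dt_ps"]], t0_ps = meta[["t0_ps"]],
       T_rep_ps = meta[["T_rep_ps"]], acq_time_s = meta[["acq_time_s"]],
       wavelength_nm = meta[["wavelength_nm"]], rho_cm = meta[["rho_cm"]])
}

#' Instrument response function record
#'
#' Bundles an IRF histogram with its shape descriptors (computed on
#' construction via [irf_descriptors()] unless supplied).
#'
#' @param histogram a [dtof()] holding the IRF
#' @param descriptors optional list (background, com_ps, fwhm_ps)
#' @return object of class `irf_record`
#' @export
irf_record <- function(histogram, descriptors = NULL) {
  .assert(inherits(histogram, "dtof"), "histogram must be a dtof")
  if (is.null(descriptors)) descriptors <- irf_descriptors(histogram)
  structure(list(histogram = histogram, descriptors = descriptors),
            class = "irf_record")
}

#' IRF shape descriptors
#'
#' Background level (mean counts/channel over a pre-peak window), center of
#' mass of the background-subtracted histogram, and FWHM by linear
#' interpolation between the channels crossing half maximum.
#'
#' @param h a [dtof()] with a single dominant peak above background
#' @param bg_frac fraction of the channels before the rising edge used for
#'   the background estimate (default 0.1 of the full axis, clipped to the
#'   pre-rise region)
#' @return list with `background` (counts/channel), `com_ps`, `fwhm_ps`
#' @export
irf_descriptors <- function(h, bg_frac = 0.1) {
  .assert(inherits(h, "dtof"), "h must be a dtof")
  y <- h$counts
  n <- length(y)
  pk <- which.max(y)
  rise <- which(y >= 0.5 * y[pk])[1]
  nbg <- min(max(1L, floor(bg_frac * n)), max(1L, rise - 1L))
  bg <- mean(y[seq_len(nbg)])
  ys <- pmax(y - bg, 0)
  if (max(ys) <= 0) stop("no peak above background", call. = FALSE)
  t <- dtof_times(h)
  # support: contiguous region around the peak above 0.1% of peak
  thr <- 1e-3 * max(ys)
  lo <- pk; while (lo > 1 && ys[lo - 1] > thr) lo <- lo - 1
  hi <- pk; while (hi < n && ys[hi + 1] > thr) hi <- hi + 1
  sup <- lo:hi
  com <- sum(t[sup] * ys[sup]) / sum(ys[sup])
  half <- 0.5 * max(ys)
  iL <- which(ys[1:pk] >= half)[1]
  tL <- if (iL == 1) t[1] else
    t[iL - 1] + (half - ys[iL - 1]) / (ys[iL] - ys[iL - 1]) * h$dt_ps
  iRrel <- which(ys[pk:n] < half)[1]
  if (is.na(iRrel)) stop("falling edge never crosses half maximum",
                         call. = FALSE)
  iR <- pk + iRrel - 1L
  tR <- t[iR - 1] + (half - ys[iR - 1]) / (ys[iR] - ys[iR - 1]) * h$dt_ps
  list(background = bg, com_ps = com, fwhm_ps = tR - tL)
}

#' Responsivity of the detection system
#'
#' `s(lambda) = N_tot / (t_meas * L)` where the input radiance `L` is
#' obtained from the power on a calibrated transmitting phantom,
#' `L = P_in * kappa`, and expressed in photons/(s m^2 sr) by dividing the
#' radiant flux by the photon energy `h c / lambda`.
#'
#' @param N_tot detected photon counts
#' @param t_meas_s measurement duration, s
#' @param P_in_W input power, W
#' @param kappa diffuse transmittance factor of the calibrated phantom,
#'   1/(m^2 sr)
#' @param wavelength_nm wavelength, nm (converts power to photon rate)
#' @return responsivity in m^2 sr
#' @export
responsivity <- function(N_tot, t_meas_s, P_in_W, kappa, wavelength_nm) {
  .assert(all(c(N_tot, t_meas_s, P_in_W, kappa, wavelength_nm) > 0),
          "all inputs must be > 0")
  h_planck <- 6.62607015e-34; c_ms <- 2.99792458e8
  photon_rate <- P_in_W * (wavelength_nm * 1e-9) / (h_planck * c_ms)  # 1/s
  L_photons <- photon_rate * kappa                   # photons / (s m^2 sr)
  N_tot / (t_meas_s * L_photons)
}

#' Afterpulsing ratio of an IRF
#'
#' `R_AP = (N_bkg - N_dark) * T / (N_tot * dt)` where `N_bkg` is the IRF
#' background per channel, `N_dark` the dark-measurement background per
#' channel, `T` the laser period and `N_tot` the total IRF counts after
#' background subtraction.
#'
#' @param irf an [irf_record()]
#' @param dark a [dtof()] acquired with the laser off (same dt)
#' @return dimensionless ratio (multiply by 100 for %)
#' @export
afterpulsing_ratio <- function(irf, dark) {
  .assert(inherits(irf, "irf_record"), "irf must be an irf_record")
  .assert(inherits(dark, "dtof"), "dark must be a dtof")
  h <- irf$histogram
  .assert(abs(h$dt_ps - dark$dt_ps) < 1e-9, "irf and dark must share dt")
  N_bkg <- irf$descriptors$background
  N_dark <- mean(dark$counts)
  N_tot <- sum(pmax(h$counts - N_bkg, 0))
  if (N_tot <= 0) stop("N_tot = 0 after background subtraction", call. = FALSE)
  (N_bkg - N_dark) * h$T_rep_ps / (N_tot * h$dt_ps)
}

#' Differential nonlinearity of the timing electronics
#'
#' Normalizes a constant-illumination histogram to its mean across channels;
#' an ideal board gives DNL identically 1. The summary metric is the maximum
#' absolute deviation from 1 (peak deviation).
#'
#' @param cw_hist a [dtof()] measured under constant (CW) illumination
#' @return list with `dnl` (per-channel, mean exactly 1) and `peak`
#'   (max |dnl - 1|)
#' @export
dnl_curve <- function(cw_hist) {
  .assert(inherits(cw_hist, "dtof"), "cw_hist must be a dtof")
  y <- cw_hist$counts
  .assert(length(y) > 0 && sum(y) > 0, "empty histogram")
  dnl <- y / mean(y)
  list(dnl = dnl, peak = max(abs(dnl - 1)))
}

#' Time-gate specification
#'
#' Half-open intervals `[start, stop)` in ps on the DTOF time axis.
#' `gate_spec_regular` builds a contiguous partition of equal-width gates
#' (e.g. the 500 ps gates of the depth-sensitivity analysis).
#'
#' @param start,stop vectors of gate edges, ps
#' @return object of class `gate_spec` (data.frame start/stop)
#' @export
gate_spec <- function(start, stop) {
  .assert(length(start) == length(stop), "start/stop length mismatch")
  .assert(all(start < stop), "need start < stop")
  structure(data.frame(start = start, stop = stop), class = c("gate_spec",
                                                              "data.frame"))
}

#' @rdname gate_spec
#' @param from,to axis range to partition, ps
#' @param width_ps gate width, ps (default 500)
#' @export
gate_spec_regular <- function(from, to, width_ps = 500) {
  edges <- seq(from, to, by = width_ps)
  if (tail(edges, 1) < to) edges <- c(edges, tail(edges, 1) + width_ps)
  gate_spec(head(edges, -1), tail(edges, -1))
}

#' Counts per time gate
#'
#' Sums DTOF counts in each gate. Gate boundaries snap to the nearest channel
#' edge and intervals are half-open, so a gate set that partitions the axis
#' conserves the total counts exactly.
#'
#' @param h a [dtof()]
#' @param gates a [gate_spec()]
#' @return numeric vector N_k, one per gate
#' @export
gate_counts <- function(h, gates) {
  .assert(inherits(h, "dtof"), "h must be a dtof")
  .assert(inherits(gates, "gate_spec"), "gates must be a gate_spec")
  n <- length(h$counts)
  # channel i covers [t0 + (i-1)*dt, t0 + i*dt)
  lo_edge <- h$t0_ps
  hi_edge <- h$t0_ps + n * h$dt_ps
  vapply(seq_len(nrow(gates)), function(k) {
    a <- gates$start[k]; b <- gates$stop[k]
    if (a < lo_edge - h$dt_ps / 2 || b > hi_edge + h$dt_ps / 2)
      stop(sprintf("gate [%g, %g) outside histogram support [%g, %g)",
                   a, b, lo_edge, hi_edge), call. = FALSE)
    i0 <- round((a - lo_edge) / h$dt_ps) + 1   # snap to nearest channel edge
    i1 <- round((b - lo_edge) / h$dt_ps)       # exclusive edge
    i0 <- max(1, i0); i1 <- min(n, i1)
    if (i1 < i0) 0 else sum(h$counts[i0:i1])
  }, numeric(1))
}
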