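# End-to-end analysis pipelines, Welch PSD and configuration.

#' Centered moving-average filter
#'
#' k-sample moving average with shrinking windows at the edges (used as the
#' final visualization filter on hemodynamic traces).
#'
#' @param y numeric vector
#' @param k window length (odd)
#' @return filtered vector, same length
#' @export
moving_average <- function(y, k = 5) {
  .assert(k %% 2 == 1, "k must be odd")
  n <- length(y); h <- (k - 1) / 2
  vapply(seq_len(n), function(i) mean(y[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

#' Run the stepped-occlusion analysis pipeline
#'
#' The processing chain, in order: per sample and wavelength, a
#' semi-infinite homogeneous fit of the DTOF ([fit_dtof()]); Beer's-law
#' inversion of the absorption pair for HbO2/HHb/tHb/StO2; per sample, the
#' DCS curves of all channels at a distance are averaged, a 5-sample moving
#' median filter is applied to the curve sequence, each curve is fitted
#' ([fit_g2()]) for the BFI; finally a 5-sample moving average filter is
#' applied to all output traces. Non-converged fits propagate as quality
#' flags, not interpolated values.
#'
#' @param ds an `occlusion_dataset` (from [simulate_occlusion_dataset()] or
#'   assembled from files)
#' @param corr_cfg correlator configuration for the per-sample curves
#' @param nirs_opts,dcs_opts option lists passed to the fitters
#' @param median_k,avg_k filter lengths (defaults 5 and 5)
#' @return list of `hemodynamic_trace` data.frames, one per distance:
#'   columns `t_s, HbO2, HHb, tHb, StO2, BFI, mua_<wl>..., ok`
#' @export
run_occlusion_pipeline <- function(ds,
                                   corr_cfg = correlator_config(
                                     base_bin_s = 1e-6, m = 16, octaves = 9),
                                   nirs_opts = list(), dcs_opts = list(),
                                   median_k = 5, avg_k = 5) {
  .assert(inherits(ds, "occlusion_dataset"), "ds must be an occlusion_dataset")
  .assert(!is.null(ds$irf), "missing IRF calibration")
  ns <- nrow(ds$truth)
  basis2 <- chromophore_basis(ds$wavelengths_nm)
  lapply(seq_along(ds$rhos), function(ri) {
    rho <- ds$rhos[ri]
    # --- TD NIRS chain ---
    mua_fit <- sapply(seq_along(ds$wavelengths_nm), function(wi) {
      vapply(seq_len(ns), function(i) {
        f <- fit_dtof(ds$dtof[[ri]][[wi]][[i]], ds$irf[[wi]], rho = rho,
                      n = ds$n, opts = nirs_opts)
        if (f$converged) f$mua else NA_real_
      }, numeric(1))
    })
    hemo <- t(apply(mua_fit, 1, function(mm) {
      if (anyNA(mm)) return(c(NA, NA, NA, NA))
      b <- beer_invert(mm - ds$mua_offset, basis2)
      c(b$HbO2, b$HHb, b$tHb, b$StO2)
    }))
    colnames(hemo) <- c("HbO2", "HHb", "tHb", "StO2")
    # --- DCS chain: average channels -> median filter -> fit ---
    curves <- lapply(seq_len(ns), function(i) {
      ch_curves <- lapply(ds$tags[[ri]], function(chl)
        multitau_g2(chl[[i]], corr_cfg))
      average_curves(ch_curves)
    })
    curves <- median_filter_curves(curves, k = median_k)
    pr785 <- optical_props(0.1, ds$musp_dcs, n = ds$n, wavelength = 785)
    bfi <- vapply(seq_len(ns), function(i) {
      pr <- optical_props(ds$truth[i, "mua_785"], ds$musp_dcs, n = ds$n,
                          wavelength = 785)
      f <- fit_g2(curves[[i]], rho, pr, opts = dcs_opts)
      if (f$converged) f$DB else NA_real_
    }, numeric(1))
    ok <- stats::complete.cases(hemo) & is.finite(bfi)
    out <- data.frame(t_s = ds$truth$t_s, hemo, BFI = bfi,
                      mua = mua_fit, ok = ok)
    names(out)[grep("^mua", names(out))] <-
      paste0("mua_", ds$wavelengths_nm)
    for (cn in c("HbO2", "HHb", "tHb", "StO2", "BFI"))
      out[[cn]][ok] <- moving_average_na(out[[cn]], avg_k)[ok]
    class(out) <- c("hemodynamic_trace", "data.frame")
    attr(out, "rho_cm") <- rho
    attr(out, "fs_hz") <- ds$spec$fs_hz
    out
  })
}

# moving average ignoring NA gaps (flagged samples stay flagged)
moving_average_na <- function(y, k) {
  n <- length(y); h <- (k - 1) / 2
  vapply(seq_len(n), function(i) {
    w <- y[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Run the pulsatility analysis pipeline
#'
#' Windowed correlation (default 30 ms windows, 33 Hz sampling), 5-sample
#' median filter of the curve sequence, per-window g2 fit for the BFI, and
#' the Welch power spectral density of the BFI trace.
#'
#' @param streams list of [tag_stream()] (channels are averaged)
#' @param rho source-detector distance, cm
#' @param props an [optical_props()] at the DCS wavelength
#' @param window_s analysis window, s (default 0.03)
#' @param corr_cfg correlator configuration for the windows
#' @param psd_window_s,psd_overlap Welch parameters (defaults 20 s, 50%)
#' @param median_k median filter length
#' @return list: `trace` (data.frame t_s, BFI, beta), `psd` (a
#'   `psd_result`), `fs_hz`
#' @export
run_pulsatility_pipeline <- function(streams, rho, props, window_s = 0.03,
                                     corr_cfg = correlator_config(
                                       base_bin_s = 5e-7, m = 16,
                                       octaves = 7, window_s = NULL),
                                     psd_window_s = 20, psd_overlap = 0.5,
                                     median_k = 5) {
  if (inherits(streams, "tag_stream")) streams <- list(streams)
  corr_cfg$window_s <- window_s
  wseq <- lapply(streams, function(s) windowed_g2(s, corr_cfg))
  nw <- min(lengths(wseq))
  curves <- lapply(seq_len(nw), function(i)
    average_curves(lapply(wseq, `[[`, i)))
  curves <- median_filter_curves(curves, k = median_k)
  fits <- lapply(curves, fit_g2, rho = rho, props = props)
  bfi <- vapply(fits, `[[`, numeric(1), "DB")
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  fs <- 1 / window_s
  tr <- data.frame(t_s = (seq_len(nw) - 0.5) * window_s, BFI = bfi,
                   beta = beta)
  psd <- welch_psd(bfi, fs, window_s = psd_window_s, overlap = psd_overlap)
  list(trace = tr, psd = psd, fs_hz = fs)
}

#' Welch power spectral density
#'
#' Mean modified periodogram over Hamming-windowed segments (default 20 s)
#' with 50% overlap; one-sided density normalized so that the integral over
#' frequency approximates the signal variance (each segment has its mean
#' removed).
#'
#' @param x signal
#' @param fs sampling rate, Hz
#' @param window_s segment length, s
#' @param overlap fractional overlap in `[0, 1)`
#' @return object of class `psd_result`: `freq_hz`, `power` (units^2/Hz),
#'   `window_s`, `overlap`, `n_segments`
#' @export
welch_psd <- function(x, fs, window_s = 20, overlap = 0.5) {
  L <- round(window_s * fs)
  .assert(length(x) >= 2 * L * (1 - overlap) + L * overlap,
          "signal shorter than two Welch segments")
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  .assert(length(starts) >= 2, "signal shorter than two Welch segments")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming
  U <- sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nf]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  structure(list(freq_hz = (0:(nf - 1)) * fs / L, power = p * dbl,
                 window_s = window_s, overlap = overlap,
                 n_segments = length(starts)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  pk <- which.max(x$power[-1]) + 1
  cat(sprintf("psd_result: %d bins to %.3g Hz, %d segments, peak at %.3g Hz\n",
              length(x$freq_hz), max(x$freq_hz), x$n_segments,
              x$freq_hz[pk]))
  invisible(x)
}

#' Default pipeline configuration
#'
#' All tunable defaults of the package in one nested list, suitable for
#' serialization to YAML and for the command-line interface.
#'
#' @param path optional YAML file whose entries override the defaults
#' @return nested configuration list
#' @export
nirsdcs_config <- function(path = NULL) {
  cfg <- list(
    geometry = list(rho_short_cm = 1.5, rho_long_cm = 2.5),
    nirs = list(wavelengths_nm = c(685, 830), dt_ps = 9.77,
                T_rep_ps = 12500, n = 1.4,
                fit = default_nirs_fit_opts()),
    dcs = list(wavelength_nm = 785, beta = 0.5, n = 1.4,
               correlator = list(base_bin_s = 200e-9, m = 16, octaves = 20),
               median_filter_k = 5),
    protocols = list(gate_width_ps = 500, cv_threshold_nirs = 0.03,
                     cv_threshold_dcs = 0.05, stability_band_percent = 1),
    pipeline = list(fs_occlusion_hz = 5, fs_pulsatile_hz = 100 / 3,
                    moving_average_k = 5,
                    welch = list(window_s = 20, overlap = 0.5)))
  if (!is.null(path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg
}
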