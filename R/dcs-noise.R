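# End-to-end DCS noise characterization on synthetic speckle streams.

#' Simulated DCS noise study: CV of fitted DB vs count rate
#'
#' For every analysis window, independent speckle fields are synthesized for
#' each detection channel and thinned at all requested count rates (sharing
#' the field realization across rates, which leaves each rate's photon
#' statistics exact while keeping the cost bounded by the largest rate).
#' Per window and rate the channel curves are averaged and fitted; the CV of
#' the fitted diffusion coefficient across windows is summarized by
#' [dcs_noise_scan()], including the interpolated rate at the 5% CV
#' threshold.
#'
#' @param rates_khz count rates per channel to probe, kHz
#' @param n_windows analysis windows per rate (default 100)
#' @param window_s window length, s (default 1)
#' @param n_channels averaged detection channels (default 4)
#' @param props medium [optical_props()] at the DCS wavelength
#' @param DB true Brownian diffusion coefficient, cm^2/s
#' @param beta coherence factor (realized as 1/round(1/beta))
#' @param rho source-detector distance, cm
#' @param wavelength_nm DCS wavelength
#' @param cfg correlator configuration (default: 200 ns base, m = 16,
#'   10 octaves, lags to ~1.6 ms)
#' @param cv_threshold threshold for the crossing-rate interpolation
#' @param seed optional seed
#' @return the [dcs_noise_scan()] report, plus `db_values` (per-rate fitted
#'   DB vectors) and `DB_true`
#' @export
run_dcs_noise_study <- function(rates_khz = c(10, 20, 40, 80),
                                n_windows = 100, window_s = 1,
                                n_channels = 4,
                                props = optical_props(0.05, 7, n = 1.33,
                                                      wavelength = 785),
                                DB = 1e-8, beta = 0.5, rho = 2.5,
                                wavelength_nm = 785,
                                cfg = correlator_config(base_bin_s = 2e-7,
                                                        m = 16,
                                                        octaves = 10),
                                cv_threshold = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dyn <- dynamics_params(DB, beta = beta, n = props$n,
                         wavelength_nm = wavelength_nm)
  g1f <- function(tau) g1_semi_infinite(tau, rho, props, dyn)
  mix <- g1_expmix(g1f, tau_max_s = 2 * max_lag_s(cfg))
  M <- max(1L, as.integer(round(1 / beta)))
  rates_hz <- rates_khz * 1e3
  nr <- length(rates_hz)
  db <- matrix(NA_real_, n_windows, nr)
  for (wi in seq_len(n_windows)) {
    curves <- vector("list", nr)
    for (ch in seq_len(n_channels)) {
      tt <- .speckle_multi_rate(mix, rates_hz, window_s, M)
      for (ri in seq_len(nr)) {
        s <- tag_stream(.make_strict(tt[[ri]]), channel = ch,
                        duration_s = window_s)
        cv <- multitau_g2(s, cfg)
        curves[[ri]] <- c(curves[[ri]], list(cv))
      }
    }
    for (ri in seq_len(nr)) {
      f <- fit_g2(average_curves(curves[[ri]]), rho, props,
                  wavelength_nm = wavelength_nm)
      if (f$converged) db[wi, ri] <- f$DB
    }
  }
  vals <- lapply(seq_len(nr), function(ri) db[is.finite(db[, ri]), ri])
  scan <- dcs_noise_scan(vals, rates_khz, factor_name = "count_rate_khz",
                         cv_threshold = cv_threshold,
                         min_windows = min(50, n_windows))
  scan$db_values <- vals
  scan$DB_true <- DB
  scan$beta_eff <- 1 / M
  scan
}
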