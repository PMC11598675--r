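# Synthetic in-vivo-like measurements: stepped vascular occlusion and
# pulsatile blood flow.

#' Stepped-occlusion protocol specification
#'
#' Default phase durations follow the standard cuff protocol (2 min
#' baseline, 1 min light, 1 min venous, 1 min arterial occlusion, 5 min
#' recovery) at 5 Hz sampling. Hemodynamic targets encode the expected
#' phenomenology: during venous occlusion HbO2 and HHb rise in proportion
#' (tissue saturation constant) and flow falls slightly; during arterial
#' occlusion HbO2 falls while HHb keeps rising with total hemoglobin
#' constant and flow abruptly drops; release produces hyperemic overshoots.
#' Trajectories are piecewise-linear ramps smoothed with a 5 s one-pole
#' filter; hyperemia is a gamma-shaped pulse.
#'
#' @param durations_s named phase durations, s
#' @param fs_hz sampling rate, Hz
#' @param baseline list: `HbO2`, `HHb` (uM), `DB` (cm^2/s)
#' @param venous list: `dHbO2`, `dHHb` (uM ramp over the phase),
#'   `db_factor`
#' @param arterial list: `dHbO2`, `dHHb`, `db_factor`
#' @param hyperemia list: `amp_HbO2` (uM), `amp_HHb` (uM, undershoot when
#'   negative), `amp_DB` (fractional overshoot), `t_peak_s`, `shape_k`
#' @param recovery_tau_s time constants of the return to baseline after
#'   cuff release: `hemo` (hemoglobin pools, slow) and `DB` (flow rebound,
#'   fast -- reactive hyperemia restores flow within seconds)
#' @param smooth_tau_s one-pole smoothing time constant, s
#' @param cardiac list: `rate_hz`, `rel_amp` (on DB), `harmonics`
#' @return object of class `occlusion_spec`
#' @export
occlusion_spec <- function(durations_s = c(baseline = 120, light = 60,
                                           venous = 60, arterial = 60,
                                           recovery = 300),
                           fs_hz = 5,
                           baseline = list(HbO2 = 35, HHb = 15, DB = 1.5e-8),
                           venous = list(dHbO2 = 7, dHHb = 3,
                                         db_factor = 0.85),
                           arterial = list(dHbO2 = -8, dHHb = 8,
                                           db_factor = 0.2),
                           hyperemia = list(amp_HbO2 = 6, amp_HHb = -3,
                                            amp_DB = 1.0, t_peak_s = 15,
                                            shape_k = 2),
                           recovery_tau_s = list(hemo = 15, DB = 3),
                           smooth_tau_s = 5,
                           cardiac = list(rate_hz = 1.1, rel_amp = 0,
                                          harmonics = 0)) {
  .assert(all(durations_s > 0), "phase durations must be > 0")
  .assert(fs_hz > 0, "fs must be > 0")
  .assert(all(unlist(baseline) >= 0), "baseline values must be >= 0")
  structure(list(durations_s = durations_s, fs_hz = fs_hz,
                 baseline = baseline, venous = venous, arterial = arterial,
                 hyperemia = hyperemia, recovery_tau_s = recovery_tau_s,
                 smooth_tau_s = smooth_tau_s, cardiac = cardiac),
            class = "occlusion_spec")
}

# one-pole exponential smoothing, time constant tau (s)
.smooth1p <- function(y, fs, tau_s) {
  if (tau_s <= 0) return(y)
  a <- 1 / (1 + tau_s * fs)
  out <- y
  for (i in 2:length(y)) out[i] <- out[i - 1] + a * (y[i] - out[i - 1])
  out
}

#' Ground-truth hemodynamic trajectories of an occlusion protocol
#'
#' @param spec an [occlusion_spec()]
#' @return data.frame: `t_s`, `phase`, `HbO2`, `HHb`, `tHb`, `StO2`, `DB`
#' @export
occlusion_truth <- function(spec) {
  d <- spec$durations_s
  fs <- spec$fs_hz
  edges <- cumsum(c(0, d))
  total <- edges[length(edges)]
  t <- seq(1 / fs / 2, total - 1e-9, by = 1 / fs)  # window-center stamps
  phase <- cut(t, edges, labels = names(d), right = FALSE)
  b <- spec$baseline
  ramp_in <- function(ph) {  # 0 -> 1 across the named phase
    out <- numeric(length(t))
    if (!ph %in% names(d)) return(out)   # phase absent from this protocol
    i0 <- which(names(d) == ph)
    out[t >= edges[i0 + 1]] <- 1
    in_ph <- phase == ph
    out[in_ph] <- (t[in_ph] - edges[i0]) / d[[ph]]
    out
  }
  rv <- ramp_in("venous"); ra <- ramp_in("arterial")
  HbO2 <- b$HbO2 + spec$venous$dHbO2 * rv + spec$arterial$dHbO2 * ra
  HHb <- b$HHb + spec$venous$dHHb * rv + spec$arterial$dHHb * ra
  logDB <- log(b$DB) + log(spec$venous$db_factor) * rv +
    log(spec$arterial$db_factor) * ra
  DB <- exp(logDB)
  # recovery: decay back to baseline plus hyperemic pulse
  i_rec <- which(phase == "recovery")
  if (length(i_rec) > 0) {
    x <- t[i_rec] - edges[which(names(d) == "recovery")]
    dec_h <- exp(-x / max(spec$recovery_tau_s$hemo, 1e-9))
    dec_d <- exp(-x / max(spec$recovery_tau_s$DB, 1e-9))
    HbO2[i_rec] <- b$HbO2 + (HbO2[i_rec[1]] - b$HbO2) * dec_h
    HHb[i_rec] <- b$HHb + (HHb[i_rec[1]] - b$HHb) * dec_h
    DB[i_rec] <- exp(log(b$DB) + (logDB[i_rec[1]] - log(b$DB)) * dec_d)
    hy <- spec$hyperemia
    g <- (x / hy$t_peak_s)^hy$shape_k *
      exp(hy$shape_k * (1 - x / hy$t_peak_s))
    HbO2[i_rec] <- HbO2[i_rec] + hy$amp_HbO2 * g
    HHb[i_rec] <- HHb[i_rec] + hy$amp_HHb * g
    DB[i_rec] <- DB[i_rec] * (1 + hy$amp_DB * g)
  }
  HbO2 <- .smooth1p(HbO2, fs, spec$smooth_tau_s)
  HHb <- .smooth1p(HHb, fs, spec$smooth_tau_s)
  DB <- exp(.smooth1p(log(DB), fs, spec$smooth_tau_s))
  if (spec$cardiac$rel_amp > 0 && spec$cardiac$harmonics >= 1) {
    mod <- rep(0, length(t))
    for (i in seq_len(spec$cardiac$harmonics))
      mod <- mod + spec$cardiac$rel_amp / i *
        cos(2 * pi * i * spec$cardiac$rate_hz * t)
    DB <- DB * (1 + mod)
  }
  data.frame(t_s = t, phase = phase, HbO2 = HbO2, HHb = HHb,
             tHb = HbO2 + HHb, StO2 = 100 * HbO2 / (HbO2 + HHb), DB = DB)
}

#' Simulate a synchronized occlusion dataset
#'
#' For every output sample: Poisson DTOFs at both wavelengths and
#' source-detector distances, whose absorption follows Beer's law applied
#' to the ground-truth chromophore trajectories, and DCS photon-tag
#' streams whose g1 follows the correlation-diffusion model at the
#' truth `DB(t)`. Ground truth is stored alongside the raw data.
#'
#' @param spec an [occlusion_spec()]
#' @param rhos source-detector distances, cm (default c(1.5, 2.5))
#' @param wavelengths_nm TD-NIRS wavelengths (default c(685, 830))
#' @param musp_nirs reduced scattering at the NIRS wavelengths, 1/cm
#' @param musp_dcs,mua_offset reduced scattering at 785 nm and a fixed
#'   background absorption added on top of the hemoglobin term, 1/cm
#' @param n refractive index
#' @param N_dtof expected DTOF counts per sample
#' @param dcs_rate_hz per-channel DCS count rate
#' @param dcs_channels number of DCS detectors per distance (default
#'   c(1, 3): one short, three long)
#' @param beta coherence factor of the DCS detection
#' @param irf_spec_nirs an [irf_spec()] used for all NIRS channels
#' @param seed optional seed (the whole dataset is seed-deterministic)
#' @return object of class `occlusion_dataset`: `truth`, `spec`, `irf`,
#'   `dtof` (list by rho then wavelength: list of per-sample [dtof()]),
#'   `tags` (list by rho: per-channel list of per-sample [tag_stream()]),
#'   `basis`, geometry metadata
#' @export
simulate_occlusion_dataset <- function(spec = occlusion_spec(),
                                       rhos = c(1.5, 2.5),
                                       wavelengths_nm = c(685, 830),
                                       musp_nirs = c(11, 9.5),
                                       musp_dcs = 10, mua_offset = 0.02,
                                       n = 1.4,
                                       N_dtof = 2e5, dcs_rate_hz = 3e4,
                                       dcs_channels = c(1, 3), beta = 0.5,
                                       irf_spec_nirs = irf_spec(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- occlusion_truth(spec)
  basis <- chromophore_basis(c(wavelengths_nm, 785))
  mua <- t(apply(truth[, c("HbO2", "HHb")], 1, function(cc)
    beer_forward(cc[1], cc[2], basis))) + mua_offset
  colnames(mua) <- c(paste0("mua_", wavelengths_nm), "mua_785")
  ns <- nrow(truth)
  win_s <- 1 / spec$fs_hz
  irf <- lapply(wavelengths_nm, function(wl)
    make_irf(irf_spec_nirs, N_tot = 2e6, wavelength_nm = wl))
  names(irf) <- as.character(wavelengths_nm)

  dtofs <- lapply(seq_along(rhos), function(ri)
    lapply(seq_along(wavelengths_nm), function(wi) {
      pr <- function(i) optical_props(mua[i, wi], musp_nirs[wi], n = n,
                                      wavelength = wavelengths_nm[wi])
      lapply(seq_len(ns), function(i)
        simulate_dtof(pr(i), rhos[ri], irf[[wi]], N_target = N_dtof,
                      acq_time_s = win_s))
    }))

  k0 <- 2 * pi * n / (785 * 1e-7)  # 785 nm in cm
  tags <- lapply(seq_along(rhos), function(ri) {
    lapply(seq_len(dcs_channels[ri]), function(ch) {
      lapply(seq_len(ns), function(i) {
        pr <- optical_props(mua[i, "mua_785"], musp_dcs, n = n,
                            wavelength = 785)
        dyn <- dynamics_params(truth$DB[i], beta = beta, k0 = k0)
        g1f <- function(tau) g1_semi_infinite(tau, rhos[ri], pr, dyn)
        mix <- g1_expmix(g1f, tau_max_s = 5e-3)
        tt <- .speckle_multi_rate(mix, dcs_rate_hz, win_s,
                                  M = round(1 / beta))[[1]]
        tag_stream(.make_strict(tt), channel = ch, duration_s = win_s)
      })
    })
  })
  structure(list(truth = cbind(truth, mua), spec = spec, rhos = rhos,
                 wavelengths_nm = wavelengths_nm, musp_nirs = musp_nirs,
                 musp_dcs = musp_dcs, mua_offset = mua_offset, n = n,
                 beta = beta, irf = irf, dtof = dtofs, tags = tags,
                 basis = basis),
            class = "occlusion_dataset")
}

#' Simulate pulsatile blood-flow tag streams
#'
#' `DB(t) = DB0 (1 + sum_i a_i cos(2 pi i HR t))`, generated as one tag
#' stream per detection channel with the field synthesized per output
#' window (default 30 ms, i.e. 33 Hz sampling).
#'
#' @param heart_rate_hz cardiac frequency
#' @param amplitude relative amplitude of the fundamental on DB
#' @param harmonics number of harmonics (amplitude falls as 1/i)
#' @param fs_hz output sampling rate (default 33.3); must exceed twice the
#'   highest harmonic frequency
#' @param duration_s measurement length
#' @param props an [optical_props()] at 785 nm
#' @param rho source-detector distance, cm
#' @param DB0 baseline diffusion coefficient, cm^2/s
#' @param rate_hz detected count rate per channel
#' @param beta coherence factor
#' @param n_channels detection channels
#' @param seed optional seed
#' @return list: `streams` (per channel [tag_stream()]), `truth`
#'   (data.frame t_s, DB), `window_s`
#' @export
simulate_pulsatile_bfi <- function(heart_rate_hz = 1.1, amplitude = 0.2,
                                   harmonics = 3, fs_hz = 100 / 3,
                                   duration_s = 60,
                                   props = optical_props(0.1, 10, n = 1.4,
                                                         wavelength = 785),
                                   rho = 1.5, DB0 = 1.5e-8, rate_hz = 1e5,
                                   beta = 0.5, n_channels = 1,
                                   seed = NULL) {
  .assert(fs_hz > 2 * harmonics * heart_rate_hz,
          "aliasing: fs must exceed twice the highest harmonic frequency")
  if (!is.null(seed)) set.seed(seed)
  win_s <- 1 / fs_hz
  nw <- floor(duration_s / win_s)
  tc <- (seq_len(nw) - 0.5) * win_s
  mod <- rep(0, nw)
  if (amplitude > 0)
    for (i in seq_len(max(harmonics, 1)))
      mod <- mod + amplitude / i * cos(2 * pi * i * heart_rate_hz * tc)
  DBt <- DB0 * pmax(1 + mod, 0.05)
  k0 <- 2 * pi * props$n / (785 * 1e-7)
  M <- round(1 / beta)
  streams <- lapply(seq_len(n_channels), function(ch) {
    times <- vector("list", nw)
    for (i in seq_len(nw)) {
      dyn <- dynamics_params(DBt[i], beta = beta, k0 = k0)
      g1f <- function(tau) g1_semi_infinite(tau, rho, props, dyn)
      mix <- g1_expmix(g1f, tau_max_s = 5e-3)
      tt <- .speckle_multi_rate(mix, rate_hz, win_s, M = M)[[1]]
      times[[i]] <- tt + (i - 1) * win_s * 1e12
    }
    tag_stream(.make_strict(unlist(times)), channel = ch,
               duration_s = nw * win_s)
  })
  list(streams = streams, truth = data.frame(t_s = tc, DB = DBt),
       window_s = win_s, beta_eff = 1 / M)
}
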