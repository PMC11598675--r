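# Independent reference implementations used as oracles. These are written
# directly from the closed forms, deliberately not sharing code with the
# package internals.

# time-domain semi-infinite reflectance, extrapolated boundary, single point
oracle_td_reflectance <- function(rho_cm, t_ps, mua, musp, n_idx) {
  cc <- 0.0299792458                     # cm/ps
  vv <- cc / n_idx
  DD <- 1 / (3 * musp)
  zz0 <- 1 / musp
  rdd <- -1.440 / n_idx^2 + 0.710 / n_idx + 0.668 + 0.0636 * n_idx
  AA <- (1 + rdd) / (1 - rdd)
  zzb <- 2 * AA * DD
  fourDvt <- 4 * DD * vv * t_ps
  pref <- 0.5 * (4 * pi * DD * vv)^(-3 / 2) * t_ps^(-5 / 2)
  pref * exp(-mua * vv * t_ps - rho_cm^2 / fourDvt) *
    (zz0 * exp(-zz0^2 / fourDvt) +
       (zz0 + 2 * zzb) * exp(-(zz0 + 2 * zzb)^2 / fourDvt))
}

# semi-infinite correlation-diffusion g1 at a single lag
oracle_g1_semi <- function(tau_s, rho_cm, mua, musp, n_idx, DB, lambda_nm) {
  kk0 <- 2 * pi * n_idx / (lambda_nm * 1e-7)
  DD <- 1 / (3 * musp)
  zz0 <- 1 / musp
  rdd <- -1.440 / n_idx^2 + 0.710 / n_idx + 0.668 + 0.0636 * n_idx
  AA <- (1 + rdd) / (1 - rdd)
  zzb <- 2 * AA * DD
  r1 <- sqrt(rho_cm^2 + zz0^2)
  r2 <- sqrt(rho_cm^2 + (zz0 + 2 * zzb)^2)
  gof <- function(tt) {
    mu_d <- mua + (1 / 3) * musp * kk0^2 * 6 * DB * tt
    kd <- sqrt(3 * musp * mu_d)
    (exp(-kd * r1) / r1 - exp(-kd * r2) / r2)
  }
  gof(tau_s) / gof(0)
}

# O(N^2)-style dense-binned correlator with the same estimator definition
# (complete bins, symmetric normalization); used on short slices only
oracle_g2_binned <- function(times_ps, t_start_ps, t_end_ps, bin_ps, lags) {
  tt <- times_ps[times_ps >= t_start_ps & times_ps < t_end_ps] - t_start_ps
  B <- floor((t_end_ps - t_start_ps) / bin_ps)
  b <- floor(tt / bin_ps)
  b <- b[b < B]
  n <- tabulate(b + 1, nbins = B)
  vapply(lags, function(j) {
    G <- sum(n[1:(B - j)] * n[(1 + j):B])
    ML <- sum(n[1:(B - j)])
    MR <- sum(n[(1 + j):B])
    if (ML == 0 || MR == 0) return(NA_real_)
    G * (B - j) / (ML * MR)
  }, numeric(1))
}

# shared small fixtures
fix_props_nirs <- optical_props(0.07, 10, n = 1.4, wavelength = 830)
fix_props_dcs <- optical_props(0.05, 7, n = 1.33, wavelength = 785)
fix_dyn <- dynamics_params(1e-8, beta = 0.5, n = 1.33, wavelength_nm = 785)

# one moderately large IRF shared across test files (deterministic)
fix_irf <- make_irf(irf_spec(fwhm_ps = 200), N_tot = 2e6, seed = 424242)

# homogeneous Poisson photon stream on [0, duration) in integer ps
poisson_stream <- function(rate_hz, duration_s, channel = 1L) {
  n <- rpois(1, rate_hz * duration_s)
  t <- sort(floor(runif(n) * duration_s * 1e12))
  t <- unique(t)
  tag_stream(t, channel = channel, duration_s = duration_s)
}
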