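# Welch PSD, pipelines, configuration, end-to-end determinism.

test_that("welch_psd: sinusoid peak, white-noise flatness, Parseval", {
  fs <- 100 / 3
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1.1 * t)
  p <- welch_psd(x, fs, window_s = 20, overlap = 0.5)
  pk <- p$freq_hz[which.max(p$power)]
  expect_equal(pk, p$freq_hz[which.min(abs(p$freq_hz - 1.1))])
  # Parseval: integrated density ~ variance (window bias < 5%)
  pow <- sum(p$power) * (p$freq_hz[2] - p$freq_hz[1])
  expect_equal(pow, var(x), tolerance = 0.05)
  set.seed(3)
  w <- rnorm(4000)
  pw <- welch_psd(w, fs, window_s = 20, overlap = 0.5)
  pow_w <- sum(pw$power) * (pw$freq_hz[2] - pw$freq_hz[1])
  expect_equal(pow_w, var(w), tolerance = 0.1)
  # flat within periodogram variance: compare halves of the band
  lo <- mean(pw$power[pw$freq_hz > 1 & pw$freq_hz < 8])
  hi <- mean(pw$power[pw$freq_hz > 8 & pw$freq_hz < 16])
  expect_equal(lo / hi, 1, tolerance = 0.25)
  expect_error(welch_psd(w[1:100], fs, window_s = 20), "shorter")
})

test_that("moving averages and medians behave at edges", {
  expect_equal(moving_average(c(1, 1, 1, 1, 1), 5), rep(1, 5))
  expect_equal(moving_average(1:5, 3), c(1.5, 2, 3, 4, 4.5))
})

test_that("occlusion pipeline reproduces the phase signatures of its own
           ground truth", {
  spec <- occlusion_spec(
    durations_s = c(baseline = 18, light = 8, venous = 14, arterial = 14,
                    recovery = 32),
    fs_hz = 1,
    hyperemia = list(amp_HbO2 = 6, amp_HHb = -3, amp_DB = 1.0,
                     t_peak_s = 8, shape_k = 2),
    smooth_tau_s = 2)
  ds <- simulate_occlusion_dataset(spec, rhos = 2.5, dcs_channels = 2,
                                   N_dtof = 1e5, dcs_rate_hz = 5e4,
                                   seed = 2024)
  tr <- run_occlusion_pipeline(ds)[[1]]
  expect_s3_class(tr, "hemodynamic_trace")
  expect_true(mean(tr$ok) > 0.9)
  ph <- ds$truth$phase
  base <- ph == "baseline" & tr$t_s > 5
  ven <- ph == "venous" & tr$t_s > 36
  art <- ph == "arterial" & tr$t_s > 50
  rec <- ph == "recovery"
  m <- function(v, sel) mean(v[sel & tr$ok], na.rm = TRUE)
  # tHb = HbO2 + HHb by construction of the inversion
  expect_equal(tr$tHb, tr$HbO2 + tr$HHb, tolerance = 1e-9)
  # venous: HbO2 and HHb rise, StO2 flat
  expect_gt(m(tr$HbO2, ven), m(tr$HbO2, base) + 2)
  expect_gt(m(tr$HHb, ven), m(tr$HHb, base) + 1)
  expect_lt(abs(m(tr$StO2, ven) - m(tr$StO2, base)), 2.5)
  # arterial: tHb flat relative to venous end, StO2 falls, BFI drops hard
  expect_lt(abs(m(tr$tHb, art) - m(tr$tHb, ven)), 0.08 * m(tr$tHb, base))
  expect_lt(m(tr$StO2, art), m(tr$StO2, base) - 3)
  expect_lt(m(tr$BFI, art), 0.5 * m(tr$BFI, base))
  # release: hyperemic BFI peak
  expect_gt(max(tr$BFI[rec & tr$ok], na.rm = TRUE), 1.3 * m(tr$BFI, base))
})

test_that("baseline-only dataset gives flat traces at the noise floor", {
  spec <- occlusion_spec(durations_s = c(baseline = 25), fs_hz = 1)
  ds <- simulate_occlusion_dataset(spec, rhos = 2.5, dcs_channels = 2,
                                   N_dtof = 1e5, dcs_rate_hz = 5e4,
                                   seed = 91)
  tr <- run_occlusion_pipeline(ds)[[1]]
  cv <- function(v) sd(v[tr$ok]) / mean(v[tr$ok])
  expect_lt(cv(tr$HbO2), 0.1)
  expect_lt(cv(tr$StO2), 0.05)
  expect_lt(cv(tr$BFI), 0.2)
})

test_that("median filtering before the fit suppresses an outlier curve that
           would otherwise corrupt the BFI trace", {
  lag <- 10^seq(-6.5, -3, length.out = 50)
  g1 <- g1_semi_infinite(lag, 2.5, fix_props_dcs, fix_dyn)
  clean <- nirsdcs:::new_corr_curve(lag, siegert(g1, 0.5), 5e4, 0, 1, 1L)
  bad <- clean
  bad$g2 <- clean$g2 + 0.5 * exp(-lag / 1e-5)  # spurious fast component
  curves <- rep(list(clean), 9)
  curves[[5]] <- bad
  db_of <- function(cs) vapply(cs, function(cc)
    fit_g2(cc, 2.5, fix_props_dcs)$DB, numeric(1))
  db_nofilter <- db_of(curves)
  db_filtered <- db_of(median_filter_curves(curves, 5))
  expect_gt(abs(db_nofilter[5] / 1e-8 - 1), 0.3)   # outlier corrupts
  expect_lt(max(abs(db_filtered / 1e-8 - 1)), 0.01) # filter removes it
})

test_that("pipelines are deterministic under a fixed seed", {
  spec <- occlusion_spec(durations_s = c(baseline = 6), fs_hz = 1)
  d1 <- simulate_occlusion_dataset(spec, rhos = 2.5, dcs_channels = 1,
                                   N_dtof = 5e4, dcs_rate_hz = 2e4,
                                   seed = 5)
  d2 <- simulate_occlusion_dataset(spec, rhos = 2.5, dcs_channels = 1,
                                   N_dtof = 5e4, dcs_rate_hz = 2e4,
                                   seed = 5)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$dtof[[1]][[1]][[1]]$counts,
                   d2$dtof[[1]][[1]][[1]]$counts)
  expect_identical(d1$tags[[1]][[1]][[3]]$times_ps,
                   d2$tags[[1]][[1]][[3]]$times_ps)
  t1 <- run_occlusion_pipeline(d1)[[1]]
  t2 <- run_occlusion_pipeline(d2)[[1]]
  expect_identical(t1, t2)
})

test_that("configuration loads defaults and YAML overrides", {
  cfg <- nirsdcs_config()
  expect_equal(cfg$nirs$dt_ps, 9.77)
  expect_equal(cfg$dcs$correlator$base_bin_s, 2e-7)
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(dcs = list(beta = 0.4)), p)
  cfg2 <- nirsdcs_config(p)
  expect_equal(cfg2$dcs$beta, 0.4)
  expect_equal(cfg2$nirs$dt_ps, 9.77)
})

test_that("pulsatility pipeline finds the cardiac peak and its harmonics", {
  sim <- simulate_pulsatile_bfi(heart_rate_hz = 1.2, amplitude = 0.35,
                                harmonics = 2, fs_hz = 100 / 3,
                                duration_s = 30, rate_hz = 1e5,
                                rho = 1.5, DB0 = 1.5e-8, seed = 77)
  out <- run_pulsatility_pipeline(sim$streams, rho = 1.5,
                                  props = optical_props(0.1, 10, n = 1.4,
                                                        wavelength = 785),
                                  psd_window_s = 15)
  p <- out$psd
  band <- function(f0) p$freq_hz > f0 - 0.15 & p$freq_hz < f0 + 0.15
  floor_band <- p$freq_hz > 3.5 & p$freq_hz < 8
  expect_gt(max(p$power[band(1.2)]), 10 * mean(p$power[floor_band]))
  # visible first harmonic
  expect_gt(max(p$power[band(2.4)]), 3 * mean(p$power[floor_band]))
  # recovered BFI oscillates around the programmed baseline
  expect_equal(median(out$trace$BFI), 1.5e-8, tolerance = 0.15)
  # zero amplitude: no cardiac peak above the floor
  sim0 <- simulate_pulsatile_bfi(heart_rate_hz = 1.2, amplitude = 0,
                                 harmonics = 2, fs_hz = 100 / 3,
                                 duration_s = 25, rate_hz = 1e5,
                                 rho = 1.5, DB0 = 1.5e-8, seed = 78)
  out0 <- run_pulsatility_pipeline(sim0$streams, rho = 1.5,
                                   props = optical_props(0.1, 10, n = 1.4,
                                                         wavelength = 785),
                                   psd_window_s = 15)
  p0 <- out0$psd
  # the cardiac band of the unmodulated run sits at the noise floor: far
  # below the modulated run's peak
  expect_lt(max(p0$power[band(1.2)]), 0.05 * max(p$power[band(1.2)]))
})
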