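# Synthetic instrument generators.

test_that("make_irf honors the requested shape and total counts", {
  set.seed(61)
  # pure Gaussian: FWHM within 2 dt of the specification
  irf_g <- make_irf(irf_spec(fwhm_ps = 200, tail_weights = c(0, 0),
                             background_frac = 0), N_tot = 2e6)
  expect_equal(irf_g$descriptors$fwhm_ps, 200, tolerance = 2 * 9.77 / 200)
  expect_equal(sum(irf_g$histogram$counts), 2e6, tolerance = 4 / sqrt(2e6))
  # default double-exponential tail still within 2 dt
  expect_equal(fix_irf$descriptors$fwhm_ps, 200,
               tolerance = 2 * 9.77 / 200)
  # tail weight shifts the center of mass per the first-moment formula:
  # a tail component of weight w and decay tau adds w * tau to the mean
  irf_t <- make_irf(irf_spec(fwhm_ps = 200, tail_weights = c(0.3, 0),
                             tail_tau_ps = c(300, 600),
                             background_frac = 0), N_tot = 5e6)
  shift <- irf_t$descriptors$com_ps - irf_g$descriptors$com_ps
  expect_equal(shift, 0.3 * 300, tolerance = 0.15)
  # secondary reflection adds a delayed replica
  spec_r <- irf_spec(peak_ps = 3000,
                     reflection = list(delay_ps = 2000, amplitude = 0.02),
                     background_frac = 0)
  irf_r <- make_irf(spec_r, N_tot = 5e6)
  irf_n <- make_irf(irf_spec(peak_ps = 3000, background_frac = 0),
                    N_tot = 5e6)
  pk <- which.max(irf_r$histogram$counts)
  repl <- (pk + 200):(pk + 212)
  expect_gt(sum(irf_r$histogram$counts[repl]),
            5 * (sum(irf_n$histogram$counts[repl]) + 100))
})

test_that("simulate_dtof totals are Poisson-consistent and concentrate on
           the IRF shape at extreme absorption", {
  set.seed(63)
  d <- simulate_dtof(fix_props_nirs, 2.5, fix_irf, N_target = 5e5)
  expect_lt(abs(sum(d$counts) - 5e5), 4 * sqrt(5e5))
  # strong absorption kills the diffuse tail: the histogram approaches the
  # IRF shape (compare FWHM)
  d_abs <- simulate_dtof(optical_props(2, 10, n = 1.4), 1.0, fix_irf,
                         N_target = 5e5, background = 0)
  w_abs <- irf_descriptors(d_abs)$fwhm_ps
  w_dif <- irf_descriptors(d)$fwhm_ps
  expect_lt(w_abs, 0.6 * w_dif)
  expect_lt(abs(w_abs - fix_irf$descriptors$fwhm_ps), 60)
})

test_that("generators are seed-deterministic", {
  a <- simulate_dtof(fix_props_nirs, 2.5, fix_irf, N_target = 1e5, seed = 7)
  b <- simulate_dtof(fix_props_nirs, 2.5, fix_irf, N_target = 1e5, seed = 7)
  expect_identical(a$counts, b$counts)
  g1f <- function(tau) g1_semi_infinite(tau, 2.5, fix_props_dcs, fix_dyn)
  s1 <- simulate_speckle_tags(g1f, 2e4, 1, beta = 0.5, seed = 5)
  s2 <- simulate_speckle_tags(g1f, 2e4, 1, beta = 0.5, seed = 5)
  expect_identical(s1$streams[[1]]$times_ps, s2$streams[[1]]$times_ps)
})

test_that("exponential-mixture approximation of g1 is accurate", {
  g1f <- function(tau) g1_semi_infinite(tau, 2.5, fix_props_dcs, fix_dyn)
  mix <- g1_expmix(g1f, tau_max_s = 2e-3)
  expect_lt(mix$max_err, 5e-3)
  expect_equal(sum(mix$c2), 1, tolerance = 1e-12)
  expect_true(all(mix$c2 > 0))
})

test_that("static-medium limit passes a Poisson dispersion test", {
  # DB = 0: constant intensity within a window -> photon counts in equal
  # bins are Poisson (variance/mean = 1) and g2 = 1
  res <- simulate_speckle_tags(function(tau) rep(1, length(tau)),
                               rate_hz = 5e4, duration_s = 4, beta = 1,
                               n_channels = 1, seed = 31)
  s <- res$streams[[1]]
  bins <- tabulate(floor(s$times_ps / 1e9) + 1, nbins = 4000)  # 1 ms bins
  disp <- var(bins) / mean(bins)
  # dispersion ratio ~ 1 +/- sqrt(2/n)
  expect_lt(abs(disp - 1), 5 * sqrt(2 / 4000))
  cv <- multitau_g2(s, correlator_config(base_bin_s = 1e-6, m = 16,
                                         octaves = 8))
  expect_lt(max(abs(cv$g2 - 1)), 0.05)
})

test_that("halving the count rate leaves g2 unchanged within error", {
  g1f <- function(tau) g1_semi_infinite(tau, 2.5, fix_props_dcs, fix_dyn)
  cfg <- correlator_config(base_bin_s = 5e-7, m = 16, octaves = 10)
  set.seed(71)
  mix <- g1_expmix(g1f, 2 * nirsdcs:::max_lag_s(cfg))
  tt <- nirsdcs:::.speckle_multi_rate(mix, c(2e4, 4e4), 6, M = 2)
  g2s <- lapply(tt, function(x)
    multitau_g2(tag_stream(nirsdcs:::.make_strict(x), 1, 6), cfg)$g2)
  expect_lt(sqrt(mean((g2s[[1]] - g2s[[2]])^2)), 0.02)
})

test_that("inclusion scan: zero strength gives zero contrast; x-scan is
           symmetric about the midpoint", {
  pr <- optical_props(0.1, 10, n = 1.4)
  sc0 <- simulate_inclusion_scan(pr, 2.5, z_mm = c(5, 10), dmua_v = 0,
                                 n_rep = 2, seed = 1)
  expect_equal(sc0$expected,
               matrix(rep(sc0$expected_ref, each = 2), nrow = 2),
               tolerance = 1e-12)
  x <- seq(-15, 40, by = 5)   # midpoint at rho/2 = 12.5 mm
  scx <- simulate_inclusion_scan(pr, 2.5, z_mm = 12, x_mm = x,
                                 n_rep = 2, seed = 2)
  C <- -log(sweep(scx$expected, 2, scx$expected_ref, "/"))
  ctot <- rowSums(C)
  # symmetry about x = 12.5: compare x = -15..10 with mirror 40..15
  expect_equal(ctot[1:6], rev(ctot)[1:6], tolerance = 1e-8)
  expect_warning(simulate_inclusion_scan(pr, 2.5, z_mm = c(5, 10),
                                         dmua_v = 3, n_rep = 2),
                 "perturbative")
})

test_that("early gates lose contrast at shallower depths than late gates", {
  pr <- optical_props(0.1, 10, n = 1.4)
  sc <- simulate_inclusion_scan(pr, 2.5, z_mm = seq(0, 30, 2), seed = 3)
  C <- -log(sweep(sc$expected, 2, sc$expected_ref, "/"))
  early <- rowSums(C[, 2:3]); late <- rowSums(C[, 5:6])
  z <- sc$coord
  vanish <- function(cc) z[which(cc < 0.05 * max(cc))[1]]
  expect_lt(vanish(early), vanish(late))
  # shallow: early > late; deep: late > early
  expect_gt(early[z == 0], late[z == 0])
  expect_gt(late[z == 16], early[z == 16])
})

test_that("plane-integrated Born kernel reproduces the absorption
           derivative when integrated over all depths", {
  pr <- optical_props(0.15, 10, n = 1.4)
  ls <- simulate_layer_scan(pr, 2.5, 0, 80, dmua = 0.01, nz = 200)
  v <- 0.0299792458 / 1.4
  sel <- ls$t_ps > 500 & ls$t_ps < 3500
  ratio <- ls$relp[sel] / (0.01 * v * ls$t_ps[sel])
  expect_true(all(ratio > 0.9 & ratio < 1.05))
})

test_that("occlusion truth encodes the expected phase phenomenology", {
  spec <- occlusion_spec()
  tr <- occlusion_truth(spec)
  base <- tr$phase == "baseline" & tr$t_s > 60
  ven_end <- tr$phase == "venous" & tr$t_s > 230
  art_end <- tr$phase == "arterial" & tr$t_s > 290
  # venous: HbO2 and HHb rise, StO2 constant
  expect_gt(mean(tr$HbO2[ven_end]), mean(tr$HbO2[base]) + 3)
  expect_gt(mean(tr$HHb[ven_end]), mean(tr$HHb[base]) + 1)
  expect_lt(abs(mean(tr$StO2[ven_end]) - mean(tr$StO2[base])), 1)
  # arterial: tHb constant vs venous end (within smoothing lag), StO2
  # falls, DB drops
  expect_lt(abs(mean(tr$tHb[art_end]) - mean(tr$tHb[ven_end])), 2.5)
  expect_lt(mean(tr$StO2[art_end]), mean(tr$StO2[base]) - 3)
  expect_lt(mean(tr$DB[art_end]), 0.4 * mean(tr$DB[base]))
  # recovery: hyperemic DB overshoot then return toward baseline
  rec <- tr$phase == "recovery"
  expect_gt(max(tr$DB[rec]), 1.3 * mean(tr$DB[base]))
  tail_rec <- rec & tr$t_s > max(tr$t_s) - 30
  expect_lt(abs(mean(tr$DB[tail_rec]) / mean(tr$DB[base]) - 1), 0.25)
})

test_that("pulsatile generator rejects aliasing configurations", {
  expect_error(simulate_pulsatile_bfi(heart_rate_hz = 3, harmonics = 8,
                                      fs_hz = 30, duration_s = 5),
               "aliasing")
})
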