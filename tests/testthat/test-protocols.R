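# Protocol statistics: contrast, CNR, selectivity, resolution, noise,
# stability, reproducibility, linearity.

test_that("contrast arithmetic", {
  expect_equal(neuropt_contrast(100, 100), 0)
  expect_equal(neuropt_contrast(100 / exp(1), 100), 1)
  expect_equal(neuropt_contrast(90000, 100000), 0.10536, tolerance = 1e-4)
  expect_equal(neuropt_contrast(90000, 100000, log_base = "10"),
               0.10536 / log(10), tolerance = 1e-4)
  expect_error(neuropt_contrast(0, 10), "> 0")
})

test_that("CNR uses the sample sd of log counts and follows the
           delta-method prediction", {
  expect_equal(neuropt_cnr(0.1, log(c(100, 100) * c(1.01, 0.99))),
               0.1 / sd(log(c(101, 99))))
  expect_equal(neuropt_cnr(0.1, matrix(c(0.99, 1.01, 1.02, 0.98), 1)),
               0.1 / sd(c(0.99, 1.01, 1.02, 0.98)))
  expect_error(neuropt_cnr(0.1, rep(5, 10)), "zero variance")
  # Poisson gate counts: sd(log N) ~ 1/sqrt(N) so CNR ~ C sqrt(N)
  set.seed(17)
  N <- 1e5; C <- 0.2
  reps <- rpois(200, N)
  cnr <- neuropt_cnr(C, log(reps))
  expect_equal(cnr, C * sqrt(N), tolerance = 0.15)
})

test_that("selectivity ratio and its degenerate case", {
  expect_equal(neuropt_selectivity(0.3, 0.3), 1)
  expect_equal(neuropt_selectivity(c(0.4, 0.1), c(0.2, 0.2)), c(2, 0.5))
  expect_error(neuropt_selectivity(0.1, 0), "zero")
})

test_that("deep-layer selectivity is higher for late gates and larger rho
           on the Born bilayer model", {
  pr <- optical_props(0.15, 10, n = 1.4)
  S_up <- function(rho) {
    up <- simulate_layer_scan(pr, rho, 0, 10, dmua = 0.05)
    dn <- simulate_layer_scan(pr, rho, 10, 70, dmua = 0.05)
    Cu <- neuropt_contrast(up$N_k, up$N_k_ref)
    Cd <- neuropt_contrast(dn$N_k, dn$N_k_ref)
    neuropt_selectivity(Cu, Cd)
  }
  s15 <- S_up(1.5); s25 <- S_up(2.5)
  # printed ratio C_up/C_down falls for late gates <=> deep selectivity
  # C_down/C_up rises for late gates
  expect_lt(s25[5], s25[2])
  expect_lt(s15[5], s15[2])
  # larger rho: more deep-selective (early and mid gates)
  expect_lt(s25[1], s15[1])
  expect_lt(s25[2], s15[2])
  expect_lt(s25[3], s15[3])
  # small-perturbation limit is finite and matches the sensitivity ratio
  up_eps <- simulate_layer_scan(pr, 2.5, 0, 10, dmua = 1e-4)
  dn_eps <- simulate_layer_scan(pr, 2.5, 10, 70, dmua = 1e-4)
  S_eps <- neuropt_selectivity(neuropt_contrast(up_eps$N_k, up_eps$N_k_ref),
                               neuropt_contrast(dn_eps$N_k, dn_eps$N_k_ref))
  expect_true(all(is.finite(S_eps[1:6])))
  up2 <- simulate_layer_scan(pr, 2.5, 0, 10, dmua = 5e-4)
  dn2 <- simulate_layer_scan(pr, 2.5, 10, 70, dmua = 5e-4)
  S2 <- neuropt_selectivity(neuropt_contrast(up2$N_k, up2$N_k_ref),
                            neuropt_contrast(dn2$N_k, dn2$N_k_ref))
  expect_equal(S_eps[1:6], S2[1:6], tolerance = 1e-2)
})

test_that("scan FWHM: triangular closed form, translation invariance, and
           gate ordering on simulated x-scans", {
  x <- seq(-20, 20, by = 0.5)
  tri <- pmax(1 - abs(x) / 8, 0)       # half-max crossings at +/- 4
  expect_equal(scan_fwhm(x, tri), 8, tolerance = 1e-9)
  expect_equal(scan_fwhm(x + 7, tri), 8, tolerance = 1e-9)
  expect_error(scan_fwhm(x, x * 0 + 1), "peak")
  pr <- optical_props(0.1, 10, n = 1.4)
  scx <- simulate_inclusion_scan(pr, 2.5, z_mm = 15,
                                 x_mm = seq(-25, 50, 2.5), seed = 5)
  C <- -log(sweep(scx$expected, 2, scx$expected_ref, "/"))
  w_early <- scan_fwhm(scx$coord, rowSums(C[, 2:3]))
  w_late <- scan_fwhm(scx$coord, rowSums(C[, 5:6]))
  expect_lt(w_early, w_late)
})

test_that("noise scan on constructed N^(-1/2) data is exact", {
  counts <- 10^seq(4, 6, length.out = 6)
  cv_true <- 0.3 / sqrt(counts)
  set.seed(19)
  # construct repetition sets whose sample CV is exactly cv_true
  vals <- lapply(cv_true, function(cv) {
    v <- rnorm(10)
    1 + (v - mean(v)) / sd(v) * cv
  })
  ns <- medphot_noise_scan(vals, counts, cv_threshold = 0.03)
  expect_equal(ns$slope, -0.5, tolerance = 1e-9)
  expect_equal(ns$r_squared, 1, tolerance = 1e-9)
  expect_equal(ns$counts_at_threshold, (0.3 / 0.03)^2, tolerance = 1e-6)
  expect_error(medphot_noise_scan(vals[1:2], counts[1:2]), ">= 3")
})

test_that("stability metrics: constant, step and exponential approach", {
  t <- seq(0, 1000, by = 1)
  const <- rep(5, length(t))
  m <- stability_metrics(t, const)
  expect_equal(m$warmup_s, 0)
  expect_equal(m$cv_percent, 0)
  stepy <- ifelse(t < 300, 4, 5)
  ms <- stability_metrics(t, stepy)
  expect_equal(ms$warmup_s, 300, tolerance = 1)
  # exponential approach with time constant tauc and initial deficit Delta:
  # enters the p% band at tauc * log(Delta / p)
  tauc <- 120; Delta <- 0.2
  ye <- 10 * (1 - Delta * exp(-t / tauc))
  me <- stability_metrics(t, ye, band_percent = 1)
  expect_equal(me$warmup_s, tauc * log(Delta / 0.01), tolerance = 0.05 *
                 tauc * log(Delta / 0.01))
  never <- t * 0.01  # drifts forever
  mn <- stability_metrics(t, never)
  expect_false(mn$stabilized)
  expect_equal(mn$warmup_s, 1000)
})

test_that("reproducibility CV arithmetic and Poisson-level consistency", {
  expect_equal(reproducibility_cv(c(10, 10, 10)), 0)
  expect_equal(reproducibility_cv(c(9, 11)), 100 * sd(c(9, 11)) / 10)
  expect_equal(reproducibility_cv(c(9, 11)), 14.1421, tolerance = 1e-4)
  expect_error(reproducibility_cv(9), "2 days")
  m <- cbind(a = c(10, 10.1, 9.9), b = c(5, 5, 5))
  expect_equal(unname(reproducibility_cv(m)[2]), 0)
  # stationary simulated instrument: day means of Poisson counts
  set.seed(23)
  days <- replicate(6, mean(rpois(30, 1e4)))
  expect_lt(reproducibility_cv(days), 3 * 100 / sqrt(30 * 1e4))
})

test_that("linearity statistics on ideal and biased grids", {
  conv <- expand.grid(mua = seq(0.05, 0.4, length.out = 4),
                      musp = seq(5, 20, length.out = 4))
  perfect <- medphot_linearity(conv, conv)
  expect_equal(perfect$slope_mua, 1, tolerance = 1e-12)
  expect_equal(perfect$slope_musp, 1, tolerance = 1e-12)
  expect_equal(perfect$mare_mua, 0, tolerance = 1e-12)
  expect_equal(perfect$coupling_mua_on_musp, 0, tolerance = 1e-12)
  biased <- conv; biased$mua <- 1.03 * conv$mua; biased$musp <- 1.03 * conv$musp
  b <- medphot_linearity(biased, conv)
  expect_equal(b$slope_mua, 1.03, tolerance = 1e-12)
  expect_equal(b$mare_mua, 0.03, tolerance = 1e-12)
  expect_equal(b$mare_musp, 0.03, tolerance = 1e-12)
})

test_that("end-to-end linearity on a small simulated phantom grid", {
  set.seed(47)
  grid <- expand.grid(mua = c(0.05, 0.15, 0.3), musp = c(7, 12, 18))
  fits <- t(apply(grid, 1, function(g) {
    d <- simulate_dtof(optical_props(g[1], g[2], n = 1.4), 2.5, fix_irf,
                       N_target = 3e5)
    f <- fit_dtof(d, fix_irf, rho = 2.5, n = 1.4,
                  opts = list(mua_init = 0.1, musp_init = 10))
    c(mua = f$mua, musp = f$musp)
  }))
  lin <- medphot_linearity(as.data.frame(fits), grid)
  expect_equal(lin$slope_mua, 1, tolerance = 0.05)
  expect_equal(lin$slope_musp, 1, tolerance = 0.05)
  expect_lt(abs(lin$coupling_mua_on_musp), 0.005)
  expect_lt(lin$mare_mua, 0.05)
})

test_that("dcs_noise_scan on constructed data reproduces exact CVs and
           threshold interpolation", {
  set.seed(53)
  levels <- c(10, 20, 40, 80)
  cv_true <- 0.4 / levels   # slope -1 in log-log
  vals <- lapply(cv_true, function(cv) {
    v <- rnorm(60)
    1e-8 * (1 + (v - mean(v)) / sd(v) * cv)
  })
  sc <- dcs_noise_scan(vals, levels, cv_threshold = 0.05)
  expect_equal(sc$cv_percent, 100 * cv_true, tolerance = 1e-9)
  expect_equal(sc$slope, -1, tolerance = 1e-9)
  expect_equal(sc$level_at_threshold, 0.4 / 0.05, tolerance = 1e-6)
  expect_error(dcs_noise_scan(vals, levels, min_windows = 100),
               "insufficient")
})

test_that("protocol reports serialize to JSON and CSV", {
  ns <- list(counts = c(1e4, 1e5), cv_percent = c(5, 1.5), slope = -0.52)
  pre <- file.path(tempdir(), "noise_report")
  write_protocol_report(ns, pre)
  back <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(back$slope, -0.52)
  tab <- read.csv(paste0(pre, ".csv"))
  expect_equal(tab$cv_percent, c(5, 1.5))
})
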