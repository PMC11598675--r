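# BIP/MEDPHOT/nEUROPt and DCS-noise characterization statistics.

#' Gated contrast of a perturbation measurement
#'
#' `C_k = -log(N_k / N_k_ref)` (natural log by default; base-10 available
#' for comparability with conventions that use it). Positive for an
#' absorbing perturbation (`N_k < N_k_ref`).
#'
#' @param N_k,N_k_ref photon counts in gate k with and without the
#'   perturbation (both > 0); vectors are handled elementwise
#' @param log_base `"natural"` (default) or `"10"`
#' @return contrast values
#' @export
neuropt_contrast <- function(N_k, N_k_ref, log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  .assert(all(N_k > 0) && all(N_k_ref > 0), "counts must be > 0")
  C <- -log(N_k / N_k_ref)
  if (log_base == "10") C <- C / log(10)
  C
}

#' Contrast-to-noise ratio
#'
#' `CNR_k = C_k / sd(log N_k)` with the sample (n-1) standard deviation of
#' the per-repetition log gate counts.
#'
#' @param C_k contrast (scalar or vector over gates)
#' @param logN_reps matrix of log gate counts, gates x repetitions (or a
#'   vector of repetitions for a single gate)
#' @return CNR values; zero spread across repetitions is an error
#' @export
neuropt_cnr <- function(C_k, logN_reps) {
  if (is.vector(logN_reps)) logN_reps <- matrix(logN_reps, nrow = 1)
  .assert(ncol(logN_reps) >= 2, "need at least 2 repetitions")
  s <- apply(logN_reps, 1, sd)
  if (any(s == 0)) stop("zero variance across repetitions", call. = FALSE)
  C_k / s
}

#' Depth selectivity
#'
#' Ratio of the contrasts produced by the same absorption change applied to
#' the upper vs the lower layer of a bilayer medium, `S_k = C_up / C_down`;
#' S = 1 when the two contrasts are equal, S < 1 when the instrument is more
#' sensitive to the deep layer.
#'
#' @param C_up,C_down contrasts for the upper- and lower-layer change
#' @return selectivity values; a zero denominator is an error
#' @export
neuropt_selectivity <- function(C_up, C_down) {
  if (any(C_down == 0)) stop("zero lower-layer contrast", call. = FALSE)
  C_up / C_down
}

#' FWHM of a single-peaked scan profile
#'
#' Linear-interpolated half-maximum crossings of, e.g., contrast vs the
#' longitudinal inclusion position (the bell curves whose width gives the
#' longitudinal resolution).
#'
#' @param x coordinate values (mm), increasing
#' @param y profile values (single peak)
#' @return FWHM in the units of `x`
#' @export
scan_fwhm <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 3, "need >= 3 points")
  pk <- which.max(y)
  .assert(pk > 1 && pk < length(y), "no interior peak")
  half <- y[pk] / 2
  iL <- rev(which(y[1:pk] < half))[1]
  iR <- pk - 1 + which(y[pk:length(y)] < half)[1]
  .assert(!is.na(iL) && !is.na(iR), "profile does not cross half maximum")
  xL <- x[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) * (x[iL + 1] - x[iL])
  xR <- x[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) *
    (x[iR] - x[iR - 1])
  xR - xL
}

#' Noise scan of fitted optical parameters vs photon counts
#'
#' Coefficient of variation (sd/mean over repetitions) of a fitted quantity
#' at several total-count levels, with an ordinary least-squares fit of
#' `log10 CV` on `log10 N` (the Poisson-limited trend has slope -1/2) and
#' threshold-count interpolation on the fitted line in log-log space.
#'
#' @param values matrix of fitted values, levels x repetitions, or a list of
#'   per-level vectors
#' @param counts total counts per level
#' @param cv_threshold CV (as a fraction, e.g. 0.03) at which the crossing
#'   count is interpolated on the fitted line
#' @return list: `counts`, `cv_percent`, `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `counts_at_threshold`
#' @export
medphot_noise_scan <- function(values, counts, cv_threshold = 0.03) {
  if (is.list(values)) {
    .assert(all(lengths(values) >= 5), "need >= 5 repetitions per level")
    cv <- vapply(values, function(v) sd(v) / mean(v), numeric(1))
  } else {
    .assert(ncol(values) >= 5, "need >= 5 repetitions per level")
    cv <- apply(values, 1, function(v) sd(v) / mean(v))
  }
  .assert(length(counts) == length(cv), "counts/values length mismatch")
  ok <- is.finite(cv) & cv > 0
  .assert(sum(ok) >= 2, "fewer than 2 valid levels")
  .assert(length(counts) >= 3, "need >= 3 count levels")
  fit <- lm(log10(cv[ok]) ~ log10(counts[ok]))
  # constructed inputs can fit exactly; the perfect-fit warning is benign
  sl <- suppressWarnings(summary(fit))$coefficients
  slope <- sl[2, 1]
  b0 <- sl[1, 1]
  nthr <- 10^((log10(cv_threshold) - b0) / slope)
  list(counts = counts, cv_percent = 100 * cv, slope = slope,
       slope_se = sl[2, 2], intercept = b0,
       r_squared = suppressWarnings(summary(fit))$r.squared,
       counts_at_threshold = nthr, cv_threshold = cv_threshold)
}

#' Warm-up and stability of a monitored quantity
#'
#' Reference value = mean of the final 10% of samples; warm-up = first time
#' the series enters the +/- p% band around the reference and never leaves
#' it again; the CV is computed over the post-warm-up samples.
#'
#' @param t_s sample times, s
#' @param y monitored values
#' @param band_percent half-width of the stationarity band, % (default 1)
#' @return list: `warmup_s`, `cv_percent` (post-warm-up), `reference`,
#'   `stabilized` (FALSE when the series never settles; `warmup_s` is then
#'   the measurement duration)
#' @export
stability_metrics <- function(t_s, y, band_percent = 1) {
  .assert(length(t_s) == length(y) && length(y) >= 10, "series too short")
  n <- length(y)
  ref <- mean(y[ceiling(0.9 * n):n])
  inside <- abs(y - ref) <= abs(ref) * band_percent / 100
  # last index that is outside the band
  out_idx <- which(!inside)
  if (length(out_idx) == 0) {
    k <- 1L
  } else if (max(out_idx) == n) {
    return(list(warmup_s = t_s[n] - t_s[1], cv_percent = NA_real_,
                reference = ref, stabilized = FALSE))
  } else {
    k <- max(out_idx) + 1L
  }
  post <- y[k:n]
  list(warmup_s = t_s[k] - t_s[1],
       cv_percent = 100 * sd(post) / mean(post),
       reference = ref, stabilized = TRUE)
}

#' Day-to-day reproducibility
#'
#' CV (sample sd / mean, %) of per-day estimates of a quantity.
#'
#' @param day_values vector of per-day values (>= 2 days), or a matrix with
#'   one column per quantity
#' @return CV in % (vector when a matrix is given)
#' @export
reproducibility_cv <- function(day_values) {
  if (is.matrix(day_values)) {
    .assert(nrow(day_values) >= 2, "need >= 2 days")
    return(apply(day_values, 2, function(v) 100 * sd(v) / mean(v)))
  }
  .assert(length(day_values) >= 2, "need >= 2 days")
  100 * sd(day_values) / mean(day_values)
}

#' Linearity, accuracy and coupling over a phantom grid
#'
#' Per-series regression of measured on conventional values, mean absolute
#' relative error, and cross-coupling (regression slope of measured mua on
#' conventional musp and vice versa).
#'
#' @param measured data.frame with columns `mua`, `musp` (fitted values)
#' @param conventional data.frame with columns `mua`, `musp` (reference)
#' @return list with `slope_mua`, `slope_musp`, `mare_mua`, `mare_musp`
#'   (mean absolute relative errors), `coupling_mua_on_musp`,
#'   `coupling_musp_on_mua` (slopes, ideally 0)
#' @export
medphot_linearity <- function(measured, conventional) {
  .assert(nrow(measured) == nrow(conventional) && nrow(measured) >= 3,
          "need >= 3 phantoms")
  sl <- function(y, x) unname(coef(lm(y ~ x))[2])
  ok_a <- conventional$mua > 1e-6
  list(slope_mua = sl(measured$mua, conventional$mua),
       slope_musp = sl(measured$musp, conventional$musp),
       mare_mua = mean(abs(measured$mua[ok_a] / conventional$mua[ok_a] - 1)),
       mare_musp = mean(abs(measured$musp / conventional$musp - 1)),
       coupling_mua_on_musp = sl(measured$mua, conventional$musp),
       coupling_musp_on_mua = sl(measured$musp, conventional$mua))
}

#' DCS noise scan: CV of the fitted diffusion coefficient
#'
#' Simulates (or accepts) repeated fitted `DB` values over analysis windows
#' at several levels of one swept factor (count rate, duration or number of
#' averaged channels), computes the CV per level and the log-log slope, and
#' returns the level at which the CV crosses a threshold (interpolated on
#' the fitted line). The companion curve from the shot-noise variance model
#' ([g2_noise_model()]) is attached for comparison.
#'
#' @param db_values list (one element per level) of fitted DB vectors
#'   across windows
#' @param levels numeric values of the swept factor (e.g. count rate, kHz)
#' @param factor_name name of the swept factor
#' @param cv_threshold threshold CV as a fraction (default 0.05)
#' @param min_windows minimum fitted windows per level (default 50)
#' @return list: `levels`, `cv_percent`, `slope`, `r_squared`,
#'   `level_at_threshold`
#' @export
dcs_noise_scan <- function(db_values, levels,
                           factor_name = "count_rate_khz",
                           cv_threshold = 0.05, min_windows = 50) {
  .assert(length(db_values) == length(levels), "levels mismatch")
  .assert(length(levels) >= 3, "need >= 3 levels")
  nw <- lengths(db_values)
  .assert(all(nw >= min_windows),
          sprintf("insufficient windows (min %d, got %d)", min_windows,
                  min(nw)))
  cv <- vapply(db_values, function(v) sd(v) / mean(v), numeric(1))
  fit <- lm(log10(cv) ~ log10(levels))
  slope <- unname(coef(fit)[2]); b0 <- unname(coef(fit)[1])
  lev_thr <- 10^((log10(cv_threshold) - b0) / slope)
  list(levels = levels, factor_name = factor_name, cv_percent = 100 * cv,
       slope = slope,
       r_squared = suppressWarnings(summary(fit))$r.squared,
       level_at_threshold = lev_thr, cv_threshold = cv_threshold)
}

#' Serialize a protocol report
#'
#' Writes any protocol result list as JSON beside a CSV table of its
#' vector fields.
#'
#' @param report a list as returned by the protocol functions
#' @param path_prefix output path without extension
#' @return invisibly, the JSON path
#' @export
write_protocol_report <- function(report, path_prefix) {
  jp <- paste0(path_prefix, ".json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  vecs <- Filter(function(x) is.numeric(x) && length(x) > 1, report)
  if (length(vecs) > 0 && length(unique(lengths(vecs))) == 1)
    write.csv(as.data.frame(vecs), paste0(path_prefix, ".csv"),
              row.names = FALSE)
  invisible(jp)
}
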