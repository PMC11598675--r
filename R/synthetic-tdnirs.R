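# Photon-level synthetic TD-NIRS instrument: IRFs, DTOFs and movable-
# inclusion scans (first Born approximation).

#' Synthetic IRF specification
#'
#' Noiseless profile: Gaussian core convolved with a double-exponential
#' falling tail (the shape typical of SiPM detectors), plus a flat
#' signal-dependent background and an optional delayed secondary-reflection
#' replica.
#'
#' @param fwhm_ps FWHM of the Gaussian core, ps (default 200)
#' @param peak_ps position of the peak on the time axis, ps
#' @param tail_tau_ps decay constants of the two exponential tail terms, ps
#' @param tail_weights weights of the two tail terms (fraction of the
#'   response routed through each exponential; 0 gives a pure Gaussian)
#' @param background_frac fraction of the total counts spread uniformly
#'   over all channels (flat afterpulsing-like background)
#' @param reflection `NULL`, or `list(delay_ps =, amplitude =)` for a
#'   secondary peak (relative amplitude)
#' @return object of class `irf_spec`
#' @export
irf_spec <- function(fwhm_ps = 200, peak_ps = 2000,
                     tail_tau_ps = c(120, 600), tail_weights = c(0.08, 0.02),
                     background_frac = 1e-3, reflection = NULL) {
  .assert(fwhm_ps > 0, "FWHM must be > 0")
  .assert(all(tail_weights >= 0) && sum(tail_weights) < 1,
          "tail weights must be >= 0 and sum below 1")
  structure(list(fwhm_ps = fwhm_ps, peak_ps = peak_ps,
                 tail_tau_ps = tail_tau_ps, tail_weights = tail_weights,
                 background_frac = background_frac, reflection = reflection),
            class = "irf_spec")
}

# noiseless IRF profile on a channel grid (sums to 1 over signal part)
irf_profile <- function(spec, n_channels, dt_ps) {
  t <- (seq_len(n_channels) - 1) * dt_ps
  sigma <- spec$fwhm_ps / (2 * sqrt(2 * log(2)))
  core <- exp(-(t - spec$peak_ps)^2 / (2 * sigma^2))
  core <- core / sum(core)
  w <- spec$tail_weights
  kern <- numeric(n_channels)
  kern[1] <- 1 - sum(w)
  tk <- t
  for (i in seq_along(w)) if (w[i] > 0) {
    e <- exp(-tk / spec$tail_tau_ps[i])
    kern <- kern + w[i] * e / sum(e)
  }
  prof <- Re(fft(fft(core) * fft(kern), inverse = TRUE)) / n_channels
  if (!is.null(spec$reflection)) {
    dchan <- round(spec$reflection$delay_ps / dt_ps)
    repl <- c(rep(0, dchan), head(prof, n_channels - dchan)) *
      spec$reflection$amplitude
    prof <- prof + repl
  }
  pmax(prof, 0) / sum(pmax(prof, 0))
}

#' Generate a Poisson-sampled synthetic IRF
#'
#' @param spec an [irf_spec()]
#' @param N_tot expected total signal counts
#' @param dt_ps channel width, ps
#' @param T_rep_ps laser period, ps (sets the number of channels)
#' @param wavelength_nm recorded wavelength
#' @param seed optional seed for reproducibility
#' @return an [irf_record()] (descriptors computed from the sampled
#'   histogram)
#' @export
make_irf <- function(spec, N_tot = 1e6, dt_ps = 9.77, T_rep_ps = 12500,
                     wavelength_nm = NA_real_, seed = NULL) {
  .assert(inherits(spec, "irf_spec"), "spec must be an irf_spec")
  .assert(N_tot > 0, "N_tot must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nch <- floor(T_rep_ps / dt_ps)
  mu <- N_tot * irf_profile(spec, nch, dt_ps) +
    N_tot * spec$background_frac / nch
  counts <- rpois(nch, mu)
  irf_record(dtof(counts, dt_ps = dt_ps, T_rep_ps = T_rep_ps,
                  wavelength_nm = wavelength_nm))
}

#' Simulate a measured DTOF
#'
#' Per-channel Poisson draws around `A * (IRF (x) td_reflectance) +
#' background`, with the amplitude chosen so the expected signal total
#' equals `N_target`.
#'
#' @param props an [optical_props()]
#' @param rho source-detector distance, cm
#' @param irf an [irf_record()] (its measured histogram is used, background
#'   subtracted and area-normalized)
#' @param N_target expected total signal counts
#' @param background expected background counts per channel (default 0)
#' @param t0_ps extra instrumental delay applied to the model, ps
#' @param acq_time_s recorded acquisition time
#' @param seed optional seed
#' @param sample Poisson-sample the histogram (default); `FALSE` returns
#'   the noiseless expected counts
#' @return a [dtof()]
#' @export
simulate_dtof <- function(props, rho, irf, N_target = 5e5, background = 0,
                          t0_ps = 0, acq_time_s = NA_real_, seed = NULL,
                          sample = TRUE) {
  .assert(inherits(irf, "irf_record"), "irf must be an irf_record")
  if (!is.null(seed)) set.seed(seed)
  h <- irf$histogram
  nch <- length(h$counts)
  ir <- pmax(h$counts - irf$descriptors$background, 0)
  ir <- ir / sum(ir)
  tgrid <- (seq_len(nch) - 1) * h$dt_ps
  R <- td_reflectance(rho, tgrid - t0_ps, props)
  m <- nextn(2 * nch, 2)
  cv <- Re(fft(fft(c(ir, rep(0, m - nch))) * fft(c(R, rep(0, m - nch))),
               inverse = TRUE)) / m
  shape <- pmax(cv[seq_len(nch)], 0)
  mu <- N_target * shape / sum(shape) + background
  dtof(if (sample) rpois(nch, mu) else mu,
       dt_ps = h$dt_ps, T_rep_ps = h$T_rep_ps,
       acq_time_s = acq_time_s, wavelength_nm = props$wavelength,
       rho_cm = rho)
}

# semi-infinite fluence Green's function (image-source pair) between two
# points at depths z1, z2 and lateral separation rl; t in ps, lengths in cm
.g_fluence <- function(t_ps, rl, z1, z2, props) {
  v <- .C_CM_PS / props$n
  D <- 1 / (3 * props$musp)
  zb <- 2 * fresnel_A(props$n) * D
  out <- numeric(length(t_ps))
  pos <- t_ps > 0
  t <- t_ps[pos]
  s <- 4 * D * v * t
  d2 <- rl^2 + (z1 - z2)^2
  d2i <- rl^2 + (z1 + z2 + 2 * zb)^2
  out[pos] <- v * (pi * s)^(-1.5) *
    (exp(-d2 / s) - exp(-d2i / s)) * exp(-props$mua * v * t)
  out
}

#' Simulate a movable-inclusion gated scan (Born approximation)
#'
#' First-order absorption perturbation: the reflectance change caused by a
#' point-like inclusion of strength `dmua_v` (delta mua x volume) is the
#' time convolution of the semi-infinite fluence Green's functions
#' source -> inclusion and inclusion -> detector. Gate counts for the
#' perturbed and reference (no-inclusion) medium are Poisson-sampled over
#' repetitions, ready for the contrast/CNR/selectivity statistics.
#'
#' Geometry: source at the origin, detector at `(rho, 0, 0)` on the
#' surface; the inclusion sits at `(x, 0, z)` (depth z > 0, cm inputs in
#' mm for coordinates).
#'
#' @param props background medium [optical_props()]
#' @param rho source-detector distance, cm
#' @param z_mm,x_mm inclusion coordinates, mm; give a vector for the
#'   scanned coordinate and a scalar for the fixed one (z-scan: `x_mm`
#'   defaults to the midpoint `rho/2`; x-scan: fix `z_mm`)
#' @param dmua_v inclusion strength, cm^-1 cm^3 (default 0.17, a
#'   conventional equivalent-perturbation value; `0` gives zero contrast
#'   exactly). Strengths beyond ~1 leave the perturbative regime and
#'   trigger a warning.
#' @param gates a [gate_spec()] on the DTOF axis (default 500 ps gates over
#'   0-4000 ps)
#' @param N_per_rep expected total reference counts per repetition
#' @param n_rep repetitions (default 10)
#' @param dt_ps channel width, ps
#' @param seed optional seed
#' @return list: `coord` (scanned coordinate values, mm), `gates`,
#'   `counts` (pos x gate x rep array), `ref_counts` (gate x rep),
#'   `expected` and `expected_ref` (noiseless per-gate means)
#' @export
simulate_inclusion_scan <- function(props, rho, z_mm = seq(0, 30, 2),
                                    x_mm = NULL, dmua_v = 0.17,
                                    gates = gate_spec_regular(0, 4000, 500),
                                    N_per_rep = 1e6, n_rep = 10,
                                    dt_ps = 9.77, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dmua_v < 0) stop("dmua_v must be >= 0")
  if (dmua_v > 1) warning("dmua_v beyond the perturbative regime")
  scan_x <- length(z_mm) == 1 && !is.null(x_mm) && length(x_mm) > 1
  if (is.null(x_mm)) x_mm <- rho / 2 * 10       # midpoint, mm
  coord <- if (scan_x) x_mm else z_mm
  t_max <- max(gates$stop)
  nch <- ceiling(t_max / dt_ps)
  tg <- (seq_len(nch) - 1) * dt_ps
  z0 <- 1 / props$musp

  R0 <- td_reflectance(rho, tg, props)
  h_ref <- dtof(R0 / sum(R0) * N_per_rep, dt_ps = dt_ps,
                T_rep_ps = nch * dt_ps)
  Nk_ref_mu <- gate_counts(h_ref, gates)
  scale <- N_per_rep / sum(R0)

  # Relative Born contrast: conv(Gs, Gd) * dt / G_sd is dimensionless once
  # multiplied by dmua_v (cm^2); integrating the inclusion over all space
  # recovers the absorption derivative -d ln R = mua * v * t exactly.
  Gsd <- .g_fluence(tg, rho, z0, z0, props)
  m <- nextn(2 * nch, 2)
  pert_gates <- function(xi_mm, zi_mm) {
    xi <- xi_mm / 10; zi <- max(zi_mm / 10, 1e-3)
    Gs <- .g_fluence(tg, abs(xi), z0, zi, props)
    Gd <- .g_fluence(tg, abs(rho - xi), zi, z0, props)
    cv <- Re(fft(fft(c(Gs, rep(0, m - nch))) * fft(c(Gd, rep(0, m - nch))),
                 inverse = TRUE)) / m
    relp <- numeric(nch)
    okg <- Gsd > max(Gsd) * 1e-12
    relp[okg] <- dmua_v * cv[seq_len(nch)][okg] * dt_ps / Gsd[okg]
    # exponentiated Born (time-resolved microscopic Beer-Lambert): equal to
    # first order, exact for a whole-space change, keeps counts positive
    Rp <- R0 * exp(-relp)
    hp <- dtof(Rp * scale, dt_ps = dt_ps, T_rep_ps = nch * dt_ps)
    gate_counts(hp, gates)
  }

  ng <- nrow(gates); np <- length(coord)
  expected <- matrix(0, np, ng)
  for (i in seq_len(np)) {
    expected[i, ] <- if (scan_x) pert_gates(coord[i], z_mm)
                     else pert_gates(x_mm, coord[i])
  }
  counts <- array(rpois(np * ng * n_rep, rep(expected, n_rep)),
                  dim = c(np, ng, n_rep))
  ref_counts <- matrix(rpois(ng * n_rep, rep(Nk_ref_mu, n_rep)),
                       ng, n_rep)
  list(coord = coord, scan = if (scan_x) "x" else "z", gates = gates,
       counts = counts, ref_counts = ref_counts,
       expected = expected, expected_ref = Nk_ref_mu)
}

# laterally integrated Born sensitivity kernel K(z, t): relative reflectance
# change per unit (dmua * dz) from a uniformly perturbed plane at depth z.
# Built from the closed-form lateral convolution of the two image-source
# Gaussians; integrating K over all depths recovers the absorption
# derivative mua -> -d ln R = v * t.
.born_plane_kernel <- function(t_ps, rho, z_cm, props) {
  v <- .C_CM_PS / props$n
  D <- 1 / (3 * props$musp)
  z0 <- 1 / props$musp
  zb <- 2 * fresnel_A(props$n) * D
  n <- length(t_ps)
  dt <- t_ps[2] - t_ps[1]
  a <- 4 * D * v * t_ps          # cm^2 (0 at t=0 handled below)
  a[t_ps <= 0] <- NA
  Zs <- outer(a, z_cm, function(aa, zz)
    exp(-(zz - z0)^2 / aa) - exp(-(zz + z0 + 2 * zb)^2 / aa))
  P <- Zs / sqrt(pi * a)         # n x nz ; 1D z-propagator with images
  P[is.na(P)] <- 0
  # The lateral 2D convolution of the two Gaussians depends only on the
  # total time t = t1 + t2 (variance 4Dv t), so the kernel factorizes:
  # K(z, t) = lat(t) * conv_t[P(., z), P(., z)](t) * v^2 * dt
  m <- nextn(2 * n, 2)
  PF <- mvfft(rbind(P, matrix(0, m - n, length(z_cm))))
  conv_t <- Re(mvfft(PF * PF, inverse = TRUE)) / m
  lat <- numeric(n)
  pos <- t_ps > 0
  lat[pos] <- exp(-rho^2 / (4 * D * v * t_ps[pos]) -
                    props$mua * v * t_ps[pos]) /
    (pi * 4 * D * v * t_ps[pos])
  sweep(conv_t[seq_len(n), , drop = FALSE], 1, lat * v^2 * dt, `*`)
}

#' Expected gated counts for a uniformly perturbed layer (Born)
#'
#' First-order sensitivity of the gated reflectance to an absorption change
#' applied uniformly to a depth slab (`z_from_mm` to `z_to_mm`), from the
#' laterally integrated product of semi-infinite Green's functions. Used to
#' compute the depth-selectivity statistics for bilayer media without a
#' layered time-domain forward model.
#'
#' @param props background medium [optical_props()]
#' @param rho source-detector distance, cm
#' @param z_from_mm,z_to_mm slab boundaries, mm (use a large `z_to_mm`,
#'   e.g. 60, for the semi-infinite bottom compartment)
#' @param dmua absorption change in the slab, 1/cm
#' @param gates a [gate_spec()]
#' @param N_total expected reference counts
#' @param dt_ps channel width
#' @param nz depth quadrature points in the slab
#' @return list: `N_k` (perturbed gate counts), `N_k_ref`, `gates`
#' @export
simulate_layer_scan <- function(props, rho, z_from_mm, z_to_mm, dmua,
                                gates = gate_spec_regular(0, 4000, 500),
                                N_total = 1e6, dt_ps = 9.77, nz = 40) {
  t_max <- max(gates$stop)
  nch <- ceiling(t_max / dt_ps)
  tg <- (seq_len(nch) - 1) * dt_ps
  zg <- seq(z_from_mm, min(z_to_mm, 80), length.out = nz) / 10   # cm
  dz <- zg[2] - zg[1]
  K <- .born_plane_kernel(tg, rho, zg, props)
  Gsd <- .g_fluence(tg, rho, 1 / props$musp, 1 / props$musp, props)
  relp <- numeric(nch)
  okg <- Gsd > max(Gsd) * 1e-12
  ksum <- rowSums(K) * dz
  # trapezoid end-weights
  ksum <- ksum - 0.5 * (K[, 1] + K[, nz]) * dz
  relp[okg] <- dmua * ksum[okg] / Gsd[okg]
  R0 <- td_reflectance(rho, tg, props)
  scale <- N_total / sum(R0)
  h_ref <- dtof(R0 * scale, dt_ps = dt_ps, T_rep_ps = nch * dt_ps)
  # exponentiated Born: exact in the whole-space limit, first-order
  # equivalent for small dmua, and strictly positive
  hp <- dtof(R0 * exp(-relp) * scale, dt_ps = dt_ps,
             T_rep_ps = nch * dt_ps)
  list(N_k = gate_counts(hp, gates), N_k_ref = gate_counts(h_ref, gates),
       gates = gates, relp = relp, t_ps = tg)
}
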