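# Fitting the correlation-diffusion model to measured g2 curves.

#' Fit a g2 curve for the Brownian diffusion coefficient and beta
#'
#' Least-squares fit of `1 + beta |g1(tau; DB)|^2` (semi-infinite
#' correlation-diffusion g1, effective Brownian motion) to a measured
#' intensity autocorrelation. Weights are uniform by default; optionally a
#' shot-noise (Koppel-type) variance model can supply lag-dependent weights.
#' The fit range runs from the smallest lag to the lag where `g2 - 1` drops
#' below 1% of the fitted beta, iterated once.
#'
#' @param curve a `corr_curve`
#' @param rho source-detector distance, cm
#' @param props an [optical_props()] of the medium at the DCS wavelength
#' @param wavelength_nm DCS wavelength (default 785)
#' @param weights `"uniform"` or a numeric vector of per-lag weights
#' @param opts list: `DB_init` (cm^2/s) and `beta_init` override the
#'   closed-form initialization; `tail_frac` (default 0.01) sets the fit
#'   range cutoff as a fraction of beta
#' @return object of class `dcs_fit`: `DB` (= BFI, cm^2/s), `beta`, `gof`
#'   (RMS residual), `fit_lag_range_s`, `converged`
#' @export
fit_g2 <- function(curve, rho, props, wavelength_nm = 785,
                   weights = "uniform", opts = list()) {
  .assert(inherits(curve, "corr_curve"), "curve must be a corr_curve")
  o <- utils::modifyList(list(DB_init = NULL, beta_init = NULL,
                              tail_frac = 0.01, maxit = 500), opts)
  ok <- is.finite(curve$g2)
  tau <- curve$lag_s[ok]; y <- curve$g2[ok]
  .assert(length(tau) >= 10, "need at least 10 finite lags")
  k0 <- 2 * pi * props$n / (wavelength_nm * 1e-7)

  # initialization: beta from the first 3 lags, DB from the 1/e lag of
  # g2 - 1 via the single-exponential approximation of the g1 decay
  beta0 <- if (!is.null(o$beta_init)) o$beta_init else
    max(min(mean(y[1:3]) - 1, 1), 1e-3)
  DB0 <- o$DB_init
  if (is.null(DB0)) {
    D <- 1 / (3 * props$musp)
    z0 <- 1 / props$musp
    zb <- 2 * fresnel_A(props$n) * D
    r1 <- sqrt(rho^2 + z0^2)
    K0 <- sqrt(props$mua / D)
    i_e <- which(y - 1 < beta0 / exp(1))[1]
    tau_e <- if (is.na(i_e)) tau[length(tau)] else tau[max(i_e, 2)]
    Ke <- K0 + 0.5 / r1
    DB0 <- max((Ke^2 - K0^2) * D / (2 * props$musp * k0^2 * tau_e), 1e-12)
  }

  wvec <- if (identical(weights, "uniform")) rep(1, length(tau)) else {
    .assert(length(weights) == length(curve$g2), "weights length mismatch")
    weights[ok]
  }

  fit_once <- function(sel) {
    obj <- function(p) {
      DB <- exp(p[1]); beta <- exp(p[2])
      if (beta > 1) return(1e12)
      g1 <- g1_semi_infinite(tau[sel], rho, props,
                             dynamics_params(DB, beta = min(beta, 1),
                                             k0 = k0))
      sum(wvec[sel] * (1 + beta * g1^2 - y[sel])^2)
    }
    optim(c(log(DB0), log(min(beta0, 0.999))), obj, method = "Nelder-Mead",
          control = list(maxit = o$maxit, reltol = 1e-12))
  }

  sel <- rep(TRUE, length(tau))
  f1 <- fit_once(sel)
  beta1 <- exp(f1$par[2])
  g1f <- g1_semi_infinite(tau, rho, props,
                          dynamics_params(exp(f1$par[1]), beta = 0.5,
                                          k0 = k0))
  cut <- which(beta1 * g1f^2 < o$tail_frac * beta1)[1]
  if (!is.na(cut) && cut > 10) sel <- seq_along(tau) <= cut
  f2 <- fit_once(sel)
  DB <- exp(f2$par[1]); beta <- min(exp(f2$par[2]), 1)
  structure(list(DB = DB, beta = beta,
                 gof = sqrt(f2$value / sum(wvec[sel])),
                 fit_lag_range_s = range(tau[sel]),
                 converged = f2$convergence == 0),
            class = "dcs_fit")
}

#' @export
print.dcs_fit <- function(x, ...) {
  cat(sprintf("dcs_fit: DB = %.3e cm^2/s, beta = %.3f, rms = %.2e%s\n",
              x$DB, x$beta, x$gof,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Shot-noise (Koppel-type) variance model for g2 estimates
#'
#' Approximate variance of a photon-correlation estimate at lag tau for a
#' single-exponential-like decay with coherence beta, mean count rate and
#' integration time: `Var[g2(tau)] ~ (1 + beta e^(-tau/tauc))^2 /
#' (n_bar^2 N_bins)` plus the photon-pair shot term `(1 + beta) /
#' (n_bar^2 N_bins)`, with `n_bar` the mean counts per bin and `N_bins` the
#' number of bins in the window. Used for optional fit weighting and as the
#' comparison curve of the DCS noise characterization.
#'
#' @param tau_s lag grid, s
#' @param rate_hz mean count rate, Hz
#' @param T_s integration time, s
#' @param bin_s correlator bin width per lag, s (vector or scalar)
#' @param beta coherence factor
#' @param tauc_s decay time of g2 - 1, s
#' @return vector of variances of g2 at each lag
#' @export
g2_noise_model <- function(tau_s, rate_hz, T_s, bin_s, beta, tauc_s) {
  nbar <- rate_hz * bin_s
  nbins <- T_s / bin_s
  gdec <- exp(-tau_s / tauc_s)
  ((1 + beta * gdec)^2 + (1 + beta * gdec) / pmax(nbar, 1e-300)) / nbins
}
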