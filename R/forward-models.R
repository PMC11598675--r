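# Analytic photon-migration forward models: time-domain diffuse reflectance
# and field autocorrelation (correlation diffusion equation), both for the
# extrapolated-boundary semi-infinite geometry, plus the two-layer g1.

# Fresnel mismatch factor A(n) (internal-reflection parameter of the
# extrapolated boundary z_b = 2 A D), standard polynomial approximation.
fresnel_A <- function(n) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

#' Time-domain diffuse reflectance of a semi-infinite medium
#'
#' Extrapolated-boundary solution of the time-dependent diffusion equation:
#' an isotropic source at depth `z0 = 1/musp` and its negative image mirrored
#' about the extrapolated boundary `z = -z_b`, `z_b = 2 A D`, with
#' `D = 1/(3 musp)` and `A` from the Fresnel reflection mismatch for the
#' medium refractive index. Reflectance is obtained from Fick's law at the
#' physical surface. Values are on an arbitrary common scale (per unit area
#' and time); only ratios and shapes matter downstream.
#'
#' @param rho source-detector distance, cm (> 0)
#' @param t_ps time grid in ps, strictly increasing; values <= 0 map to 0
#' @param props an [optical_props()]
#' @return numeric vector of reflectance values (>= 0), same length as `t_ps`
#' @export
td_reflectance <- function(rho, t_ps, props) {
  .assert(inherits(props, "optical_props"), "props must be optical_props")
  .assert(rho > 0, "rho must be > 0")
  .assert(all(diff(t_ps) > 0), "t grid must be strictly increasing")
  v <- .C_CM_PS / props$n            # cm/ps
  D <- 1 / (3 * props$musp)          # cm
  z0 <- 1 / props$musp
  zb <- 2 * fresnel_A(props$n) * D
  out <- numeric(length(t_ps))
  pos <- t_ps > 0
  t <- t_ps[pos]
  s <- 4 * D * v * t                 # cm^2
  geom <- z0 * exp(-z0^2 / s) + (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / s)
  out[pos] <- 0.5 * (4 * pi * D * v)^(-1.5) * t^(-2.5) *
    exp(-props$mua * v * t - rho^2 / s) * geom
  out
}

# dynamic absorption mu_a + (1/3) musp k0^2 <dr^2(tau)> with <dr^2> = 6 DB tau
.mua_dynamic <- function(props, dyn, tau_s) {
  props$mua + 2 * props$musp * dyn$k0^2 * dyn$DB * tau_s
}

#' Field autocorrelation g1 for a semi-infinite medium
#'
#' Solution of the correlation diffusion equation for a homogeneous
#' semi-infinite medium with effective Brownian motion
#' (mean-square displacement `6 DB tau`): the CW diffusion Green's function
#' evaluated at the tau-dependent absorption
#' `mua(tau) = mua + (1/3) musp k0^2 6 DB tau`, normalized to `g1(0) = 1`.
#'
#' @param tau_s lag grid in seconds, non-negative, increasing
#' @param rho source-detector distance, cm
#' @param props an [optical_props()]
#' @param dyn a [dynamics_params()] (`DB` in cm^2/s, `k0` in 1/cm)
#' @return numeric vector g1(tau) in `[0, 1]`, non-increasing, g1(0) = 1
#' @export
g1_semi_infinite <- function(tau_s, rho, props, dyn) {
  .assert(inherits(props, "optical_props"), "props must be optical_props")
  .assert(inherits(dyn, "dynamics_params"), "dyn must be dynamics_params")
  .assert(all(tau_s >= 0), "tau must be >= 0")
  .assert(dyn$DB >= 0, "DB must be >= 0")
  G <- .g1_semi_unnorm(tau_s, rho, props, dyn)
  G0 <- .g1_semi_unnorm(0, rho, props, dyn)
  pmin(pmax(G / G0, 0), 1)
}

.g1_semi_unnorm <- function(tau_s, rho, props, dyn) {
  D <- 1 / (3 * props$musp)
  z0 <- 1 / props$musp
  zb <- 2 * fresnel_A(props$n) * D
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  K <- sqrt(.mua_dynamic(props, dyn, tau_s) / D)
  (exp(-K * r1) / r1 - exp(-K * r2) / r2) / (4 * pi * D)
}

#' Field autocorrelation g1 for a two-layer medium
#'
#' Correlation diffusion solution for a slab of thickness `d` over a
#' semi-infinite bottom layer, assembled in spatial-frequency (Hankel) space
#' with per-layer dynamic absorption and inverted numerically by
#' Gauss-Legendre quadrature. Node count is doubled until g1 changes by less
#' than `tol` at every lag.
#'
#' @param tau_s lag grid in seconds
#' @param medium a [layered_medium()] with exactly two layers
#' @param tol absolute convergence tolerance on g1 (default 1e-4)
#' @param max_nodes quadrature-node ceiling before a numerical error is raised
#' @return numeric vector g1(tau), g1(0) = 1, non-increasing
#' @export
g1_two_layer <- function(tau_s, medium, tol = 1e-4, max_nodes = 16384) {
  .assert(inherits(medium, "layered_medium"), "medium must be layered_medium")
  .assert(length(medium$layers) == 2, "exactly two layers supported")
  l1 <- medium$layers[[1]]; l2 <- medium$layers[[2]]
  rho <- medium$rho
  L <- l1$thickness_mm / 10                 # cm
  D1 <- 1 / (3 * l1$props$musp); D2 <- 1 / (3 * l2$props$musp)
  z0 <- 1 / l1$props$musp
  zb <- 2 * fresnel_A(l1$props$n) * D1
  .assert(L > z0, "top layer must be thicker than 1/musp of layer 1")

  # Hankel-space surface fluence for isotropic source at z0 in layer 1,
  # extrapolated boundary at -zb, layer interface at L (stable form, all
  # exponents negative).
  phi_hat <- function(s2, tau) {
    a1 <- sqrt((.mua_dynamic(l1$props, l1$dyn, tau)) / D1 + s2)
    a2 <- sqrt((.mua_dynamic(l2$props, l2$dyn, tau)) / D2 + s2)
    El <- exp(-2 * a1 * (L - z0))
    EL <- exp(-2 * a1 * (L + zb))
    num <- D1 * a1 * (1 + El) + D2 * a2 * (1 - El)
    den <- D1 * a1 * (1 + EL) + D2 * a2 * (1 - EL)
    (1 - exp(-2 * a1 * zb)) * exp(-a1 * z0) / (2 * D1 * a1) * num / den
  }

  smax <- 35 / z0
  eval_with <- function(nn) {
    gl <- pracma::gaussLegendre(nn, 0, smax)
    s <- gl$x; w <- gl$w
    J <- besselJ(s * rho, 0)
    s2 <- s^2
    G <- vapply(tau_s, function(tt) sum(w * s * J * phi_hat(s2, tt)),
                numeric(1))
    G0 <- sum(w * s * J * phi_hat(s2, 0))
    G / G0
  }
  n_nodes <- 512
  g_prev <- eval_with(n_nodes)
  last_change <- Inf
  repeat {
    n_nodes <- n_nodes * 2
    if (n_nodes > max_nodes)
      stop(sprintf(paste0("two-layer Hankel inversion did not converge: ",
                          "max |change| %.2e > tol %.2e at %d nodes"),
                   last_change, tol, n_nodes / 2), call. = FALSE)
    g_cur <- eval_with(n_nodes)
    last_change <- max(abs(g_cur - g_prev))
    if (last_change < tol) break
    g_prev <- g_cur
  }
  pmin(pmax(g_cur, 0), 1)
}

#' Siegert relation
#'
#' `g2 = 1 + beta * |g1|^2` for Gaussian-statistics light with coherence
#' factor beta.
#'
#' @param g1 field autocorrelation values
#' @param beta coherence factor in (0, 1]
#' @return intensity autocorrelation values g2
#' @export
siegert <- function(g1, beta) {
  .assert(beta > 0 && beta <= 1, "beta must be in (0, 1]")
  1 + beta * Mod(g1)^2
}
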