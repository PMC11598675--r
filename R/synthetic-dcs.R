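# Speckle-field photon-stream synthesis with a prescribed g1.

#' Approximate a completely monotone g1 by a sum of exponentials
#'
#' Non-negative least squares (lsqnonneg) fit of
#' `g1(tau) ~ sum_k c2_k exp(-lambda_k tau)` on a logarithmic lag grid, with
#' weights renormalized so that the mixture is exactly 1 at tau = 0. The
#' mixture is the exact autocorrelation of the Ornstein-Uhlenbeck field
#' sampler used by [simulate_speckle_tags()].
#'
#' @param g1_fun function of tau (s) returning g1 values
#' @param tau_max_s largest lag that must be represented, s
#' @param K number of candidate decay rates (log-spaced)
#' @param tau_min_s smallest lag represented (default `tau_max_s * 1e-4`)
#' @return list with `lambda` (1/s), `c2` (weights, sum 1), `max_err`
#'   (max abs deviation over the fit grid)
#' @export
g1_expmix <- function(g1_fun, tau_max_s, K = 12, tau_min_s = tau_max_s * 1e-4) {
  tau <- c(0, exp(seq(log(tau_min_s), log(tau_max_s), length.out = 80)))
  b <- g1_fun(tau)
  .assert(all(diff(b) <= 1e-9), "g1 must be non-increasing")
  # include a non-decaying (lambda = 0) term so that static media and
  # plateaus of g1 are represented exactly
  lam <- c(0, 1 / exp(seq(log(tau_min_s / 2), log(tau_max_s * 2),
                          length.out = K - 1)))
  A <- exp(-outer(tau, lam))
  # weight the tau = 0 row heavily to pin the normalization
  w <- c(50, rep(1, length(tau) - 1))
  fit <- pracma::lsqnonneg(A * w, b * w)
  c2 <- fit$x
  keep <- c2 > 0
  c2 <- c2[keep]; lam <- lam[keep]
  c2 <- c2 / sum(c2)
  err <- max(abs(drop(exp(-outer(tau, lam)) %*% c2) - b))
  list(lambda = lam, c2 = c2, max_err = err)
}

#' Synthesize photon tag streams with a prescribed field autocorrelation
#'
#' Generates complex Gaussian speckle fields whose autocorrelation equals
#' the target g1 (through an exponential-mixture Ornstein-Uhlenbeck
#' construction advanced exactly between photon candidates), sums
#' `M = round(1/beta)` independent speckle intensities to realize the
#' coherence factor, and draws photons by thinning a homogeneous Poisson
#' candidate process. The estimated g2 of the output matches
#' `1 + beta_eff |g1|^2` within statistical error.
#'
#' @param g1_fun target g1 as a function of tau in seconds (completely
#'   monotone); build one from the physics models, e.g.
#'   `function(tau) g1_semi_infinite(tau, rho, props, dyn)`
#' @param rate_hz mean detected count rate per channel, Hz
#' @param duration_s stream duration, s
#' @param beta requested coherence factor; realized as `1/M` with
#'   `M = round(1/beta)` summed speckles (the exact value is recorded)
#' @param n_channels number of independent detection channels
#' @param seed optional integer seed (`set.seed`) for bit-reproducibility
#' @param tau_max_s largest lag that must be faithful (default 20 ms)
#' @param cand_factor candidate-rate multiplier for the thinning bound;
#'   intensities above `cand_factor` times the mean are clipped
#'   (probability ~1e-4 at the default 6 for two summed speckles)
#' @return list with `streams` (list of [tag_stream()]), `beta_eff`,
#'   `mixture` (the exponential mixture used)
#' @export
simulate_speckle_tags <- function(g1_fun, rate_hz, duration_s, beta = 0.5,
                                  n_channels = 1, seed = NULL,
                                  tau_max_s = 20e-3, cand_factor = 6) {
  .assert(rate_hz * duration_s >= 1e3,
          "need at least ~1e3 expected photons")
  .assert(beta > 0 && beta <= 1, "beta must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  M <- max(1L, as.integer(round(1 / beta)))
  mix <- g1_expmix(g1_fun, tau_max_s)
  streams <- lapply(seq_len(n_channels), function(chan) {
    cseed <- floor(runif(1) * 2^31) * 2^21 + floor(runif(1) * 2^21)
    tt <- .speckle_tags_cpp(duration_s, rate_hz, mix$lambda, mix$c2, M,
                            cand_factor, cseed)[[1]]
    tag_stream(.make_strict(tt), channel = chan, duration_s = duration_s)
  })
  list(streams = streams, beta_eff = 1 / M, mixture = mix)
}

# resolve rare picosecond collisions by nudging duplicates forward
.make_strict <- function(t) {
  while (anyDuplicated(t)) {
    d <- duplicated(t)
    t[d] <- t[d] + 1
    t <- sort(t)
  }
  t
}

# internal: one channel, several thinning rates sharing the same field
# realization (used by the DCS noise scan); returns list of time vectors
.speckle_multi_rate <- function(g1_mix, rates_hz, duration_s, M,
                                cand_factor = 6) {
  cseed <- floor(runif(1) * 2^31) * 2^21 + floor(runif(1) * 2^21)
  .speckle_tags_cpp(duration_s, rates_hz, g1_mix$lambda, g1_mix$c2, M,
                    cand_factor, cseed)
}
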