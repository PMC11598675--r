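---
title: "Models and methods behind nirsdcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirsdcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsdcs)
```

`nirsdcs` models a hybrid diffuse-optics instrument that combines
time-domain near-infrared spectroscopy (TD NIRS: picosecond laser pulses,
time-correlated single-photon counting, distributions of times of flight)
with diffuse correlation spectroscopy (DCS: a long-coherence CW laser, photon
time tags, intensity autocorrelations). This vignette documents the physical
models, the estimators, the numerical choices, and what the synthetic
generators do and do not emulate.

## Forward models

**Time-domain diffuse reflectance.** `td_reflectance()` implements the
extrapolated-boundary solution of the time-dependent diffusion equation for
a homogeneous semi-infinite medium: an isotropic point source at depth
$z_0 = 1/\mu_s'$ and a negative image mirrored about the extrapolated
boundary at $z = -z_b$, $z_b = 2AD$, $D = 1/(3\mu_s')$, with the
internal-reflection parameter $A(n)$ from the standard Fresnel-mismatch
polynomial. Reflectance follows from Fick's law at the surface:

$$
R(\rho, t) \propto t^{-5/2}
e^{-\mu_a v t - \rho^2/(4 D v t)}
\left[ z_0 e^{-z_0^2/(4Dvt)} + (z_0 + 2 z_b) e^{-(z_0+2z_b)^2/(4Dvt)} \right].
$$

Absorption factorizes exactly, $R(t;\mu_a) = R(t;0)\,e^{-\mu_a v t}$, which
the tests assert at machine precision. The speed of light in the medium is
$v = c/n$ with a single configurable refractive index ($n = 1.4$ for
tissue, $1.33$ for water-based phantoms); higher-order transport models
(P3, radiative transfer, Monte Carlo) are out of scope.

**Correlation diffusion.** For dynamic media the normalized field
autocorrelation `g1_semi_infinite()` evaluates the same CW Green's function
at the lag-dependent absorption
$\mu_a(\tau) = \mu_a + \tfrac13 \mu_s' k_0^2 \,6 D_B \tau$
(effective Brownian motion, mean-square displacement $6 D_B \tau$,
$k_0 = 2\pi n/\lambda$). The blood-flow index is reported as
$\mathrm{BFI} = \alpha D_B$ with $\alpha \equiv 1$: the two factors are not
separable in a homogeneous fit, so $D_B$ and BFI are used interchangeably.
`siegert()` maps field to intensity correlations, $g_2 = 1 + \beta |g_1|^2$.

**Two-layer medium.** `g1_two_layer()` assembles the slab-over-half-space
solution in spatial-frequency (Hankel) space with per-layer dynamic
absorption and inverts it by Gauss–Legendre quadrature (nodes from
`pracma::gaussLegendre`). The quadrature doubles its node count until g1
changes by less than `1e-4` at every lag (raising a numerical error with
diagnostics past 16384 nodes), and the integrand is written with strictly
negative exponents so large spatial frequencies cannot overflow. The
homogeneous limit reproduces the semi-infinite curve within 1%, which is a
standing test.

**Chromophores.** `beer_invert()` solves the 2x2 linear system
$\mu_a(\lambda) = E(\lambda)\,[\mathrm{HbO_2}, \mathrm{HHb}]^T$ and derives
$\mathrm{tHb}$ and $\mathrm{StO_2}$. The extinction table
(`inst/extdata/extinction_hb.csv`, natural-log units of
cm$^{-1}\mu M^{-1}$ at 685/785/830 nm) is compiled from standard literature
tabulations and is deliberately a replaceable input file, since sources
differ at the few-percent level. Water and lipid background absorption are
excluded by default; a fixed per-wavelength offset can be supplied.

## DTOF analysis

`fit_dtof()` minimizes the Poisson deviance between the measured histogram
and $A \cdot (\mathrm{IRF} \circledast R)(t - t_0)$ on the native 9.77 ps
channel grid (discrete linear convolution of the background-subtracted,
area-normalized IRF via FFT). Poisson deviance rather than Gaussian least
squares is used because the information about $\mu_a$ is concentrated in the
low-count tail. Choices that the instrument literature leaves open, and the
defaults adopted here:

* **Fit range**: from the channel at 80% of peak on the rising edge to 1%
  of peak on the falling edge. The range is selected on a lightly smoothed
  (5-channel moving average) copy of the curve so that single-channel
  Poisson fluctuations do not randomize the range at low counts; the fit
  itself uses the raw counts.
* **Background**: mean over a pre-peak window (first 10% of the axis,
  clipped to the pre-rise region), subtracted and clipped at zero.
* **$t_0$**: a free nuisance delay, default bounds $\pm 500$ ps. A
  `t0_fixed` option performs the 3-parameter fit when the instrumental
  delay is calibrated separately. The free-$t_0$ fit is the default
  because a monitoring instrument cannot assume a stable delay.
* **Optimizer**: Nelder–Mead on $(\log\mu_a, \log\mu_s', \log A, t_0)$
  with one restart; convergence is declared when the restart no longer
  moves the deviance. On noiseless self-generated curves the fit returns
  the generating parameters to better than 0.1%, and a Cramér–Rao analysis
  (numeric Fisher information of the same model) shows the Monte-Carlo
  spread attains the bound, i.e. the estimator is statistically efficient.

The per-channel width (9.77 ps) and the default laser period (12.5 ns,
80 MHz class; only the channel width is fixed by the hardware description)
live in the configuration. Differential-nonlinearity correction of DTOFs is
available in principle but off by default, since DNL artifacts sit outside
the range of a typical DTOF.

## Software correlator

`multitau_g2()` computes the intensity autocorrelation directly from photon
time tags held as 64-bit integer picoseconds (stored in doubles, exact below
$2^{53}$ ps). Multi-tau binning by integer division: level 0 evaluates lags
$1..m$ at the base bin, every deeper level doubles the bin and evaluates
lags $m/2+1..m$. Defaults: 200 ns base bin, $m = 16$, 20 octaves (lags
~200 ns–20 ms), chosen to resolve both phantom and tissue decays at 1.5 and
2.5 cm. The estimator uses *symmetric normalization* — the pair count at lag
$j$ is divided by the mean rates restricted to the first $B-j$ and last
$B-j$ bins of the window — which suppresses finite-window bias. Only
complete bins inside the window enter; photons at window boundaries belong
to the window containing their timestamp. The C++ kernel sweeps occupied
bins with two pointers, so the cost is $O(\mathrm{levels}\times m \times
N)$ per curve. Correctness is pinned by an exact (1e-12) comparison against
an independently coded dense-binned correlator and by a type-I control:
homogeneous Poisson input yields $g_2 \equiv 1$ within sampling error.

`windowed_g2()` tiles a stream into contiguous windows (30 ms windows give
the 33 Hz sampling used for pulsatile flow), `average_curves()` forms the
count-rate-weighted mean of $g_2 - 1$ across detectors,
`median_filter_curves()` applies the 5-sample pointwise moving median used
before fitting, and `g2_variance_stat()` is the root-sum-of-variances noise
figure of repeated curves.

`fit_g2()` does weighted least squares of $1 + \beta |g_1(\tau; D_B)|^2$,
uniform weights by default with an optional Koppel-type shot-noise variance
model (`g2_noise_model()`) for lag-dependent weighting. Initialization is
closed-form ($\beta$ from the first three lags; $D_B$ from the $1/e$ lag of
$g_2-1$ through a single-exponential approximation), and the fit range runs
from the smallest lag to where $g_2 - 1$ falls below 1% of the fitted
$\beta$, iterated once.

## Synthetic instrument

**IRF.** `make_irf()` draws Poisson counts around a Gaussian core convolved
with a double-exponential tail (the falling-edge shape typical of silicon
photomultipliers), a flat signal-proportional background, and an optional
delayed secondary-reflection replica. Defaults: 200 ps FWHM, tail constants
120/600 ps with weights 0.08/0.02, background 0.1% of total counts.

**DTOF.** `simulate_dtof()` scales the IRF-convolved reflectance so that the
expected total equals the requested counts and draws per-channel Poisson
counts; `sample = FALSE` returns the noiseless expectation for
inverse-crime-free oracle tests.

**Speckle photon streams.** `simulate_speckle_tags()` synthesizes a complex
Gaussian field with a prescribed autocorrelation. The target $g_1$ is first
approximated by a non-negative exponential mixture
($g_1(\tau) \approx \sum_k c_k^2 e^{-\lambda_k \tau}$, fitted with
`pracma::lsqnonneg` on a logarithmic lag grid, a $\lambda = 0$ term included
so static media are exact; residuals are below ~$10^{-3}$ for
correlation-diffusion curves). Each component is realized as an independent
complex Ornstein–Uhlenbeck process, which can be advanced *exactly* across
an arbitrary gap $\Delta$:
$z \leftarrow e^{-\lambda\Delta} z + \sqrt{c^2(1 - e^{-2\lambda\Delta})/2}
\,(\mathcal N + i\mathcal N)$. This was chosen over FFT spectral coloring
because the field then only needs evaluating at *photon candidate times*:
photons are drawn by thinning a homogeneous Poisson candidate process at
`cand_factor` (default 6) times the requested rate, accepting with
probability proportional to the instantaneous summed-speckle intensity.
Intensities above the candidate bound are clipped with probability
~$10^{-4}$ for two summed speckles, a negligible distortion. The coherence
factor is realized by summing $M = \mathrm{round}(1/\beta)$ independent
speckle intensities; the exact $\beta_{\mathrm{eff}} = 1/M$ is recorded.
Randomness comes from an internal xoshiro256++ generator seeded from R's
RNG, so `set.seed()` makes every stream bit-reproducible. Closure tests:
the estimated $g_2$ of generated streams matches
$1 + \beta_{\mathrm{eff}}|g_1|^2$, fitted $(D_B, \beta)$ are unbiased
within simulation error at $\geq 10^5$ photons, and the static
($D_B = 0$) limit passes a Poisson dispersion test.

**Perturbed media.** `simulate_inclusion_scan()` models the movable
absorbing inclusion by first-order (Born) perturbation theory: the relative
reflectance change is the time convolution of the semi-infinite fluence
Green's functions source→inclusion and inclusion→detector, divided by the
direct source→detector Green's function, times the inclusion strength
$\Delta\mu_a V$ (default 0.17 cm$^{-1}$cm$^3$, a conventional
equivalent-perturbation magnitude; the real inclusion's size and contrast
are not published, so absolute contrasts are simulator-relative).
`simulate_layer_scan()` integrates the laterally-closed-form version of the
same kernel over a depth slab to produce bilayer contrasts without a layered
TD forward model (which stays out of scope). Both use the *exponentiated*
Born term $R \to R_0 e^{-\mathrm{relp}}$: identical to first order, exact
in the whole-space limit (where it reduces to the absorption
factorization), and strictly positive. A standing test integrates the slab
kernel over all depths and recovers the absorption derivative
$-\mathrm{d}\ln R/\mathrm{d}\mu_a = v t$ to a few percent. Because the model
is first order in $\Delta\mu_a$, the selectivity ratio is
$\Delta\mu_a$-independent — the saturation of contrast at large
perturbations seen in real phantoms is not reproduced.

**In-vivo-like time courses.** `simulate_occlusion_dataset()` builds
synchronized DTOF pairs and tag streams whose ground truth follows the
stepped-occlusion phenomenology: venous occlusion raises HbO$_2$ and HHb in
proportion (saturation constant) with a mild flow decrease; arterial
occlusion swaps HbO$_2$ for HHb at constant tHb and drops the flow to 20%;
release produces a gamma-shaped hyperemic overshoot. Trajectories are
piecewise-linear ramps with 5 s one-pole smoothing; after release the
hemoglobin pools recover with a 15 s constant while flow rebounds with a
3 s constant (reactive hyperemia is fast). All magnitudes live in
`occlusion_spec()` and none is claimed to be a measured value.
`simulate_pulsatile_bfi()` modulates $D_B(t)$ with a cardiac fundamental
plus $1/i$-weighted harmonics, generated per 30 ms window.

## Pipelines

`run_occlusion_pipeline()` follows the processing order used for cuff
protocols: per sample and wavelength a homogeneous semi-infinite DTOF fit;
Beer inversion of the $\mu_a$ pair; DCS curves of all detectors at a
distance averaged, 5-sample moving *median* over the curve sequence
*before* fitting; and a 5-sample moving *average* on all output traces at
the end. A test demonstrates the order matters: a single corrupted curve is
fully absorbed by the pre-fit median filter but corrupts the BFI trace when
the filter is skipped. Non-converged fits propagate as flagged gaps, never
interpolated. Output samples are stamped at window centers.

`welch_psd()` averages Hamming-windowed modified periodograms (20 s windows,
50% overlap by default) into a one-sided density; each segment has its mean
removed, and the integrated density matches the signal variance within the
~5% window bias (Parseval test). No installed package provides Welch's
method, so it is the one standard estimator implemented by hand here.

## Protocol statistics and their conventions

* Contrast uses the natural logarithm, $C_k = -\ln(N_k/N_{k,\mathrm{ref}})$
  (a base-10 flag exists); $N_k$ is summed over repetitions while the CNR
  denominator is the sample (n−1) standard deviation of per-repetition log
  counts — the two are deliberately different reductions.
* The selectivity operation returns the literal ratio
  $S_k = C_{\mathrm{UP}}/C_{\mathrm{DOWN}}$. Note that "higher depth
  selectivity" for late gates and larger distances corresponds to this
  ratio *decreasing* (the deep-layer contrast grows relative to the
  superficial one); the ordering tests are phrased accordingly.
* Noise scans fit ordinary least squares on $(\log_{10} N, \log_{10}
  \mathrm{CV})$ and interpolate threshold crossings on the fitted line in
  log-log space, where the trend is linear.
* Stability: reference = mean of the final 10% of samples; warm-up = first
  entry into the ±1% band that is never left again (band and reference
  window are configurable; no published criterion exists).
* All standard deviations are sample (n−1) throughout.

## Problem sizes and statistical expectations

The shipped characterization studies use sizes chosen so a complete run is
comfortable on a single CPU while keeping the estimates meaningful:

* TD-NIRS noise scan: 12 count levels from $10^4$ to $10^6$, 10 repetitions
  each. With 10 repetitions the sampling error of each CV estimate is
  $\approx 1/\sqrt{2(n-1)} = 24\%$, which bounds the achievable log-log
  $R^2$ near 0.92 over a two-decade span; the slope estimate is much more
  stable ($-0.5$ to $-0.6$; the free $t_0$ and amplitude make the observed
  slope slightly steeper than the pure Poisson $-1/2$).
* DCS noise scan: per-channel rates 10/20/40/80 kHz, 100 windows of 1 s,
  4 averaged channels, $\beta = 0.5$, phantom $D_B = 10^{-8}$ cm$^2$/s
  (a typical room-temperature Intralipid value; the field realization is
  shared across thinning rates, which is exact per rate and bounds the
  cost by the largest rate). The simulated instrument is strictly
  photon/speckle-noise limited — no dark counts, afterpulsing, beta drift
  or probe instability — so its CV at a given rate is a *lower* bound on
  what hardware achieves, and the 5% CV crossing lands at a lower rate
  than for a physical system.
* Occlusion/pulsatility tests run shortened protocols (tens of seconds at
  1–33 Hz) with reduced counts; they probe orderings and signatures, not
  absolute hardware figures.

What passing these tests shows about real data is limited accordingly: the
generators emulate Poisson photon statistics, speckle statistics, diffusion
shapes and protocol phenomenology, but not detector afterpulsing inside the
DTOF, pile-up, DNL coupling, motion artifacts, layered TD propagation, or
physiological variability beyond the programmed trajectories.

## Degenerate inputs and numerics

Validation errors are raised for non-physical optical properties, empty
streams and histograms, windows longer than the data, gates outside the
histogram support, even median lengths, zero repetition variance in the CNR
denominator, and zero lower-layer contrast in the selectivity ratio.
Non-convergence is flagged, never silent. Gate boundaries snap to the
nearest channel edge with half-open intervals so partitions conserve
counts exactly; the DNL curve is normalized to mean exactly 1; picosecond
timestamp collisions in generated streams (probability ~$10^{-7}$ per
photon) are resolved by nudging duplicates forward one picosecond.
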