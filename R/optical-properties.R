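#' Optical properties of a turbid medium
#'
#' Container for the absorption coefficient, reduced scattering coefficient,
#' refractive index and wavelength of a homogeneous turbid medium.
#'
#' @param mua absorption coefficient, 1/cm (>= 0)
#' @param musp reduced scattering coefficient, 1/cm (> 0)
#' @param n refractive index (>= 1); 1.4 is a common tissue value, 1.33 for
#'   water-based phantoms
#' @param wavelength wavelength in nm
#' @return object of class `optical_props`
#' @export
optical_props <- function(mua, musp, n = 1.4, wavelength = NA_real_) {
  .assert(is.numeric(mua) && length(mua) == 1 && is.finite(mua) && mua >= 0,
          "mua must be a single finite number >= 0")
  .assert(is.numeric(musp) && length(musp) == 1 && is.finite(musp) && musp > 0,
          "musp must be a single finite number > 0")
  .assert(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1")
  structure(list(mua = mua, musp = musp, n = n, wavelength = wavelength),
            class = "optical_props")
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("optical_props: mua = %.4g /cm, musp = %.4g /cm, n = %.3f, lambda = %s nm\n",
              x$mua, x$musp, x$n,
              if (is.na(x$wavelength)) "?" else format(x$wavelength)))
  invisible(x)
}

#' Dynamical parameters of moving scatterers
#'
#' @param DB effective Brownian diffusion coefficient, cm^2/s (>= 0). The
#'   blood flow index (BFI) is alpha * DB with alpha fixed to 1 here, so DB is
#'   reported interchangeably with BFI.
#' @param beta coherence factor in (0, 1], set by the detection optics
#' @param k0 optical wavenumber in the medium, 1/cm; computed as
#'   `2*pi*n/lambda` when `n` and `wavelength_nm` are given instead
#' @param n,wavelength_nm used to derive `k0` when it is not supplied
#' @return object of class `dynamics_params`
#' @export
dynamics_params <- function(DB, beta = 0.5, k0 = NULL, n = NULL,
                            wavelength_nm = NULL) {
  .assert(is.numeric(DB) && length(DB) == 1 && is.finite(DB) && DB >= 0,
          "DB must be a single finite number >= 0")
  .assert(is.numeric(beta) && length(beta) == 1 && beta > 0 && beta <= 1,
          "beta must be in (0, 1]")
  if (is.null(k0)) {
    .assert(!is.null(n) && !is.null(wavelength_nm),
            "supply k0, or n and wavelength_nm to derive it")
    k0 <- 2 * pi * n / (wavelength_nm * 1e-7)  # nm -> cm
  }
  structure(list(DB = DB, beta = beta, k0 = k0), class = "dynamics_params")
}

#' Layered medium description
#'
#' Ordered list of layers (top first); the last layer is semi-infinite.
#' All layers must share the refractive index.
#'
#' @param layers list of layers, each `list(thickness_mm =, props =, dyn =)`;
#'   the last layer's thickness must be `Inf`
#' @param rho source-detector distance, cm
#' @return object of class `layered_medium`
#' @export
layered_medium <- function(layers, rho) {
  .assert(length(layers) >= 2, "need at least two layers")
  th <- vapply(layers, function(l) l$thickness_mm, numeric(1))
  .assert(is.infinite(th[length(th)]), "last layer must have thickness_mm = Inf")
  .assert(all(th[-length(th)] > 0), "layer thicknesses must be > 0")
  ns <- vapply(layers, function(l) l$props$n, numeric(1))
  .assert(all(abs(ns - ns[1]) < 1e-12), "all layers must share n")
  .assert(rho > 0, "rho must be > 0")
  structure(list(layers = layers, rho = rho), class = "layered_medium")
}

#' Brownian diffusion coefficient from the Einstein relation
#'
#' `DB = kB * T / (6 * pi * eta * r)` for spherical scatterers of radius `r`
#' in a fluid of viscosity `eta` at absolute temperature `T`. Useful to
#' predict the expected diffusion coefficient of liquid phantoms (e.g.
#' Intralipid-based, with glycerol added to raise the viscosity).
#'
#' @param T_abs absolute temperature, K
#' @param eta dynamic viscosity, Pa s
#' @param r particle radius, m
#' @param kB Boltzmann constant, J/K
#' @return diffusion coefficient in m^2/s (multiply by 1e4 for cm^2/s)
#' @export
einstein_db <- function(T_abs, eta, r, kB = 1.380649e-23) {
  .assert(all(c(T_abs, eta, r, kB) > 0), "all arguments must be positive")
  kB * T_abs / (6 * pi * eta * r)
}

#' Chromophore extinction basis
#'
#' A wavelengths x chromophores matrix of specific absorption coefficients in
#' 1/(cm uM), natural-log convention, so that `mua = E %*% conc` for
#' concentrations in uM. The default table ships with the package
#' (compiled literature values for HbO2 and HHb at 685, 785 and 830 nm) and
#' can be replaced by any CSV with columns `wavelength_nm, HbO2, HHb`.
#'
#' @param wavelengths_nm wavelengths to extract (rows), default c(685, 830)
#' @param file optional path to a replacement extinction CSV
#' @param water_mua optional fixed water absorption per wavelength, 1/cm,
#'   subtracted from measured mua before inversion (default 0)
#' @return object of class `chromophore_basis` with fields `E` (matrix),
#'   `wavelengths_nm`, `water_mua`
#' @export
chromophore_basis <- function(wavelengths_nm = c(685, 830), file = NULL,
                              water_mua = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "extinction_hb.csv", package = "nirsdcs")
  tab <- read.csv(file, comment.char = "#")
  .assert(all(c("wavelength_nm", "HbO2", "HHb") %in% names(tab)),
          "extinction table needs columns wavelength_nm, HbO2, HHb")
  idx <- match(wavelengths_nm, tab$wavelength_nm)
  .assert(!anyNA(idx), "requested wavelength not in extinction table")
  E <- as.matrix(tab[idx, c("HbO2", "HHb")])
  rownames(E) <- as.character(wavelengths_nm)
  .assert(all(E > 0), "extinction entries must be positive")
  if (is.null(water_mua)) water_mua <- rep(0, length(wavelengths_nm))
  .assert(length(water_mua) == length(wavelengths_nm),
          "water_mua must match wavelengths")
  structure(list(E = E, wavelengths_nm = wavelengths_nm,
                 water_mua = water_mua),
            class = "chromophore_basis")
}

#' Invert Beer's law for hemoglobin concentrations
#'
#' Solves the linear system `mua = E %*% c` for the chromophore
#' concentrations and derives total hemoglobin `tHb = HbO2 + HHb` and tissue
#' oxygen saturation `StO2 = 100 * HbO2 / tHb`.
#'
#' @param mua vector of absorption coefficients (1/cm), one per basis
#'   wavelength (default order 685, 830 nm)
#' @param basis a [chromophore_basis()]
#' @return list with `HbO2`, `HHb`, `tHb` (uM) and `StO2` (%); `StO2` errors
#'   when `tHb` is zero
#' @export
beer_invert <- function(mua, basis = chromophore_basis()) {
  .assert(length(mua) == nrow(basis$E), "mua length must match basis rows")
  d <- det(basis$E)
  .assert(is.finite(d) && abs(d) > 1e-12, "singular extinction basis")
  conc <- solve(basis$E, mua - basis$water_mua)
  HbO2 <- conc[1]; HHb <- conc[2]
  tHb <- HbO2 + HHb
  if (abs(tHb) < .Machine$double.eps * 16)
    if (abs(HbO2) < 1e-12 && abs(HHb) < 1e-12) {
      return(list(HbO2 = 0, HHb = 0, tHb = 0,
                  StO2 = NA_real_, StO2_defined = FALSE))
    } else stop("StO2 undefined: tHb = 0", call. = FALSE)
  list(HbO2 = unname(HbO2), HHb = unname(HHb), tHb = unname(tHb),
       StO2 = unname(100 * HbO2 / tHb), StO2_defined = TRUE)
}

#' Forward Beer's law
#'
#' @param HbO2,HHb concentrations in uM
#' @param basis a [chromophore_basis()]
#' @return vector of mua (1/cm) per basis wavelength
#' @export
beer_forward <- function(HbO2, HHb, basis = chromophore_basis()) {
  drop(basis$E %*% c(HbO2, HHb)) + basis$water_mua
}
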