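# Two-pore extravasation primitives. These R functions are the reference
# implementation of the flux arithmetic; the compiled ODE core evaluates the
# same expressions from terms precomputed here (one set per organ per run).

#' Hindered-diffusion factor for a cylindrical pore
#'
#' Product of the steric partition coefficient `(1 - lambda)^2` and the
#' centre-line Renkin hydrodynamic hindrance polynomial
#' `1 - 2.1044*lambda + 2.089*lambda^3 - 0.948*lambda^5`, with
#' `lambda = r_solute / r_pore`. Returns 0 for `lambda >= 1` (full steric
#' exclusion).
#'
#' @param lambda Solute-to-pore radius ratio (>= 0).
#' @return Dimensionless hindrance in `[0, 1]`.
#' @export
hindrance_diffusion <- function(lambda) {
  stopifnot(all(lambda >= 0))
  h <- (1 - lambda)^2 *
    (1 - 2.1044 * lambda + 2.089 * lambda^3 - 0.948 * lambda^5)
  h[lambda >= 1] <- 0
  pmax(h, 0)
}

#' Osmotic reflection coefficient of a cylindrical pore
#'
#' Curry's hindered-convection closure: `sigma = 1 - W` with
#' `W = (2*Phi - Phi^2) * (1 - lambda^2 / 3)` and `Phi = (1 - lambda)^2`.
#' `sigma -> 0` as `lambda -> 0` (free convection) and `sigma = 1` at
#' `lambda >= 1`.
#'
#' @param lambda Solute-to-pore radius ratio (>= 0).
#' @return Reflection coefficient in `[0, 1]`.
#' @export
reflection_coefficient <- function(lambda) {
  stopifnot(all(lambda >= 0))
  lam <- pmin(lambda, 1)
  phi <- (1 - lam)^2
  w <- (2 * phi - phi^2) * (1 - lam^2 / 3)
  pmin(pmax(1 - w, 0), 1)
}

#' Pore exchange terms for one organ
#'
#' Computes the permeability-surface products, reflection coefficients and
#' Peclet numbers of the small- and large-pore pathways of one organ for a
#' given solute. Permeability follows restricted diffusion through cylindrical
#' pores: `PS = D_free * (A0/dx) * H(lambda)` with the organ-scale pore
#' area-to-path ratio `A0/dx = SA_cap * pore_area_fraction /
#' membrane_thickness`, split between pore classes by `A0_frac_L`. Peclet
#' numbers are `Pe = J * (1 - sigma) / PS` per class.
#'
#' @param organ One row of `physiology$organs` (data.frame row or list).
#' @param solute List/`compound_parameters` with `solute_radius` (nm) and
#'   `D_free` (cm2/s).
#' @param pore_area_fraction Fraction of capillary surface that is pore area.
#' @param membrane_thickness_cm Endothelial path length, cm.
#' @return List of class `pore_exchange_terms` with `PS_S`, `PS_L` (L/h),
#'   `sigma_S`, `sigma_L`, `Pe_S`, `Pe_L`, `J_S`, `J_L` (L/h).
#' @export
pore_exchange_terms <- function(organ, solute,
                                pore_area_fraction = 8e-4,
                                membrane_thickness_cm = 5e-5) {
  r <- solute$solute_radius
  stopifnot(r > 0, solute$D_free > 0)
  lam_S <- r / organ$r_S
  lam_L <- r / organ$r_L
  # cm2 * 1 / cm = cm; D [cm2/s] * A0/dx [cm] = cm3/s -> L/h (x 3.6)
  a0_dx <- organ$SA_cap * pore_area_fraction / membrane_thickness_cm
  to_l_h <- 3.6e-3 * 1000  # cm3/s -> L/h
  ps_unit <- solute$D_free * a0_dx * to_l_h
  PS_S <- ps_unit * (1 - organ$A0_frac_L) * hindrance_diffusion(lam_S)
  PS_L <- ps_unit * organ$A0_frac_L * hindrance_diffusion(lam_L)
  sigma_S <- reflection_coefficient(lam_S)
  sigma_L <- reflection_coefficient(lam_L)
  Pe_S <- if (PS_S > 0) organ$J_S * (1 - sigma_S) / PS_S else 0
  Pe_L <- if (PS_L > 0) organ$J_L * (1 - sigma_L) / PS_L else 0
  structure(list(PS_S = PS_S, PS_L = PS_L,
                 sigma_S = sigma_S, sigma_L = sigma_L,
                 Pe_S = Pe_S, Pe_L = Pe_L,
                 J_S = organ$J_S, J_L = organ$J_L),
            class = "pore_exchange_terms")
}

# Pe / (exp(Pe) - 1) with the analytic Pe -> 0 limit of 1.
peclet_factor <- function(pe) {
  ifelse(abs(pe) < 1e-10, 1, pe / expm1(pe))
}

#' Two-pore transcapillary solute flux
#'
#' Net vascular-to-interstitial flux (nmol/h) of one organ:
#' `fu * sum_pore [ J*(1 - sigma)*C_v + PS*(C_v - C_i/K_iv) * Pe/(e^Pe - 1) ]`
#' summed over the large and small pore classes. Positive values move drug
#' from plasma into the interstitium.
#'
#' @param C_v,C_i Vascular and interstitial concentrations, nmol/L.
#' @param terms A [pore_exchange_terms()] object.
#' @param J_L,J_S Large/small-pore fluid flows, L/h (default: from `terms`).
#' @param fu Fraction unbound in plasma.
#' @param K_iv Interstitial-to-plasma partition coefficient.
#' @return Flux in nmol/h.
#' @export
two_pore_flux <- function(C_v, C_i, terms, J_L = terms$J_L, J_S = terms$J_S,
                          fu = 1, K_iv = 0.94) {
  stopifnot(C_v >= 0, C_i >= 0, fu >= 0, fu <= 1, K_iv > 0)
  grad <- C_v - C_i / K_iv
  fl <- J_L * (1 - terms$sigma_L) * C_v +
    terms$PS_L * grad * peclet_factor(terms$Pe_L)
  fs <- J_S * (1 - terms$sigma_S) * C_v +
    terms$PS_S * grad * peclet_factor(terms$Pe_S)
  fu * (fl + fs)
}

#' Liver-specific permeability flux
#'
#' The additional liver extravasation pathway acting on top of the two-pore
#' exchange: `fu * P_liver * SA_liver * (C_pls - C_int/Kp)`, converted to
#' nmol/h (`cm/min * cm2 = cm3/min`; 1 cm3/min = 0.06 L/h).
#'
#' @param C_pls,C_int Liver vascular plasma and interstitial concentrations,
#'   nmol/L.
#' @param P_liver Permeability, cm/min.
#' @param SA_liver Liver capillary surface area, cm2.
#' @param fu Fraction unbound.
#' @param Kp Partition coefficient.
#' @return Flux in nmol/h (positive: plasma -> interstitium).
#' @export
liver_permeability_flux <- function(C_pls, C_int, P_liver, SA_liver,
                                    fu = 1, Kp = 0.94) {
  stopifnot(C_pls >= 0, C_int >= 0, P_liver >= 0, SA_liver > 0,
            fu >= 0, fu <= 1, Kp > 0)
  fu * P_liver * SA_liver * 0.06 * (C_pls - C_int / Kp)
}
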