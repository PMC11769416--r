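# Parameter containers. All user-facing values keep the units of the source
# literature (per-minute endosomal rates, micromolar pools); conversion to the
# internal nmol / nmol/L / h basis happens once, in assemble_model().

#' Compound-specific PK-PD parameter set
#'
#' @param name Compound identifier.
#' @param molecular_weight g/mol.
#' @param solute_radius Hydrodynamic radius, nm.
#' @param fu Fraction unbound in plasma.
#' @param Kp Plasma-interstitial partition coefficient (dimensionless).
#' @param ka First-order subcutaneous absorption rate, 1/h.
#' @param F_bio Subcutaneous bioavailability (fraction). May be accompanied by
#'   dose-specific overrides in `F_override`.
#' @param F_override Named numeric vector of dose-specific bioavailabilities,
#'   names are doses in mg/kg (e.g. `c("25" = 0.35)`); empty by default.
#' @param k_endosome Endosomal degradation/escape rate for siRNA, 1/h.
#' @param kon_RISC Antisense-RISC association rate, L/nmol/h.
#' @param stabilization `"ESC"` or `"ADV-ESC"` chemistry tag.
#' @param pd A [pd_parameters()] object.
#' @param D_free Free aqueous diffusion coefficient, cm2/s. If `NA`, estimated
#'   from the solute radius by the Stokes-Einstein relation at 37 C.
#' @return A validated list of class `compound_parameters`.
#' @export
compound_parameters <- function(name = "generic",
                                molecular_weight = 16000,
                                solute_radius = 1.0,
                                fu = 1.0,
                                Kp = 0.94,
                                ka = 0.84,
                                F_bio = 1.0,
                                F_override = numeric(0),
                                k_endosome = 0.012,
                                kon_RISC = 0.00027,
                                stabilization = "ESC",
                                pd = pd_parameters(),
                                D_free = NA_real_) {
  if (is.na(D_free)) D_free <- stokes_einstein_diffusivity(solute_radius)
  p <- structure(list(
    name = name, molecular_weight = molecular_weight,
    solute_radius = solute_radius, fu = fu, Kp = Kp, ka = ka,
    F_bio = F_bio, F_override = F_override, k_endosome = k_endosome,
    kon_RISC = kon_RISC, stabilization = stabilization, pd = pd,
    D_free = D_free
  ), class = "compound_parameters")
  validate_parameters(p)
  p
}

#' Global (non-liver) disposition parameters
#'
#' Defaults are the fitted global values of the mouse model: unspecific
#' endosomal uptake/recycling in all non-liver organs (a kidney-specific
#' pair), and pseudo-first-order ribonuclease degradation applied in plasma
#' and all non-liver tissues. `P_liver` is the additional liver endothelial
#' permeability acting on top of the two-pore exchange.
#'
#' @param k_uptake,k_recycling Endosomal uptake/recycling, 1/min.
#' @param k_kid_uptake,k_kid_recycling Kidney-specific pair, 1/min.
#' @param k_RNase Ribonuclease degradation rate constant, 1/h per umol/L of
#'   RNase (combined as `k_RNase * [RNase]`).
#' @param RNase_kidney,RNase_remaining RNase concentrations, umol/L.
#' @param P_liver Liver endothelial permeability, cm/min.
#' @return A validated list of class `global_parameters`.
#' @export
global_parameters <- function(k_uptake = 20.87,
                              k_recycling = 0.000077,
                              k_kid_uptake = 68.2,
                              k_kid_recycling = 0.00039,
                              k_RNase = 0.00012,
                              RNase_kidney = 1.17,
                              RNase_remaining = 0.17,
                              P_liver = 0.02) {
  p <- structure(as.list(environment()), class = "global_parameters")
  validate_parameters(p)
  p
}

#' ASGPR target-mediated disposition parameters
#'
#' Receptor pool, binding, internalization, endosomal processing and
#' cytoplasmic escape for the hepatocyte asialoglycoprotein receptor system.
#' Concentration-like parameters are on the liver interstitial volume basis.
#'
#' @param R_tot Total receptor density, umol/L.
#' @param k_on GalNAc-ASGPR association, L/nmol/h.
#' @param k_off Dissociation, 1/h.
#' @param k_deg Surface receptor degradation, 1/h.
#' @param k_deg_R Endosomal receptor degradation, 1/h.
#' @param k_syn Receptor synthesis, umol/L/h (consistency `k_syn = R_tot*k_deg`
#'   is enforced to 1% by validation).
#' @param k_int Complex internalization, 1/h.
#' @param k_cle Endosomal GalNAc cleavage, 1/h.
#' @param k_rec Receptor recycling endosome -> surface, 1/h.
#' @param f_escape Fraction of endosomal siRNA escaping to the cytoplasm.
#' @param k_deg_C Cytoplasmic siRNA degradation, 1/h.
#' @return A validated list of class `asgpr_parameters`.
#' @export
asgpr_parameters <- function(R_tot = 5.23,
                             k_on = 0.53,
                             k_off = 1.53,
                             k_deg = 1.52,
                             k_deg_R = 1.53,
                             k_syn = R_tot * k_deg,
                             k_int = 5.14,
                             k_cle = 1.32,
                             k_rec = 13.8,
                             f_escape = 0.01,
                             k_deg_C = 0.10) {
  p <- structure(as.list(environment()), class = "asgpr_parameters")
  validate_parameters(p)
  p
}

#' RISC formation parameters
#'
#' @param RISC_tot Total Ago2/RISC pool, umol/L (hepatocyte intracellular
#'   volume basis).
#' @param koff_RISC Antisense-RISC dissociation, 1/h.
#' @param k_DR Degradation rate of the loaded RISC complex, 1/h (Ago2 is
#'   regenerated; the antisense strand is degraded).
#' @return A validated list of class `risc_parameters`.
#' @export
risc_parameters <- function(RISC_tot = 0.0003,
                            koff_RISC = 1e-7,
                            k_DR = 0.0033) {
  p <- structure(as.list(environment()), class = "risc_parameters")
  validate_parameters(p)
  p
}

#' Indirect-response pharmacodynamic parameters
#'
#' @param Smax Maximum stimulation of mRNA degradation (dimensionless).
#' @param SC50 RISC-loaded siRNA concentration at half-maximal stimulation,
#'   nmol/L (liver tissue basis).
#' @param gamma Power coefficient linking relative mRNA to protein synthesis.
#' @param k_deg_mRNA,k_deg_protein Turnover degradation rates, 1/h.
#' @param mRNA0,Protein0 Baselines, percent (fixed at 100).
#' @return A validated list of class `pd_parameters`.
#' @export
pd_parameters <- function(Smax = 13.1,
                          SC50 = 3.52,
                          gamma = 1.77,
                          k_deg_mRNA = 0.06,
                          k_deg_protein = 0.05,
                          mRNA0 = 100,
                          Protein0 = 100) {
  p <- structure(as.list(environment()), class = "pd_parameters")
  validate_parameters(p)
  p
}

#' Stokes-Einstein estimate of the free diffusion coefficient
#'
#' `D = kB*T / (6*pi*eta*r)` at 37 C in water (eta = 6.9e-4 Pa s), returned
#' in cm2/s. Used when a compound does not supply a measured diffusivity.
#'
#' @param radius_nm Hydrodynamic radius in nm.
#' @return Diffusion coefficient, cm2/s.
#' @export
stokes_einstein_diffusivity <- function(radius_nm) {
  stopifnot(radius_nm > 0)
  kB <- 1.380649e-23            # J/K
  T_K <- 310.15                 # 37 C
  eta <- 6.9e-4                 # Pa s, water at 37 C
  r_m <- radius_nm * 1e-9
  d_m2_s <- kB * T_K / (6 * pi * eta * r_m)
  d_m2_s * 1e4                  # cm2/s
}

#' Validate a parameter object
#'
#' @param p One of the parameter classes of this package.
#' @return Invisibly `TRUE`; errors describe the violated constraint.
#' @export
validate_parameters <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  pos <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
  if (inherits(p, "compound_parameters")) {
    chk(pos(p$molecular_weight) && p$molecular_weight > 0, "molecular_weight must be > 0")
    chk(pos(p$solute_radius) && p$solute_radius > 0, "solute_radius must be > 0")
    chk(pos(p$fu) && p$fu <= 1, "fu must be in [0, 1]")
    chk(pos(p$F_bio) && p$F_bio <= 1, "F_bio must be in [0, 1]")
    chk(length(p$F_override) == 0 || (pos(p$F_override) && all(p$F_override <= 1)),
        "F_override entries must be in [0, 1]")
    chk(pos(p$Kp) && p$Kp > 0, "Kp must be > 0")
    chk(pos(c(p$ka, p$k_endosome, p$kon_RISC)), "rates must be >= 0")
    chk(pos(p$D_free) && p$D_free > 0, "D_free must be > 0")
    validate_parameters(p$pd)
  } else if (inherits(p, "global_parameters")) {
    chk(pos(unlist(p)), "global disposition parameters must be >= 0")
  } else if (inherits(p, "asgpr_parameters")) {
    chk(pos(unlist(p)), "ASGPR parameters must be >= 0")
    chk(p$f_escape <= 1, "f_escape must be in [0, 1]")
    if (p$R_tot > 0 && p$k_deg > 0) {
      chk(abs(p$k_syn - p$R_tot * p$k_deg) / (p$R_tot * p$k_deg) < 0.01,
          "k_syn inconsistent with R_tot * k_deg (> 1%)")
    }
  } else if (inherits(p, "risc_parameters")) {
    chk(pos(unlist(p)), "RISC parameters must be >= 0")
  } else if (inherits(p, "pd_parameters")) {
    chk(pos(p$Smax), "Smax must be >= 0")
    chk(pos(p$SC50) && p$SC50 > 0, "SC50 must be > 0")
    chk(pos(p$gamma), "gamma must be >= 0")
    chk(pos(c(p$k_deg_mRNA, p$k_deg_protein)), "turnover rates must be >= 0")
    chk(isTRUE(all.equal(p$mRNA0, 100)) && isTRUE(all.equal(p$Protein0, 100)),
        "baselines are fixed at 100%")
  } else {
    stop("unknown parameter class")
  }
  invisible(TRUE)
}

#' Dose event
#'
#' @param time Administration time, h.
#' @param route `"IV"` or `"SC"`.
#' @param dose Dose in mg/kg.
#' @param body_weight Body weight in kg.
#' @return A list of class `dose_event`.
#' @export
dose_event <- function(time = 0, route = c("SC", "IV"), dose = 1,
                       body_weight = 0.025) {
  route <- toupper(match.arg(toupper(route), c("SC", "IV")))
  stopifnot(time >= 0, dose >= 0, body_weight > 0)
  structure(list(time = time, route = route, dose = dose,
                 body_weight = body_weight), class = "dose_event")
}
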