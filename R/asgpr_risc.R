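# Liver ASGPR target-mediated disposition and RISC kinetics, expressed on a
# concentration basis. These functions document and test the reaction wiring;
# the compiled whole-body core evaluates the same terms on the amount basis
# (multiplying by the relevant liver sub-compartment volumes).

#' Drug-free steady state of the receptor system
#'
#' With no drug, the surface receptor pool settles at
#' `A_free0 = k_syn / k_deg` (equal to `R_tot` by construction) and the
#' endosomal receptor pool at zero.
#'
#' @param asgpr An [asgpr_parameters()] object.
#' @return Named numeric: `A_free0` and `A_endosome0`, umol/L.
#' @export
receptor_initial_state <- function(asgpr) {
  if (asgpr$k_deg == 0 && asgpr$k_syn > 0) {
    stop("no steady state: k_deg = 0 with k_syn > 0")
  }
  a0 <- if (asgpr$k_syn == 0) 0 else asgpr$k_syn / asgpr$k_deg
  c(A_free0 = a0, A_endosome0 = 0)
}

#' TMDD reaction derivatives (concentration basis)
#'
#' Receptor binding, internalization, endosomal processing and cytoplasmic
#' escape of the GalNAc-siRNA in the liver:
#' surface binding `k_on*D_free*A_free` (reversible, `k_off`), receptor
#' turnover (`k_syn`, `k_deg`), complex internalization (`k_int`) into the
#' endosome, endosomal cleavage (`k_cle`) splitting the complex into free
#' endosomal siRNA and endosomal receptor, receptor recycling (`k_rec`) or
#' degradation (`k_deg_R`), endosomal siRNA exit at `k_endosome` partitioned
#' `f_escape` to the cytoplasm and `1 - f_escape` to degradation, and
#' cytoplasmic degradation `k_deg_C`. All species nmol/L on a common volume
#' basis; `k_syn` is supplied in nmol/L/h on the same basis.
#'
#' @param D_free,A_free,DA,DA_endo,A_endosome,D_endosome,D_cytoplasm Species
#'   concentrations, nmol/L (`DA`: surface complex; `DA_endo`: internalized,
#'   not yet cleaved complex).
#' @param asgpr An [asgpr_parameters()] object (`k_syn` in umol/L/h is
#'   converted to nmol/L/h internally).
#' @param k_endosome Endosomal degradation/escape rate, 1/h.
#' @return Named numeric vector of derivatives (nmol/L/h) for
#'   `dA_free`, `dD_free`, `dDA`, `dDA_endo`, `dA_endosome`, `dD_endosome`,
#'   `dD_cytoplasm`, `dDegraded`.
#' @export
tmdd_derivatives <- function(D_free, A_free, DA, DA_endo = 0, A_endosome = 0,
                             D_endosome = 0, D_cytoplasm = 0,
                             asgpr = asgpr_parameters(),
                             k_endosome = 0.012) {
  if (any(c(D_free, A_free, DA, DA_endo, A_endosome, D_endosome,
            D_cytoplasm) < 0)) {
    stop("negative concentration input")
  }
  ksyn_nM <- asgpr$k_syn * 1000  # umol/L/h -> nmol/L/h
  bind <- asgpr$k_on * D_free * A_free
  unbind <- asgpr$k_off * DA
  internal <- asgpr$k_int * DA
  cleave <- asgpr$k_cle * DA_endo
  exit <- k_endosome * D_endosome
  c(
    dA_free = ksyn_nM - asgpr$k_deg * A_free - bind + unbind +
      asgpr$k_rec * A_endosome,
    dD_free = -bind + unbind,
    dDA = bind - unbind - internal,
    dDA_endo = internal - cleave,
    dA_endosome = cleave - asgpr$k_rec * A_endosome -
      asgpr$k_deg_R * A_endosome,
    dD_endosome = cleave - exit,
    dD_cytoplasm = asgpr$f_escape * exit - asgpr$k_deg_C * D_cytoplasm,
    dDegraded = (1 - asgpr$f_escape) * exit + asgpr$k_deg_C * D_cytoplasm
  )
}

#' RISC loading derivatives (concentration basis)
#'
#' Saturable loading of the cytoplasmic antisense strand onto the finite Ago2
#' pool: `dC_RISC/dt = kon_RISC*D_cyt*(RISC_tot - C_RISC) - koff_RISC*C_RISC -
#' k_DR*C_RISC`. Binding consumes cytoplasmic drug, dissociation returns it;
#' complex degradation (`k_DR`) regenerates free Ago2 and degrades the
#' antisense strand, keeping the total Ago2 pool at `RISC_tot`.
#'
#' @param D_cytoplasm Cytoplasmic antisense concentration, nmol/L.
#' @param C_RISC Loaded RISC concentration, nmol/L.
#' @param risc A [risc_parameters()] object (`RISC_tot` in umol/L).
#' @param kon_RISC Association rate, L/nmol/h.
#' @return Named numeric: `dC_RISC`, `dD_cytoplasm`, `dDegraded` (nmol/L/h).
#' @export
risc_derivatives <- function(D_cytoplasm, C_RISC, risc = risc_parameters(),
                             kon_RISC = 0.00027) {
  risc_tot_nM <- risc$RISC_tot * 1000
  if (C_RISC > risc_tot_nM * (1 + 1e-9)) {
    stop("C_RISC exceeds RISC_tot")
  }
  if (D_cytoplasm < 0 || C_RISC < 0) stop("negative concentration input")
  on <- kon_RISC * D_cytoplasm * (risc_tot_nM - C_RISC)
  off <- risc$koff_RISC * C_RISC
  deg <- risc$k_DR * C_RISC
  c(dC_RISC = on - off - deg,
    dD_cytoplasm = -on + off,
    dDegraded = deg)
}
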