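# Whole-body model assembly and simulation. assemble_model() turns parameter
# objects into the flat constant structure consumed by the compiled RHS;
# simulate() integrates the system with event restarts at dose times.

#' State labels of the whole-body model
#'
#' @param physiology A `physiology_table` (for organ names/order).
#' @return Character vector naming every state of the ODE system, in the
#'   internal order.
#' @export
state_labels <- function(physiology = load_physiology()) {
  org <- physiology$organs$organ
  c("depot", "venous", "arterial",
    as.vector(t(outer(org, c("vas", "int", "endo"), paste, sep = "."))),
    "liver.D_int", "liver.A_free", "liver.DA", "liver.DA_endo",
    "liver.A_endo", "liver.D_endo", "liver.D_cyt", "liver.RISC",
    "mRNA", "Protein", "urine", "degraded")
}

#' Assemble the whole-body PBPK-PD ODE system
#'
#' Combines compound, global-disposition, physiology, ASGPR and RISC
#' parameters into a model handle: pore-exchange terms are computed once per
#' organ ([pore_exchange_terms()]), all literature units are converted to the
#' internal nmol / L / h basis (per-minute rates x 60, micromolar pools
#' x 1000), and flow bookkeeping (portal drainage into the liver, lung in
#' series) is resolved.
#'
#' @param compound A [compound_parameters()] object.
#' @param globals A [global_parameters()] object.
#' @param physiology A `physiology_table` from [load_physiology()].
#' @param asgpr An [asgpr_parameters()] object.
#' @param risc A [risc_parameters()] object.
#' @return An object of class `sirna_model` wrapping the parameter structure
#'   passed to the compiled core plus the originating objects.
#' @export
assemble_model <- function(compound = compound_parameters(),
                           globals = global_parameters(),
                           physiology = load_physiology(),
                           asgpr = asgpr_parameters(),
                           risc = risc_parameters()) {
  for (p in list(compound, globals, asgpr, risc)) validate_parameters(p)
  viol <- validate_physiology(physiology)
  if (length(viol)) {
    stop("invalid physiology: ", paste(viol, collapse = "; "))
  }
  org <- physiology$organs
  n <- nrow(org)
  iliver <- match("liver", org$organ)
  ikidney <- match("kidney", org$organ)
  ilung <- match("lung", org$organ)
  if (any(is.na(c(iliver, ikidney, ilung)))) {
    stop("assembly error: physiology must contain liver, kidney and lung")
  }

  terms <- lapply(seq_len(n), function(i) {
    pore_exchange_terms(org[i, ], compound,
                        pore_area_fraction = physiology$pore_area_fraction,
                        membrane_thickness_cm = physiology$membrane_thickness_cm)
  })
  convL <- vapply(terms, function(tt) tt$J_L * (1 - tt$sigma_L), 0)
  convS <- vapply(terms, function(tt) tt$J_S * (1 - tt$sigma_S), 0)
  diffL <- vapply(terms, function(tt) tt$PS_L * peclet_factor(tt$Pe_L), 0)
  diffS <- vapply(terms, function(tt) tt$PS_S * peclet_factor(tt$Pe_S), 0)

  # destination pools: 0 venous, 1 arterial (lung), 2 liver vascular (portal)
  dest <- ifelse(org$drains_to == "portal", 2L, 0L)
  dest[ilung] <- 1L
  if (org$drains_to[iliver] == "portal") {
    stop("assembly error: liver cannot drain to itself")
  }
  portal <- which(dest == 2L)
  Qout <- org$Q_plasma - org$J_lymph
  Qout[ilung] <- physiology$cardiac_plasma_output - org$J_lymph[ilung]
  Qout[iliver] <- org$Q_plasma[iliver] +
    sum(org$Q_plasma[portal] - org$J_lymph[portal]) - org$J_lymph[iliver]

  # per-organ trafficking (1/min -> 1/h) and RNase degradation pseudo-rates
  kup <- rep(globals$k_uptake * 60, n)
  krec <- rep(globals$k_recycling * 60, n)
  kup[ikidney] <- globals$k_kid_uptake * 60
  krec[ikidney] <- globals$k_kid_recycling * 60
  kup[iliver] <- 0
  krec[iliver] <- 0
  kdeg_tis <- rep(globals$k_RNase * globals$RNase_remaining, n)
  kdeg_tis[ikidney] <- globals$k_RNase * globals$RNase_kidney
  kdeg_tis[iliver] <- 0
  kdeg_vas <- rep(globals$k_RNase * globals$RNase_remaining, n)
  kdeg_vas[iliver] <- 0

  par <- list(
    n_org = n, iliver = iliver - 1L, ikidney = ikidney - 1L,
    ilung = ilung - 1L,
    Vvas = org$V_vas, Vint = org$V_int, Vendo = org$V_endo,
    Q = org$Q_plasma, Jlymph = org$J_lymph,
    convL = convL, convS = convS, diffL = diffL, diffS = diffS,
    kup = kup, krec = krec, kdeg_tis = kdeg_tis, kdeg_vas = kdeg_vas,
    Qout = Qout, dest = dest,
    Vven = physiology$V_venous, Vart = physiology$V_arterial,
    Qco = physiology$cardiac_plasma_output,
    fu = compound$fu, Kp = compound$Kp, ka = compound$ka,
    GFR = physiology$GFR,
    PSA_liver = globals$P_liver * org$SA_cap[iliver] * 0.06,  # cm/min*cm2 -> L/h
    kdeg_plasma = globals$k_RNase * globals$RNase_remaining,
    kon = asgpr$k_on, koff = asgpr$k_off, kint = asgpr$k_int,
    kcle = asgpr$k_cle, krecR = asgpr$k_rec, kdegR = asgpr$k_deg_R,
    kdegA = asgpr$k_deg,
    ksyn_amt = asgpr$k_syn * 1000 * org$V_int[iliver],  # umol/L/h -> nmol/h
    kendo = compound$k_endosome, fesc = asgpr$f_escape,
    kdegC = asgpr$k_deg_C,
    konR = compound$kon_RISC, koffR = risc$koff_RISC, kDR = risc$k_DR,
    RISCtot_nM = risc$RISC_tot * 1000,
    Vint_liv = org$V_int[iliver], Vcell_liv = org$V_cell[iliver],
    Vliv_total = org$V_total[iliver],
    Smax = compound$pd$Smax, SC50 = compound$pd$SC50,
    gamma = compound$pd$gamma, kdegm = compound$pd$k_deg_mRNA,
    kdegp = compound$pd$k_deg_protein,
    mRNA0 = compound$pd$mRNA0, Prot0 = compound$pd$Protein0
  )

  structure(list(par = par, compound = compound, globals = globals,
                 physiology = physiology, asgpr = asgpr, risc = risc,
                 labels = state_labels(physiology)),
            class = "sirna_model")
}

#' Initial state of the assembled model
#'
#' Drug-free: all drug amounts zero, the surface ASGPR pool at its synthesis/
#' degradation steady state ([receptor_initial_state()]) converted to an
#' amount on the liver interstitial volume, and mRNA/Protein at 100%.
#'
#' @param model A `sirna_model`.
#' @return Named numeric state vector (nmol; percent for PD states).
#' @export
initial_state <- function(model) {
  y <- setNames(numeric(length(model$labels)), model$labels)
  r0 <- receptor_initial_state(model$asgpr)
  y["liver.A_free"] <- r0[["A_free0"]] * 1000 * model$par$Vint_liv  # umol/L -> nmol
  y["mRNA"] <- model$compound$pd$mRNA0
  y["Protein"] <- model$compound$pd$Protein0
  y
}

#' Apply a dose event to a model state
#'
#' IV boluses add `dose * body_weight / MW` (nmol) to venous plasma; SC doses
#' add the bioavailable fraction `F * dose * body_weight / MW` to the
#' subcutaneous depot (pre-systemic loss is booked at the depot, so the
#' absorbed fraction is exactly `F`). Dose-specific bioavailability overrides
#' (`F_override`, keyed by mg/kg dose) take precedence over the compound `F`.
#'
#' @param state Named state vector (from [initial_state()] or a simulation).
#' @param event A [dose_event()].
#' @param compound A [compound_parameters()] object.
#' @return The updated state vector.
#' @export
apply_dose <- function(state, event, compound) {
  if (event$dose < 0) stop("negative dose")
  amount_nmol <- event$dose * event$body_weight * 1e6 / compound$molecular_weight
  if (event$route == "IV") {
    state["venous"] <- state["venous"] + amount_nmol
  } else {
    f <- compound$F_bio
    key <- as.character(event$dose)
    if (length(compound$F_override) && key %in% names(compound$F_override)) {
      f <- compound$F_override[[key]]
    }
    state["depot"] <- state["depot"] + f * amount_nmol
  }
  state
}

#' Evaluate the model right-hand side
#'
#' Exposes the compiled derivative function for audits and tests.
#'
#' @param model A `sirna_model`.
#' @param state Named state vector.
#' @return Named vector of time derivatives (nmol/h; percent/h for PD).
#' @export
model_rhs <- function(model, state) {
  setNames(.cpp_rhs(as.numeric(state), model$par), model$labels)
}

#' Simulate the whole-body model
#'
#' Integrates the stiff ODE system over `t_grid` with an L-stable Rosenbrock
#' 4(3) method, restarting at every dose time (no interpolation across the
#' dosing discontinuity). Derived observables are computed from the state
#' trajectories: venous plasma concentration (nmol/L and ng/mL), liver and
#' kidney total-tissue concentrations (nmol/L, tissue density 1 g/mL), loaded
#' RISC on the liver tissue volume (nmol/L), and mRNA / Protein (%).
#'
#' @param model A `sirna_model`.
#' @param doses A [dose_event()] or list of them.
#' @param t_grid Strictly increasing output times, h (first element is the
#'   simulation start).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param hmax Maximum step size, h.
#' @param state0 Optional initial state (default [initial_state()]).
#' @return A `sirna_sim` object: `time`, `states` (matrix, one labelled
#'   column per state), `observables` (data.frame), `units`, `model`, `doses`.
#' @export
simulate_model <- function(model, doses, t_grid = seq(0, 1000, by = 1),
                           rtol = 1e-8, atol = 1e-10, hmax = 10,
                           state0 = NULL) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(all(diff(t_grid) > 0))
  t0 <- t_grid[1]
  dose_times <- vapply(doses, `[[`, 0, "time")
  if (length(dose_times) && any(dose_times < t0 | dose_times > max(t_grid))) {
    stop("dose times must lie within the simulation span")
  }
  y <- if (is.null(state0)) initial_state(model) else state0

  # segment boundaries: start, each dose time, end
  bounds <- sort(unique(c(t0, dose_times, max(t_grid))))
  out <- matrix(NA_real_, length(t_grid), length(y),
                dimnames = list(NULL, model$labels))
  # doses exactly at t0 applied before integration
  for (d in doses) if (d$time == t0) y <- apply_dose(y, d, model$compound)
  out_idx_done <- 0L
  if (t_grid[1] == t0) {
    out[1, ] <- y
    out_idx_done <- 1L
  }
  for (b in seq_len(length(bounds) - 1)) {
    a <- bounds[b]; z <- bounds[b + 1]
    seg_t <- t_grid[t_grid > a & t_grid <= z]
    tt <- unique(c(a, seg_t, z))
    traj <- .cpp_integrate(as.numeric(y), tt, model$par,
                           rtol = rtol, atol = atol, hmax = hmax)
    y <- setNames(traj[nrow(traj), ], model$labels)
    if (length(seg_t)) {
      rows <- match(seg_t, tt)
      out[out_idx_done + seq_along(seg_t), ] <- traj[rows, , drop = FALSE]
      out_idx_done <- out_idx_done + length(seg_t)
    }
    for (d in doses) if (d$time == z && z > t0) y <- apply_dose(y, d, model$compound)
  }

  obs <- compute_observables(t_grid, out, model)
  structure(list(time = t_grid, states = out, observables = obs,
                 units = c(plasma = "nmol/L", plasma_ng_ml = "ng/mL",
                           liver = "nmol/L", kidney = "nmol/L",
                           RISC = "nmol/L", mRNA = "%", protein = "%"),
                 model = model, doses = doses),
            class = "sirna_sim")
}

compute_observables <- function(time, states, model) {
  par <- model$par
  org <- model$physiology$organs
  ik <- match("kidney", org$organ)
  kid_cols <- paste0("kidney.", c("vas", "int", "endo"))
  liv_drug <- c("liver.D_int", "liver.DA", "liver.DA_endo", "liver.D_endo",
                "liver.D_cyt", "liver.RISC", "liver.vas")
  plasma <- states[, "venous"] / par$Vven
  data.frame(
    time = time,
    plasma = plasma,
    plasma_ng_ml = plasma * model$compound$molecular_weight / 1000,
    liver = rowSums(states[, liv_drug, drop = FALSE]) / par$Vliv_total,
    kidney = rowSums(states[, kid_cols, drop = FALSE]) / org$V_total[ik],
    RISC = states[, "liver.RISC"] / par$Vliv_total,
    mRNA = states[, "mRNA"],
    protein = states[, "Protein"]
  )
}

#' Total drug amount in a state
#'
#' Sum over every siRNA-containing species: depot, plasma pools, all organ
#' vascular/interstitial/endosomal drug, the liver TMDD drug species
#' (including receptor- and RISC-bound), and the urine and degraded sinks.
#' Receptor-only species are excluded. Used by the mass-balance audits.
#'
#' @param state Named state vector or a `sirna_sim` states matrix row.
#' @return Total drug, nmol.
#' @export
total_drug_amount <- function(state) {
  labs <- names(state)
  drug <- labs[!labs %in% c("liver.A_free", "liver.A_endo", "mRNA", "Protein")]
  sum(state[drug])
}

#' @export
print.sirna_sim <- function(x, ...) {
  cat("<sirna_sim> ", length(x$time), " time points, ",
      ncol(x$states), " states; compound: ", x$model$compound$name, "\n",
      sep = "")
  cat("observables: ", paste(names(x$observables)[-1], collapse = ", "), "\n")
  invisible(x)
}
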