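test_that("dose arithmetic: mg/kg to nmol", {
  cp <- compound_parameters(molecular_weight = 15000)
  m <- assemble_model(compound = cp)
  y <- initial_state(m)
  y1 <- apply_dose(y, dose_event(0, "IV", 1, 0.025), cp)
  expect_equal(y1[["venous"]], 1 * 0.025 * 1e6 / 15000)  # 1.667 nmol
  expect_equal(y1[["venous"]], 1.6667, tolerance = 1e-4)

  cp2 <- compound_parameters(molecular_weight = 15000, F_bio = 0.401)
  y2 <- apply_dose(y, dose_event(0, "SC", 1, 0.025), cp2)
  expect_equal(y2[["depot"]], 0.401 * 1 * 0.025 * 1e6 / 15000)
  expect_equal(y2[["venous"]], 0)

  # dose-specific bioavailability override
  cp3 <- compound_parameters(F_bio = 0.73, F_override = c("25" = 0.4))
  y25 <- apply_dose(y, dose_event(0, "SC", 25, 0.025), cp3)
  expect_equal(y25[["depot"]], 0.4 * 25 * 0.025 * 1e6 / 16000)

  expect_equal(apply_dose(y, dose_event(0, "IV", 0, 0.025), cp), y)
  ev <- dose_event(0, "IV", 1, 0.025); ev$dose <- -1
  expect_error(apply_dose(y, ev, cp), "negative dose")
})

test_that("RHS is a closed flux ledger: total drug is conserved pointwise", {
  m <- aln_model()
  drug <- drug_species(m$labels)
  for (seed in 1:10) {
    y <- random_state(m, seed)
    dy <- model_rhs(m, y)
    expect_true(all(is.finite(dy)))
    # every transfer appears with opposite signs; sinks close the ledger
    expect_lt(abs(sum(dy[drug])), 1e-10 * sum(abs(dy[drug])) + 1e-12)
  }
})

test_that("with all elimination disabled the in-system total is invariant", {
  ph <- mouse_physiology()
  ph$GFR <- 0
  m <- assemble_model(
    compound = compound_parameters(),
    globals = global_parameters(k_RNase = 0),
    physiology = ph,
    asgpr = asgpr_parameters(f_escape = 1, k_deg_C = 0),
    risc = risc_parameters(k_DR = 0)
  )
  drug <- setdiff(drug_species(m$labels), c("urine", "degraded"))
  for (seed in 1:5) {
    dy <- model_rhs(m, random_state(m, seed))
    expect_lt(abs(sum(dy[drug])), 1e-10)
    expect_equal(dy[["urine"]], 0)
    expect_equal(dy[["degraded"]], 0)
  }
})

test_that("fu = 0 confines drug to the circulation", {
  m <- assemble_model(compound = compound_parameters(fu = 0))
  sim <- simulate_model(m, std_dose(1, "IV"), t_grid = seq(0, 48, by = 0.5))
  states <- sim$states
  vas_cols <- c("depot", "venous", "arterial",
                grep("\\.vas$", colnames(states), value = TRUE))
  # plasma RNase degradation still runs at fu = 0; everything else is empty
  other <- setdiff(drug_species(colnames(states)), c(vas_cols, "degraded"))
  expect_lt(max(abs(states[, other])), 1e-10)
  expect_equal(max(states[, "urine"]), 0)
  dose <- 1 * 0.025 * 1e6 / 16000
  expect_equal(rowSums(states[, c(vas_cols, "degraded")]),
               rep(dose, nrow(states)), tolerance = 1e-8)
})

test_that("whole-body mass balance holds along a full simulation", {
  sim <- aln_sim()
  dose <- 0.401 * 1 * 0.025 * 1e6 / 16000
  tot <- apply(sim$states, 1, total_drug_amount)
  expect_lt(max(abs(tot - dose)) / dose, 1e-6)
  # nonnegativity at output times (up to solver tolerance)
  expect_gt(min(sim$states), -1e-9)
})

test_that("zero dose leaves drug at zero and PD at baseline", {
  m <- aln_model()
  sim <- simulate_model(m, std_dose(0), t_grid = seq(0, 500, by = 5))
  expect_equal(max(abs(sim$states[, drug_species(m$labels)])), 0)
  expect_equal(sim$observables$mRNA, rep(100, length(sim$time)), tolerance = 1e-8)
  expect_equal(sim$observables$protein, rep(100, length(sim$time)), tolerance = 1e-8)
})

test_that("dose linearity at low dose, ASGPR saturation at high dose", {
  m <- aln_model()
  tg <- seq(0, 1000, by = 2)
  auc_liver <- function(d) {
    s <- simulate_model(m, std_dose(d), t_grid = tg)
    auc_trapezoid(s$observables$time, s$observables$liver, 0, 1000)
  }
  a1 <- auc_liver(0.01); a2 <- auc_liver(0.02)
  expect_equal(a2 / a1, 2, tolerance = 0.01)
  alo <- auc_liver(1); ahi <- auc_liver(25)
  expect_lt(ahi / 25, alo / 1)
})

test_that("plasma decays much faster than liver tissue", {
  short <- aln_sim_short()
  plasma_t12 <- terminal_half_life(short$time, short$observables$plasma_ng_ml,
                                   tail_fraction = 1 / 3, lloq = 0.01)
  sim <- aln_sim()
  liver_t12 <- elimination_half_life(sim$time, sim$observables$liver)
  expect_lt(plasma_t12, 4)
  expect_gt(liver_t12, 10 * plasma_t12)
})

test_that("solution is tolerance-converged: tighter tolerances move AUC < 0.1%", {
  m <- aln_model()
  tg <- seq(0, 1000, by = 5)
  s1 <- simulate_model(m, std_dose(1), t_grid = tg, rtol = 1e-6, atol = 1e-9)
  s2 <- simulate_model(m, std_dose(1), t_grid = tg, rtol = 1e-8, atol = 1e-11)
  for (ob in c("plasma", "liver", "kidney", "RISC")) {
    a1 <- auc_trapezoid(tg, s1$observables[[ob]], 0, 1000)
    a2 <- auc_trapezoid(tg, s2$observables[[ob]], 0, 1000)
    expect_lt(abs(a1 - a2) / a2, 1e-3, label = paste("AUC convergence", ob))
  }
})

test_that("clearance identity: GFR as sole elimination gives AUC = Dose/CL", {
  ph <- mouse_physiology()
  ph$GFR <- 0.002  # small filtration fraction keeps plasma gradients ~1%
  m <- assemble_model(
    compound = compound_parameters(),
    globals = global_parameters(k_uptake = 0, k_recycling = 0,
                                k_kid_uptake = 0, k_kid_recycling = 0,
                                k_RNase = 0),
    physiology = ph,
    asgpr = asgpr_parameters(R_tot = 0, k_on = 0, k_syn = 0),
    risc = risc_parameters()
  )
  tg <- sort(unique(c(seq(0, 2, by = 0.01), seq(2, 60, by = 0.1),
                      seq(60, 3000, by = 1))))
  sim <- simulate_model(m, std_dose(1, "IV"), t_grid = tg)
  dose <- 1 * 0.025 * 1e6 / 16000
  # essentially everything is eliminated by 3000 h
  expect_gt(sim$states[nrow(sim$states), "urine"] / dose, 0.999)
  kid_vas <- sim$states[, "kidney.vas"] /
    m$physiology$organs$V_vas[m$physiology$organs$organ == "kidney"]
  auc <- auc_trapezoid(tg, kid_vas)
  expect_equal(auc * 1 * 0.002 / dose, 1, tolerance = 0.01)
})

test_that("compiled RHS reproduces the R-level extravasation fluxes", {
  m <- aln_model()
  phys <- m$physiology
  liv <- phys$organs[phys$organs$organ == "liver", ]
  y <- initial_state(m)
  y["liver.vas"] <- 0.5  # nmol; everything else drug-free
  dy <- model_rhs(m, y)
  cvas <- 0.5 / liv$V_vas
  terms <- pore_exchange_terms(liv, m$compound, phys$pore_area_fraction,
                               phys$membrane_thickness_cm)
  f2p <- two_pore_flux(cvas, 0, terms, fu = m$compound$fu, K_iv = m$compound$Kp)
  fp <- liver_permeability_flux(cvas, 0, m$globals$P_liver, liv$SA_cap,
                                fu = m$compound$fu, Kp = m$compound$Kp)
  expect_equal(dy[["liver.D_int"]], f2p + fp, tolerance = 1e-10)
})

test_that("dosing outside the grid span and invalid grids are rejected", {
  m <- aln_model()
  expect_error(simulate_model(m, dose_event(2000, "IV", 1, 0.025),
                              t_grid = seq(0, 100, by = 1)),
               "within the simulation span")
  expect_error(simulate_model(m, std_dose(1), t_grid = c(0, 10, 5)))
})

test_that("repeat dosing restarts integration at each event", {
  m <- aln_model()
  tg <- seq(0, 300, by = 1)
  one <- simulate_model(m, std_dose(1), t_grid = tg)
  two <- simulate_model(m, list(std_dose(1), dose_event(100, "SC", 1, 0.025)),
                        t_grid = tg)
  # identical before the second dose, strictly larger after
  pre <- tg <= 100
  expect_equal(two$observables$liver[pre], one$observables$liver[pre],
               tolerance = 1e-8)
  expect_gt(min(two$observables$liver[tg > 110] - one$observables$liver[tg > 110]), 0)
  dose <- 0.401 * 1 * 0.025 * 1e6 / 16000
  tot <- apply(two$states, 1, total_drug_amount)
  expect_equal(tot[length(tot)], 2 * dose, tolerance = 1e-6)
})
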