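# Shared fixtures, memoized so expensive simulations run once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

mouse_physiology <- function() fixture("phys", function() load_physiology("mouse"))

aln_model <- function() fixture("aln_model", function() model_for_compound("ALN-AT3"))

# reference scenario: 1 mg/kg SC ALN-AT3, 0-1000 h
aln_sim <- function() fixture("aln_sim", function() {
  simulate_model(aln_model(), dose_event(0, "SC", 1, 0.025),
                 t_grid = seq(0, 1000, by = 2))
})

# dense short grid for plasma-phase work
aln_sim_short <- function() fixture("aln_sim_short", function() {
  simulate_model(aln_model(), dose_event(0, "SC", 1, 0.025),
                 t_grid = seq(0, 72, by = 0.5))
})

std_dose <- function(mg_kg = 1, route = "SC") dose_event(0, route, mg_kg, 0.025)

# independent straight-line re-implementations of the hindered-transport
# closures, used as arithmetic oracles against the package functions
oracle_hindrance <- function(lam) {
  if (lam >= 1) return(0)
  phi <- (1 - lam) * (1 - lam)
  renkin <- 1 - 2.1044 * lam + 2.089 * lam^3 - 0.948 * lam^5
  max(phi * renkin, 0)
}

oracle_sigma <- function(lam) {
  if (lam >= 1) return(1)
  phi <- (1 - lam) * (1 - lam)
  1 - (2 * phi - phi * phi) * (1 - lam * lam / 3)
}

# straight-line evaluation of the two-pore flux equation
oracle_two_pore <- function(C_v, C_i, fu, K_iv, J_L, J_S, sig_L, sig_S,
                            PS_L, PS_S, Pe_L, Pe_S) {
  pef <- function(pe) if (abs(pe) < 1e-10) 1 else pe / (exp(pe) - 1)
  fu * (J_L * (1 - sig_L) * C_v + PS_L * (C_v - C_i / K_iv) * pef(Pe_L) +
        J_S * (1 - sig_S) * C_v + PS_S * (C_v - C_i / K_iv) * pef(Pe_S))
}

# fixed-step RK4 for small test ODE systems (independent of the package solver)
rk4 <- function(f, y0, t_end, dt) {
  y <- y0
  t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# random nonnegative model state with plausible magnitudes
random_state <- function(model, seed) {
  set.seed(seed)
  y <- initial_state(model)
  y[] <- stats::runif(length(y), 0, 2)
  y["mRNA"] <- stats::runif(1, 10, 100)
  y["Protein"] <- stats::runif(1, 10, 100)
  # keep loaded RISC within the Ago2 pool
  y["liver.RISC"] <- stats::runif(1) * model$par$RISCtot_nM * model$par$Vcell_liv
  y
}

drug_species <- function(labels) {
  setdiff(labels, c("liver.A_free", "liver.A_endo", "mRNA", "Protein"))
}
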