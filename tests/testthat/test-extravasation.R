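test_that("hindrance and reflection closures match the independent oracle", {
  for (lam in c(0, 0.01, 0.1, 1 / 4.4, 1 / 22.85, 0.5, 0.9, 1, 1.3)) {
    expect_equal(hindrance_diffusion(lam), oracle_hindrance(lam),
                 tolerance = 1e-12, label = paste("H at lambda =", lam))
    expect_equal(reflection_coefficient(lam), oracle_sigma(lam),
                 tolerance = 1e-12, label = paste("sigma at lambda =", lam))
  }
  # limits: free diffusion and full steric exclusion
  expect_equal(hindrance_diffusion(0), 1)
  expect_equal(reflection_coefficient(0), 0)
  expect_equal(hindrance_diffusion(1), 0)
  expect_equal(reflection_coefficient(1), 1)
})

test_that("pore exchange terms: 1 nm solute in 4.4 / 22.85 nm pores", {
  phys <- mouse_physiology()
  muscle <- phys$organs[phys$organs$organ == "muscle", ]
  solute <- list(solute_radius = 1.0,
                 D_free = stokes_einstein_diffusivity(1.0))
  terms <- pore_exchange_terms(muscle, solute,
                               phys$pore_area_fraction,
                               phys$membrane_thickness_cm)
  # small pores hinder more: per unit pore area PS_S < PS_L, sigma_S > sigma_L
  a0dx <- muscle$SA_cap * phys$pore_area_fraction / phys$membrane_thickness_cm
  ps_per_area_S <- terms$PS_S / ((1 - muscle$A0_frac_L) * a0dx)
  ps_per_area_L <- terms$PS_L / (muscle$A0_frac_L * a0dx)
  expect_lt(ps_per_area_S, ps_per_area_L)
  expect_gt(terms$sigma_S, terms$sigma_L)
  # numeric values against the straight-line oracle
  to_l_h <- 3.6
  expect_equal(terms$PS_S,
               solute$D_free * a0dx * to_l_h * (1 - muscle$A0_frac_L) *
                 oracle_hindrance(1 / 4.4), tolerance = 1e-12)
  expect_equal(terms$PS_L,
               solute$D_free * a0dx * to_l_h * muscle$A0_frac_L *
                 oracle_hindrance(1 / 22.85), tolerance = 1e-12)
  expect_equal(terms$sigma_S, oracle_sigma(1 / 4.4), tolerance = 1e-12)
  # Peclet definition Pe = J (1 - sigma) / PS
  expect_equal(terms$Pe_S, muscle$J_S * (1 - terms$sigma_S) / terms$PS_S)
})

test_that("full steric exclusion yields PS = 0, sigma = 1, no flux", {
  phys <- mouse_physiology()
  organ <- phys$organs[phys$organs$organ == "heart", ]
  big <- list(solute_radius = 30, D_free = 1e-7)  # larger than both pores
  terms <- pore_exchange_terms(organ, big)
  expect_equal(terms$PS_S, 0)
  expect_equal(terms$PS_L, 0)
  expect_equal(terms$sigma_S, 1)
  expect_equal(terms$sigma_L, 1)
  expect_equal(two_pore_flux(10, 3, terms, fu = 1, K_iv = 0.94), 0)
})

test_that("two-pore flux equals the hand-evaluated equation", {
  # stated terms, evaluated independently in the helper
  terms <- structure(list(PS_S = 0.02, PS_L = 0.005, sigma_S = 0.18,
                          sigma_L = 0.008, Pe_S = 0.4, Pe_L = 1.2,
                          J_S = 3e-4, J_L = 1e-5),
                     class = "pore_exchange_terms")
  got <- two_pore_flux(10, 0, terms, fu = 1, K_iv = 0.94)
  want <- oracle_two_pore(10, 0, 1, 0.94, 1e-5, 3e-4, 0.008, 0.18,
                          0.005, 0.02, 1.2, 0.4)
  expect_equal(got, want, tolerance = 1e-12)
  # no driving force
  expect_equal(two_pore_flux(0, 0, terms), 0)
  # linear in fu
  expect_equal(two_pore_flux(10, 2, terms, fu = 0.35),
               0.35 * two_pore_flux(10, 2, terms, fu = 1))
  # monotone increasing in C_v, decreasing in C_i
  expect_gt(two_pore_flux(11, 2, terms), two_pore_flux(10, 2, terms))
  expect_lt(two_pore_flux(10, 3, terms), two_pore_flux(10, 2, terms))
})

test_that("zero-flow limit reduces to permeability exchange with Kp equilibrium", {
  terms <- structure(list(PS_S = 0.02, PS_L = 0.005, sigma_S = 0.18,
                          sigma_L = 0.008, Pe_S = 0, Pe_L = 0,
                          J_S = 0, J_L = 0),
                     class = "pore_exchange_terms")
  K <- 0.94
  expect_equal(two_pore_flux(2, 2 * K, terms, K_iv = K), 0, tolerance = 1e-14)
  expect_equal(two_pore_flux(3, 0, terms, K_iv = K), (0.02 + 0.005) * 3)
})

test_that("Peclet factor is continuous at Pe = 0", {
  base <- list(PS_S = 0.02, PS_L = 0.005, sigma_S = 0.18, sigma_L = 0.008,
               J_S = 0, J_L = 0)
  f0 <- two_pore_flux(5, 1, structure(c(base, Pe_S = 0, Pe_L = 0),
                                      class = "pore_exchange_terms"))
  for (eps in 10^c(-4, -6, -8)) {
    fe <- two_pore_flux(5, 1, structure(c(base, Pe_S = eps, Pe_L = eps),
                                        class = "pore_exchange_terms"))
    expect_lt(abs(fe - f0), eps * abs(f0) + 1e-12)
  }
})

test_that("liver permeability flux: units, equilibrium, fu scaling", {
  # 0.02 cm/min * 100 cm2 * 1 nmol/L, cm3/min -> L/h factor 0.06
  expect_equal(liver_permeability_flux(1, 0, 0.02, 100, fu = 1, Kp = 0.94),
               0.02 * 100 * 0.06 * 1)
  expect_equal(liver_permeability_flux(1, 0.94, 0.02, 100, Kp = 0.94), 0,
               tolerance = 1e-14)
  expect_equal(liver_permeability_flux(5, 0, 0.02, 100, fu = 0), 0)
  expect_equal(liver_permeability_flux(2, 1, 0.02, 100, fu = 0.5, Kp = 0.94),
               0.5 * 0.02 * 100 * 0.06 * (2 - 1 / 0.94))
})
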