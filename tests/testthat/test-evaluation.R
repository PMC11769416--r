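test_that("trapezoid AUC: constants, zeros, closed-form exponential", {
  expect_equal(auc_trapezoid(c(0, 1), c(1, 1)), 1)
  expect_equal(auc_trapezoid(seq(0, 10, by = 0.5), rep(0, 21)), 0)
  tt <- seq(0, 100, by = 0.1)
  expect_equal(auc_trapezoid(tt, exp(-0.1 * tt), 0, 100),
               (1 - exp(-10)) / 0.1, tolerance = 1e-3)
  # edge interpolation: window not on sample points
  tt2 <- 0:10
  expect_equal(auc_trapezoid(tt2, rep(2, 11), 0.25, 9.75), 2 * 9.5)
  expect_error(auc_trapezoid(tt2, rep(1, 11), 5, 5), "t0 must be < t1")
  expect_error(auc_trapezoid(tt2, rep(1, 11), -1, 5), "outside the series span")
})

test_that("terminal half-life: exponentials, censoring, degenerate input", {
  tt <- seq(0, 100, by = 1)
  expect_equal(terminal_half_life(tt, exp(-0.1 * tt)), log(2) / 0.1,
               tolerance = 1e-6)
  expect_equal(terminal_half_life(tt, exp(-0.1 * tt)), 6.931, tolerance = 1e-3)
  # biexponential dominated by k = 0.01 in the tail
  tt2 <- seq(0, 600, by = 2)
  bi <- 5 * exp(-0.2 * tt2) + 0.5 * exp(-0.01 * tt2)
  expect_equal(terminal_half_life(tt2, bi, tail_fraction = 0.3), log(2) / 0.01,
               tolerance = 0.05)
  expect_error(terminal_half_life(tt, rep(3, length(tt))), "not decaying")
  # LLOQ censoring drops the flat noise floor before fitting
  floored <- pmax(exp(-0.1 * tt), 1e-3)
  expect_equal(terminal_half_life(tt, floored, tail_fraction = 0.5, lloq = 2e-3),
               log(2) / 0.1, tolerance = 0.02)
})

test_that("decade-crossing elimination half-life isolates the mid phase", {
  tt <- seq(0, 1000, by = 1)
  # absorption, elimination k = 0.02, and a shallow floor 1e-3 of peak
  cc <- (exp(-0.02 * tt) - exp(-0.5 * tt)) + 2e-4
  expect_equal(elimination_half_life(tt, cc), log(2) / 0.02, tolerance = 0.03)
  expect_error(elimination_half_life(tt, rep(1, length(tt))),
               "never falls below")
})

test_that("fold-error metrics match direct arithmetic", {
  fe <- fold_error_metrics(c(2, 0.5))
  expect_equal(fe$AFE, 1)
  expect_equal(fe$AAFE, 2)
  expect_equal(unlist(fold_error_metrics(1)[c("AFE", "AAFE")]), c(AFE = 1, AAFE = 1))
  # paper-range ratios, evaluated independently
  r <- c(0.52, 1.22)
  fe2 <- fold_error_metrics(r)
  expect_equal(fe2$AFE, sqrt(0.52 * 1.22), tolerance = 1e-12)
  expect_equal(fe2$AFE, 0.796, tolerance = 1e-3)
  expect_equal(fe2$AAFE, 10^((abs(log10(0.52)) + abs(log10(1.22))) / 2),
               tolerance = 1e-12)
  expect_equal(fe2$AAFE, 1.531, tolerance = 1e-3)
  expect_true(fe2$adequate)
  expect_error(fold_error_metrics(numeric(0)))
  expect_error(fold_error_metrics(c(1, -2)))
})

test_that("AAFE >= max(AFE, 1/AFE); reciprocal union has AFE 1", {
  set.seed(7)
  for (i in 1:10) {
    r <- exp(stats::rnorm(8, 0, 1))
    fe <- fold_error_metrics(r)
    expect_gte(fe$AAFE, 1)
    expect_gte(fe$AAFE + 1e-12, max(fe$AFE, 1 / fe$AFE))
    expect_equal(fold_error_metrics(c(r, 1 / r))$AFE, 1, tolerance = 1e-10)
  }
})

test_that("WHO classification thresholds", {
  expect_equal(classify_sensitivity(0.6), "high")
  expect_equal(classify_sensitivity(-0.3), "medium")
  expect_equal(classify_sensitivity(0.15), "low")
  expect_equal(classify_sensitivity(0.05), "insignificant")
  expect_equal(classify_sensitivity(c(0.5, 0.2, 0.1, 0.099)),
               c("high", "medium", "low", "insignificant"))
})

test_that("sensitivity coefficient: linearity, analytic one-compartment", {
  # output proportional to parameter: S = 1 exactly for either scheme
  expect_equal(sensitivity_coefficient(function(p) 3 * p, 2), 1)
  # one-compartment AUC = Dose/CL: analytic S = -1; central scheme within 2%
  auc_fn <- function(cl) 10 / cl
  s_central <- sensitivity_coefficient(auc_fn, 0.5, 0.1, scheme = "central")
  expect_equal(abs(s_central), 1, tolerance = 0.02)
  # no pathway: S = 0
  expect_equal(sensitivity_coefficient(function(p) 42, 1), 0)
  expect_error(sensitivity_coefficient(function(p) p, 0), "zero-valued")
})

test_that("model-level sensitivity: proportional and disconnected parameters", {
  m <- aln_model()
  tg <- seq(0, 400, by = 4)
  # in the linear-dose regime liver AUC is proportional to bioavailability
  rec <- local_sensitivity(m, "F_bio", std_dose(0.1), output = "liver",
                           window = c(0, 400), t_grid = tg,
                           rtol = 1e-6, atol = 1e-9)
  expect_equal(rec$S, 1, tolerance = 0.02)
  expect_equal(rec$class, "high")
  # gamma only touches protein: plasma AUC is insensitive
  rec0 <- local_sensitivity(m, "gamma", std_dose(0.1), output = "plasma",
                            window = c(0, 400), t_grid = tg,
                            rtol = 1e-6, atol = 1e-9)
  expect_lt(abs(rec0$S), 1e-6)
  expect_equal(rec0$class, "insignificant")
})

test_that("fit_parameters recovers a single parameter from noise-free data", {
  lib <- compound_library()
  entry <- lib[["ALN-AT3"]]
  m <- model_for_compound(entry)
  obs <- generate_observations(entry, std_dose(1),
                               schedule = c(1, 4, 8, 24, 48, 96, 168, 250,
                                            350, 500, 750, 1000),
                               measurements = "liver",
                               noise = noise_model(CV = 0), model = m)
  fit <- fit_parameters(m, obs, free = c(k_endosome = 0.036))
  expect_equal(unname(fit$estimates), 0.012, tolerance = 0.01)
  expect_equal(fit$convergence, 0)
  expect_equal(fit$AFE, 1, tolerance = 0.02)
  expect_gte(fit$AAFE, 1)
  expect_error(fit_parameters(m, list(), free = c(k_endosome = 0.01)),
               "empty observation")
})
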