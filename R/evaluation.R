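# Model evaluation toolkit: exposure metrics, fold-error statistics, local
# sensitivity analysis with WHO-style classification, and bounded nonlinear
# least-squares parameter estimation.

#' Linear-trapezoid area under the curve
#'
#' AUC of a sampled time course on `[t0, t1]`, with linear interpolation at
#' the window edges when they fall between samples.
#'
#' @param times Sampling times, h (increasing).
#' @param values Values at `times`.
#' @param t0,t1 Integration window, h (defaults: full series span).
#' @return AUC in value-units times hours.
#' @export
auc_trapezoid <- function(times, values, t0 = min(times), t1 = max(times)) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  if (t0 >= t1) stop("t0 must be < t1")
  if (t0 < min(times) || t1 > max(times)) {
    stop("window outside the series span")
  }
  keep <- times > t0 & times < t1
  tt <- c(t0, times[keep], t1)
  vv <- c(stats::approx(times, values, xout = t0)$y, values[keep],
          stats::approx(times, values, xout = t1)$y)
  if (length(tt) < 2) stop("fewer than 2 points in window")
  sum(diff(tt) * (head_(vv) + tail_(vv)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Terminal half-life by log-linear regression
#'
#' Fits `log(C)` against time on the terminal portion of a concentration
#' series and returns `t1/2 = ln(2) / |slope|`. The terminal window is the
#' last `tail_fraction` of the time span (at least 3 positive points); values
#' at or below `lloq` are censored (dropped) first, mirroring how half-life
#' is read from assay data.
#'
#' @param times Sampling times, h.
#' @param values Concentrations (any unit).
#' @param tail_fraction Fraction of the (censored) time span used, in (0, 1].
#' @param lloq Optional lower limit of quantification; values `<= lloq` are
#'   dropped before window selection.
#' @return Half-life, h.
#' @export
terminal_half_life <- function(times, values, tail_fraction = 1 / 3,
                               lloq = 0) {
  stopifnot(length(times) == length(values), tail_fraction > 0,
            tail_fraction <= 1)
  keep <- is.finite(values) & values > max(lloq, 0)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 3) stop("fewer than 3 positive points")
  t_start <- max(times) - tail_fraction * (max(times) - min(times))
  w <- times >= t_start
  if (sum(w) < 3) w <- rank(-times) <= 3  # fall back to the last 3 points
  fit <- lm(log(values[w]) ~ times[w])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    stop("undefined half-life: terminal phase is not decaying")
  }
  log(2) / abs(slope)
}

#' Elimination-phase half-life by decade-crossing selection
#'
#' Terminal-phase (lambda-z style) half-life for multiphasic tissue
#' profiles: the regression window runs from the first post-peak crossing of
#' `upper_frac * Cmax` to the first crossing of `lower_frac * Cmax` (or the
#' series end), isolating the elimination phase from any shallow
#' redistribution tail below it. Complements [terminal_half_life()], which
#' uses a fixed tail window.
#'
#' @param times Sampling times, h.
#' @param values Concentrations.
#' @param upper_frac,lower_frac Window bounds as fractions of the observed
#'   peak (defaults 0.1 and 0.01: the decade below one-tenth of Cmax).
#' @return Half-life, h.
#' @export
elimination_half_life <- function(times, values, upper_frac = 0.1,
                                  lower_frac = 0.01) {
  stopifnot(length(times) == length(values), upper_frac > lower_frac,
            lower_frac > 0)
  imax <- which.max(values)
  cmax <- values[imax]
  if (!is.finite(cmax) || cmax <= 0) stop("no positive peak in series")
  tt <- times[imax:length(times)]
  cc <- values[imax:length(values)]
  i_hi <- which(cc <= upper_frac * cmax)[1]
  if (is.na(i_hi)) stop("series never falls below upper_frac * Cmax")
  i_lo <- which(cc <= lower_frac * cmax)[1]
  if (is.na(i_lo)) i_lo <- length(cc)
  w <- i_hi:i_lo
  if (length(w) < 3) stop("fewer than 3 points in the elimination window")
  fit <- lm(log(cc[w]) ~ tt[w])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    stop("undefined half-life: selected window is not decaying")
  }
  log(2) / abs(slope)
}

#' Average and absolute-average fold error
#'
#' For ratios `r_k = AUC_sim/AUC_obs`: `AFE = geometric mean(r)` (bias) and
#' `AAFE = 10^mean(|log10 r|)` (spread). Model performance is conventionally
#' adequate when `0.5 <= AFE <= 2` and `AAFE <= 2`.
#'
#' @param ratios Positive fold ratios.
#' @return List with `AFE`, `AAFE`, and logical `adequate`.
#' @export
fold_error_metrics <- function(ratios) {
  if (!length(ratios) || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("ratios must be a non-empty set of positive numbers")
  }
  lg <- log10(ratios)
  afe <- 10^mean(lg)
  aafe <- 10^mean(abs(lg))
  list(AFE = afe, AAFE = aafe,
       adequate = (afe >= 0.5 && afe <= 2 && aafe <= 2))
}

#' WHO-style sensitivity classification
#'
#' `|S| >= 0.5` high; `0.2 <= |S| < 0.5` medium; `0.1 <= |S| < 0.2` low;
#' `|S| < 0.1` insignificant.
#'
#' @param S Sensitivity coefficient(s).
#' @return Character vector of classes.
#' @export
classify_sensitivity <- function(S) {
  stopifnot(all(is.finite(S)))
  a <- abs(S)
  ifelse(a >= 0.5, "high",
         ifelse(a >= 0.2, "medium",
                ifelse(a >= 0.1, "low", "insignificant")))
}

#' Normalized sensitivity of a scalar function
#'
#' `S = (dY/dp) * (p/Y)` by finite differences at relative perturbation
#' `perturbation` (default 10%): one-sided forward (the default, matching the
#' +10% convention of local PBPK sensitivity analysis) or central.
#'
#' @param fn Function of a single numeric parameter returning a scalar.
#' @param p0 Baseline parameter value (non-zero).
#' @param perturbation Relative perturbation.
#' @param scheme `"forward"` or `"central"`.
#' @return Sensitivity coefficient (dimensionless).
#' @export
sensitivity_coefficient <- function(fn, p0, perturbation = 0.1,
                                    scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  if (p0 == 0) stop("undefined relative perturbation for zero-valued parameter")
  y0 <- fn(p0)
  if (!is.finite(y0) || y0 == 0) stop("baseline output must be finite and non-zero")
  dp <- perturbation * p0
  dy <- if (scheme == "forward") {
    (fn(p0 + dp) - y0) / dp
  } else {
    (fn(p0 + dp) - fn(p0 - dp)) / (2 * dp)
  }
  dy * p0 / y0
}

#' Local sensitivity of model exposure to one parameter
#'
#' Perturbs a named model parameter, re-simulates, and reports the normalized
#' sensitivity of `AUC` of the chosen observable over `window`, classified by
#' [classify_sensitivity()].
#'
#' @param model A `sirna_model`.
#' @param parameter Parameter name (see [model_parameter_names()]).
#' @param doses Dose event(s) defining the scenario.
#' @param output Observable: one of `"plasma"`, `"liver"`, `"kidney"`,
#'   `"RISC"`, `"mRNA"`, `"protein"`.
#' @param window AUC window, h (default 0-1000).
#' @param perturbation Relative perturbation (default 0.10).
#' @param scheme Difference scheme, `"forward"` (default) or `"central"`.
#' @param t_grid Simulation grid (default 0-1000 h, 2 h spacing).
#' @param ... Passed to [simulate_model()].
#' @return List of class `sensitivity_record`: `parameter`, `S`, `class`,
#'   `output`, `window`, `baseline_auc`.
#' @export
local_sensitivity <- function(model, parameter, doses,
                              output = "plasma", window = c(0, 1000),
                              perturbation = 0.1,
                              scheme = c("forward", "central"),
                              t_grid = NULL, ...) {
  scheme <- match.arg(scheme)
  if (is.null(t_grid)) {
    t_grid <- unique(sort(c(seq(0, window[2], by = 2), window)))
  }
  p0 <- get_model_parameter(model, parameter)
  auc_of <- function(p) {
    m <- set_model_parameter(model, parameter, p)
    sim <- simulate_model(m, doses, t_grid = t_grid, ...)
    auc_trapezoid(sim$observables$time, sim$observables[[output]],
                  window[1], window[2])
  }
  base <- auc_of(p0)
  if (!is.finite(base) || base <= 0) stop("baseline AUC must be positive")
  S <- sensitivity_coefficient(auc_of, p0, perturbation, scheme)
  structure(list(parameter = parameter, S = S,
                 class = classify_sensitivity(S), output = output,
                 window = window, baseline_auc = base),
            class = "sensitivity_record")
}

#' Names of perturbable model parameters
#'
#' @param model A `sirna_model`.
#' @return Character vector of parameter names accepted by
#'   [get_model_parameter()] / [set_model_parameter()].
#' @export
model_parameter_names <- function(model) {
  c("fu", "Kp", "ka", "F_bio", "k_endosome", "kon_RISC",
    "molecular_weight", "solute_radius",
    "Smax", "SC50", "gamma", "k_deg_mRNA", "k_deg_protein",
    "k_uptake", "k_recycling", "k_kid_uptake", "k_kid_recycling",
    "k_RNase", "RNase_kidney", "RNase_remaining", "P_liver",
    "R_tot", "k_on", "k_off", "k_deg", "k_deg_R", "k_int", "k_cle",
    "k_rec", "f_escape", "k_deg_C",
    "RISC_tot", "koff_RISC", "k_DR", "GFR")
}

#' @rdname model_parameter_names
#' @param name Parameter name.
#' @export
get_model_parameter <- function(model, name) {
  cp <- model$compound
  if (name %in% c("fu", "Kp", "ka", "F_bio", "k_endosome", "kon_RISC",
                  "molecular_weight", "solute_radius")) {
    return(cp[[name]])
  }
  if (name %in% names(cp$pd)) return(cp$pd[[name]])
  if (name %in% names(model$globals)) return(model$globals[[name]])
  if (name %in% setdiff(names(model$asgpr), "k_syn")) return(model$asgpr[[name]])
  if (name %in% names(model$risc)) return(model$risc[[name]])
  if (name == "GFR") return(model$physiology$GFR)
  stop("unknown model parameter: ", name)
}

#' @rdname model_parameter_names
#' @param value New parameter value.
#' @export
set_model_parameter <- function(model, name, value) {
  cp <- model$compound; gl <- model$globals; as_ <- model$asgpr
  rs <- model$risc; ph <- model$physiology
  if (name %in% c("fu", "Kp", "ka", "F_bio", "k_endosome", "kon_RISC",
                  "molecular_weight", "solute_radius")) {
    cp[[name]] <- value
    if (name == "solute_radius") cp$D_free <- stokes_einstein_diffusivity(value)
  } else if (name %in% names(cp$pd)) {
    cp$pd[[name]] <- value
  } else if (name %in% names(gl)) {
    gl[[name]] <- value
  } else if (name %in% setdiff(names(as_), "k_syn")) {
    as_[[name]] <- value
    # receptor synthesis is tied to the pool and its turnover
    if (name %in% c("R_tot", "k_deg")) as_$k_syn <- as_$R_tot * as_$k_deg
  } else if (name %in% names(rs)) {
    rs[[name]] <- value
  } else if (name == "GFR") {
    ph$GFR <- value
  } else {
    stop("unknown model parameter: ", name)
  }
  assemble_model(cp, gl, ph, as_, rs)
}

#' Observation set
#'
#' A labelled series of (time, value) measurements of one observable under
#' one dosing scenario, as consumed by [fit_parameters()] and produced by
#' [generate_observations()].
#'
#' @param compound Compound identifier.
#' @param measurement One of `"plasma"`, `"liver"`, `"kidney"`, `"RISC"`,
#'   `"mRNA"`, `"protein"`.
#' @param route,dose Dosing route ("SC"/"IV") and dose in mg/kg.
#' @param times,values Measurement times (h, increasing) and values.
#' @param unit Value unit label.
#' @param provenance `"synthetic"` or `"user"`.
#' @return A list of class `observation_set`.
#' @export
observation_set <- function(compound, measurement, route, dose, times, values,
                            unit = "nmol/L", provenance = "user") {
  stopifnot(length(times) == length(values),
            !is.unsorted(times, strictly = TRUE), all(values >= 0))
  measurement <- match.arg(measurement,
                           c("plasma", "liver", "kidney", "RISC", "mRNA", "protein"))
  structure(list(compound = compound, measurement = measurement,
                 route = route, dose = dose,
                 records = data.frame(time = times, value = values),
                 unit = unit, provenance = provenance),
            class = "observation_set")
}

# one simulation serving all observation sets that share a regimen
.sim_for_obs <- function(model, observations, body_weight, rtol, atol) {
  keys <- vapply(observations, function(o) paste(o$route, o$dose), "")
  t_end <- max(vapply(observations, function(o) max(o$records$time), 0))
  grid <- sort(unique(c(0, unlist(lapply(observations, function(o) o$records$time)),
                        seq(0, t_end, length.out = 101))))
  sims <- list()
  for (k in unique(keys)) {
    o <- observations[[match(k, keys)]]
    dose <- dose_event(0, o$route, o$dose, body_weight)
    sims[[k]] <- simulate_model(model, dose, t_grid = grid,
                                rtol = rtol, atol = atol)
  }
  list(sims = sims, keys = keys)
}

.obs_residuals <- function(sims, keys, observations) {
  res <- numeric(0)
  for (j in seq_along(observations)) {
    o <- observations[[j]]
    sim <- sims[[keys[j]]]
    pred <- stats::approx(sim$observables$time, sim$observables[[o$measurement]],
                          xout = o$records$time)$y
    if (o$measurement %in% c("mRNA", "protein")) {
      res <- c(res, (pred - o$records$value) / 100)
    } else {
      keep <- o$records$value > 0
      res <- c(res, log(pmax(pred[keep], 1e-12)) - log(o$records$value[keep]))
    }
  }
  res
}

#' Fit model parameters to observation sets
#'
#' Bounded nonlinear least squares on log-transformed parameters
#' (`stats::optim`, L-BFGS-B). Residuals are log-scale for concentration
#' observables (plasma, liver, kidney, RISC) and linear (in fraction of
#' baseline) for the percent-scale PD observables. Reports per-series
#' `AUC_sim/AUC_obs` ratios and the AFE/AAFE fold-error summary.
#'
#' @param model A `sirna_model` providing every non-free parameter.
#' @param observations List of [observation_set()] objects.
#' @param free Named numeric vector of starting values for the free
#'   parameters (names per [model_parameter_names()]).
#' @param lower,upper Named bounds (same names as `free`); defaults span
#'   `free/100` to `free*100`.
#' @param body_weight kg (default 0.025).
#' @param rtol,atol Solver tolerances used inside the objective (looser than
#'   the simulation defaults for speed).
#' @param control Passed to `optim`.
#' @return A list of class `fit_result`: `estimates`, `objective`,
#'   `auc_ratios`, `AFE`, `AAFE`, `convergence`, `message`, `n_obs`.
#' @export
fit_parameters <- function(model, observations, free,
                           lower = free / 100, upper = free * 100,
                           body_weight = 0.025,
                           rtol = 1e-6, atol = 1e-9,
                           control = list(maxit = 200)) {
  if (!length(observations)) stop("empty observation list")
  if (inherits(observations, "observation_set")) observations <- list(observations)
  stopifnot(length(free) >= 1, !is.null(names(free)),
            all(names(free) %in% model_parameter_names(model)),
            all(lower > 0), all(free >= lower), all(free <= upper))

  with_params <- function(theta) {
    m <- model
    for (nm in names(free)) m <- set_model_parameter(m, nm, theta[[nm]])
    m
  }
  objective <- function(ltheta) {
    theta <- setNames(10^ltheta, names(free))
    m <- with_params(theta)
    sw <- .sim_for_obs(m, observations, body_weight, rtol, atol)
    sum(.obs_residuals(sw$sims, sw$keys, observations)^2)
  }
  opt <- optim(log10(free), objective, method = "L-BFGS-B",
               lower = log10(lower), upper = log10(upper),
               control = control)
  est <- setNames(10^opt$par, names(free))

  m_hat <- with_params(est)
  sw <- .sim_for_obs(m_hat, observations, body_weight, rtol, atol)
  ratios <- vapply(seq_along(observations), function(j) {
    o <- observations[[j]]
    sim <- sw$sims[[sw$keys[j]]]
    tr <- o$records$time
    if (length(tr) < 2) return(NA_real_)
    pred <- stats::approx(sim$observables$time,
                          sim$observables[[o$measurement]], xout = tr)$y
    auc_trapezoid(tr, pred) / auc_trapezoid(tr, o$records$value)
  }, 0)
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  fe <- if (length(ratios)) fold_error_metrics(ratios) else
    list(AFE = NA_real_, AAFE = NA_real_)
  structure(list(estimates = est, objective = opt$value,
                 auc_ratios = ratios, AFE = fe$AFE, AAFE = fe$AAFE,
                 convergence = opt$convergence, message = opt$message,
                 n_obs = sum(vapply(observations, function(o) nrow(o$records), 0L)),
                 bounds = list(lower = lower, upper = upper)),
            class = "fit_result")
}
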