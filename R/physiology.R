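#' Load the bundled mouse physiology table
#'
#' Returns the whole-body physiological parameter set used by the circulation
#' and extravasation models: per-organ sub-compartment volumes, plasma and
#' lymph flows, capillary surface areas and pore geometry, plus whole-body
#' scalars (glomerular filtration rate, plasma pool volumes, hematocrit).
#' Volumes, flows and surface areas are scaled linearly (isometrically) from
#' the 0.025 kg reference animal to `body_weight`; dimensionless quantities
#' and pore radii are left unchanged.
#'
#' @param species Species identifier. Only `"mouse"` is supported.
#' @param body_weight Body weight in kg (default: the table's reference
#'   weight, 0.025 kg).
#' @param path Optional path to an organ table overriding the bundled one
#'   (same tab-delimited schema; see
#'   `system.file("extdata", "mouse_physiology_organs.tsv", package = "galnacpbpk")`).
#'
#' @return An object of class `physiology_table`: a list with `organs` (a
#'   data.frame, one row per organ, volumes in L, flows in L/h, areas in cm2),
#'   `body_weight` (kg), `GFR` (L/h), `hematocrit`, `V_venous`, `V_arterial`
#'   (L), `cardiac_plasma_output` (L/h), and the pore-area constants
#'   `pore_area_fraction` and `membrane_thickness_cm`.
#' @export
#' @examples
#' phys <- load_physiology("mouse")
#' phys$organs[phys$organs$organ == "liver", c("V_vas", "V_int", "Q_plasma")]
load_physiology <- function(species = "mouse", body_weight = NULL, path = NULL) {
  if (!identical(tolower(species), "mouse")) {
    stop("unsupported species: '", species, "' (only 'mouse' is bundled)")
  }
  organ_path <- if (is.null(path)) {
    system.file("extdata", "mouse_physiology_organs.tsv", package = "galnacpbpk")
  } else {
    path
  }
  raw <- read.delim(organ_path, comment.char = "#", stringsAsFactors = FALSE)
  glob_path <- system.file("extdata", "mouse_physiology_global.tsv", package = "galnacpbpk")
  glob_raw <- read.delim(glob_path, comment.char = "#", stringsAsFactors = FALSE)
  glob <- setNames(as.numeric(glob_raw$value), glob_raw$key)

  ref_bw <- glob[["body_weight_kg"]]
  if (is.null(body_weight)) body_weight <- ref_bw
  stopifnot(is.numeric(body_weight), body_weight > 0)
  f <- body_weight / ref_bw

  v_tot <- raw$v_total_ml * 1e-3 * f   # L
  organs <- data.frame(
    organ    = raw$organ,
    V_total  = v_tot,
    V_vas    = raw$f_vas * v_tot,
    V_int    = raw$f_int * v_tot,
    V_endo   = raw$f_endo * v_tot,
    V_cell   = pmax(0, (1 - raw$f_vas - raw$f_int - raw$f_endo)) * v_tot,
    Q_plasma = raw$q_plasma_ml_h * 1e-3 * f,                    # L/h
    J_lymph  = raw$lymph_frac * raw$q_plasma_ml_h * 1e-3 * f,   # L/h
    SA_cap   = raw$sa_per_g_cm2 * raw$v_total_ml * f,           # cm2 (1 g/mL)
    r_S      = raw$r_small_nm,
    r_L      = raw$r_large_nm,
    alpha_L  = raw$alpha_large,
    A0_frac_L = raw$a0_frac_large,
    drains_to = raw$drains_to,
    stringsAsFactors = FALSE
  )
  organs$J_L <- organs$alpha_L * organs$J_lymph
  organs$J_S <- (1 - organs$alpha_L) * organs$J_lymph

  structure(list(
    organs = organs,
    body_weight = body_weight,
    reference_weight = ref_bw,
    GFR = glob[["gfr_ml_h"]] * 1e-3 * f,
    hematocrit = glob[["hematocrit"]],
    cardiac_plasma_output = glob[["cardiac_plasma_output_ml_h"]] * 1e-3 * f,
    V_venous = glob[["v_venous_ml"]] * 1e-3 * f,
    V_arterial = glob[["v_arterial_ml"]] * 1e-3 * f,
    pore_area_fraction = glob[["pore_area_fraction"]],
    membrane_thickness_cm = glob[["membrane_thickness_cm"]]
  ), class = "physiology_table")
}

#' Required organ set of the whole-body model
#' @return Character vector of the 15 perfused organ identifiers.
#' @export
required_organs <- function() {
  c("lung", "heart", "brain", "muscle", "skin", "adipose", "bone", "gonads",
    "kidney", "liver", "stomach", "small_intestine", "large_intestine",
    "spleen", "pancreas")
}

#' Validate a physiology table
#'
#' Checks the structural invariants of a [load_physiology()] table: strictly
#' positive volumes, flows and areas; lymph flow not exceeding plasma flow;
#' pore radii ordered (`r_S < r_L`); dimensionless fractions in `[0, 1]`;
#' the full required organ set present; and the sum of organ plasma flows
#' (arterially fed organs, lung excluded as it is in series) consistent with
#' cardiac plasma output within 1%.
#'
#' @param table A `physiology_table`.
#' @return Character vector of violated invariants; `character(0)` if valid.
#' @export
validate_physiology <- function(table) {
  v <- character(0)
  org <- table$organs
  missing <- setdiff(required_organs(), org$organ)
  if (length(missing)) {
    v <- c(v, paste0("missing required organ: ", paste(missing, collapse = ", ")))
  }
  num_fields <- c("V_vas", "V_int", "V_endo", "Q_plasma", "J_lymph", "SA_cap",
                  "r_S", "r_L")
  for (fld in num_fields) {
    bad <- org$organ[!is.finite(org[[fld]]) | org[[fld]] <= 0]
    if (length(bad)) {
      v <- c(v, paste0("non-positive ", fld, " for organ: ",
                       paste(bad, collapse = ", ")))
    }
  }
  bad <- org$organ[org$J_lymph > org$Q_plasma]
  if (length(bad)) v <- c(v, paste0("J_lymph > Q_plasma for organ: ", paste(bad, collapse = ", ")))
  bad <- org$organ[org$r_S >= org$r_L]
  if (length(bad)) v <- c(v, paste0("r_S >= r_L for organ: ", paste(bad, collapse = ", ")))
  for (fld in c("alpha_L", "A0_frac_L")) {
    bad <- org$organ[org[[fld]] < 0 | org[[fld]] > 1]
    if (length(bad)) v <- c(v, paste0(fld, " outside [0, 1] for organ: ", paste(bad, collapse = ", ")))
  }
  if (!length(missing)) {
    fed <- org$organ != "lung"
    qsum <- sum(org$Q_plasma[fed])
    if (abs(qsum - table$cardiac_plasma_output) / table$cardiac_plasma_output > 0.01) {
      v <- c(v, "sum of organ plasma flows deviates from cardiac plasma output by > 1%")
    }
  }
  for (fld in c("V_venous", "V_arterial", "cardiac_plasma_output")) {
    if (!is.finite(table[[fld]]) || table[[fld]] <= 0) {
      v <- c(v, paste0("non-positive ", fld))
    }
  }
  if (!is.finite(table$GFR) || table$GFR < 0) v <- c(v, "negative GFR")
  v
}
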