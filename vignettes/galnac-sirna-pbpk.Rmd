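---
title: "Whole-body PBPK-PD modelling of GalNAc-conjugated siRNAs in the mouse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK-PD modelling of GalNAc-conjugated siRNAs in the mouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model structure

`galnacpbpk` simulates the disposition and pharmacodynamics of
GalNAc-conjugated small interfering RNAs (siRNA duplexes of roughly 16 kDa
and 1 nm hydrodynamic radius, conjugated to tri-antennary
N-acetylgalactosamine for hepatocyte targeting) in the mouse. The model is a
whole-body PBPK system of 15 perfused organs plus venous and arterial plasma
pools. Each organ is subdivided into vascular, interstitial and endothelial
endosomal spaces; an intracellular space is represented only in the liver,
because passive intracellular uptake is set to zero and receptor-mediated
uptake is restricted to hepatocytes. The full state vector (60 states) and
its ordering are documented in `state_labels()`.

The processes represented are:

* **Circulation** by organ plasma flows, with the lung in series between the
  venous and arterial pools and the splanchnic organs (stomach, intestines,
  spleen, pancreas) draining through the portal vein into the liver.
* **Extravasation** by the two-pore formalism: convection and restricted
  diffusion through small (4.4 nm) and large (22.85 nm) cylindrical pores,
  with organ-specific fluid flows, permeability-surface-area products,
  reflection coefficients and Peclet numbers (`pore_exchange_terms()`,
  `two_pore_flux()`).
* An **additional liver permeability pathway**,
  `fu * P_liver * SA_liver * (C_pls - C_int/Kp)`, acting on top of (not
  replacing) the liver two-pore exchange. The two-pore formalism alone
  confines a 1 nm polyanion largely to plasma and cannot produce the
  observed fast hepatic uptake; the extra generic pathway (fitted
  `P_liver` = 0.02 cm/min) restores it.
* **Unspecific tissue distribution** as first-order endosomal uptake from,
  and slow recycling to, the interstitial space of every non-liver organ
  (global pair 20.87 and 7.7e-5 per minute; kidney-specific pair 68.2 and
  3.9e-4 per minute).
* **Degradation** by ribonucleases in plasma and all non-liver tissues, and
  **renal elimination** as passive glomerular filtration of unbound drug.
* **Hepatic target-mediated drug disposition**: reversible GalNAc-ASGPR
  binding at the interstitial face, complex internalization, endosomal
  cleavage, receptor recycling or degradation, and an endosomal exit at the
  compound-specific rate `k_endosome` split between cytoplasmic escape
  (`f_escape` = 1%) and degradation.
* **RISC pharmacodynamics**: saturable loading of the cytoplasmic antisense
  strand onto a finite Ago2 pool, an indirect-response model in which loaded
  RISC stimulates mRNA degradation (parameters `Smax`, `SC50`), and protein
  turnover whose synthesis tracks relative mRNA raised to a power `gamma`.

## Units and parameter conventions

Internally all amounts are nmol, concentrations nmol/L, volumes L and times
hours. Literature units are preserved at the user surface and converted once
in `assemble_model()`: per-minute endosomal rates are multiplied by 60,
micromolar pools (receptor, Ago2, RNase) by 1000, and the liver permeability
`cm/min x cm^2` by 0.06 to L/h. A liver tissue density of 1 g/mL converts
between amounts and tissue concentrations.

Key defaults (all overridable through the parameter constructors):

| parameter | meaning | default | unit |
|---|---|---|---|
| `fu` | fraction unbound in plasma | 1.0 | - |
| `Kp` | interstitial:plasma partition | 0.94 | - |
| `ka` | SC absorption rate | 0.84 | 1/h |
| `P_liver` | added liver permeability | 0.02 | cm/min |
| `R_tot` | ASGPR density (liver interstitial basis) | 5.23 | umol/L |
| `k_on`, `k_off` | ASGPR binding | 0.53, 1.53 | L/nmol/h, 1/h |
| `k_int`, `k_cle`, `k_rec` | internalization, cleavage, recycling | 5.14, 1.32, 13.8 | 1/h |
| `f_escape` | endosomal escape fraction | 0.01 | - |
| `k_deg_C` | cytoplasmic siRNA degradation | 0.10 | 1/h |
| `RISC_tot` | Ago2 pool (hepatocyte cell basis) | 0.0003 | umol/L |
| `k_DR` | loaded-RISC degradation | 0.0033 | 1/h |
| `k_deg_mRNA`, `k_deg_protein` | PD turnover | 0.06, 0.05 | 1/h |

The compound library (`compound_library()`) carries the nine bundled
GalNAc-siRNAs with their compound-specific bioavailability, `k_endosome`,
`kon_RISC` and PD parameters, each tagged with its provenance class
(compound-specific cell, shared merged-cell group, footnote-fixed literature
value, or running-text estimate). Where the printed table and the running
text disagree (the protein-knockdown power for the antithrombin compound:
1.5 footnote vs 1.77 estimated), the compound-specific estimate wins and the
tag records it. Merged table columns are resolved cell, then shared group,
then footnote default. Molecular weight (16 kDa) and solute radius (1 nm)
are class defaults, not per-compound measurements.

## Reconstructed mechanisms

Two pieces of the source parameterization come without a complete published
wiring and are reconstructions; they are chosen once and documented here.

* **Liver endosomal cascade.** Internalized drug-receptor complex is cleaved
  (`k_cle`) into an endosomal receptor (which recycles at `k_rec` or
  degrades at `k_deg_R`) and free endosomal siRNA, which exits at
  `k_endosome` partitioned `f_escape` to the cytoplasm and `1 - f_escape` to
  a degraded sink. Degradation of the loaded RISC complex (`k_DR`)
  regenerates free Ago2 and degrades the antisense strand, which keeps the
  total Ago2 pool exactly at `RISC_tot` along any trajectory (a tested
  invariant). TMDD species live in their physical sub-compartment volumes
  (interstitial, endosomal, intracellular); the RISC concentration that
  drives the PD is expressed on the whole liver-tissue volume, matching how
  Ago2-loaded antisense is measured (per gram of liver).
* **RNase degradation.** The source gives a degradation rate constant
  (0.00012 per hour) and tissue RNase concentrations (0.17 and 1.17 umol/L)
  without the combining rule. The package applies the bimolecular
  pseudo-first-order rate `k_RNase * [RNase]` to plasma and to the
  interstitial and endosomal drug of every non-liver tissue, the kidney
  using its own RNase concentration.

## Physiology

The source model delegates its anatomy to a platform database that the text
does not tabulate. The package therefore ships a literature-derived 0.025 kg
mouse table (`inst/extdata/mouse_physiology_organs.tsv`) assembled from
standard rodent compilations: organ volumes and plasma flows of the Brown
compilation, the large-molecule PBPK conventions of lymph flow = 0.2% of
plasma flow and endosomal space = 0.5% of organ volume, and order-of-
magnitude capillary surface-area densities. Fenestrated or discontinuous
endothelia (liver, spleen) carry a larger large-pore area fraction. Other
body weights are scaled isometrically from the reference animal — the
simplest defensible rule inside one species. Every value is curation-grade;
the file header records the conventions, and `validate_physiology()` checks
the structural invariants (positivity, lymph below plasma flow, pore-radius
ordering, flow balance against cardiac output within 1%).

## Numerics

No ODE solver package is assumed: the package carries a compiled L-stable
Rosenbrock 4(3) integrator (Kaps-Rentrop, Shampine coefficient set) with a
finite-difference Jacobian, suitable for the stiffness introduced by the
fast endosomal uptake (about 4000 per hour in the kidney) and receptor
binding (about 2800 per hour) rates next to the 1000-hour horizon.
Integration restarts at every dose event; no step interpolates across the
dosing discontinuity. Default tolerances are `rtol = 1e-8`,
`atol = 1e-10` nmol; halving them moves 1000-hour exposure metrics by far
less than 0.1% (tested). Because every transfer in the right-hand side is
booked once with opposite signs in exactly two states (sinks included),
total drug is a linear invariant of the system, and linearly implicit
Rosenbrock stages preserve it to rounding — whole-body mass balance holds to
about 1e-12 relative, audited by the test suite at 1e-6.

Degenerate inputs are handled analytically: the Peclet factor
`Pe/(exp(Pe)-1)` uses its limit 1 below `1e-10`; full steric exclusion
(`lambda >= 1`) returns zero permeability and unit reflection rather than an
error; a receptor system with `k_deg = 0` but positive synthesis has no
steady state and is rejected.

## Measurement conventions: two half-lives

The simulated profiles are multiphasic. After subcutaneous dosing the
quantifiable plasma phase is absorption-limited (flip-flop kinetics,
`ka` = 0.84 per hour); far below any realistic assay quantification limit a
very shallow tail persists, fed by the slow leak from peripheral endosomal
stores (recycling 7.7e-5 per minute times a small escape fraction past
re-uptake). Two estimators are therefore provided:

* `terminal_half_life()` — log-linear fit on the last fraction of the
  series, with optional LLOQ censoring. Used for plasma, where the
  under-4-hour half-life of this drug class describes measured profiles;
  the acceptance script censors at 0.01 ng/mL (a typical siRNA assay
  sensitivity) before fitting.
* `elimination_half_life()` — lambda-z-style decade-crossing selection: the
  regression window runs from the first post-peak crossing of one tenth of
  Cmax to the first crossing of one hundredth. Used for liver tissue, where
  a fixed late window (for example 250-1000 h) can straddle the
  `k_endosome`-driven elimination phase and the sub-ng/g redistribution
  tail, mixing two slopes. With decade selection the liver elimination
  half-life is strictly decreasing in `k_endosome` across the published
  compound range (an acceptance property); with a fixed 250-1000 h window it
  is not, because for fast-eliminating compounds that window measures the
  redistribution tail instead. Both behaviours are real features of the
  model; the package treats the decade measurement as the elimination-phase
  estimate and documents the distinction here deliberately.

## Evaluation machinery

Exposure is linear-trapezoid AUC over a window (`auc_trapezoid()`).
Model-vs-observation accuracy uses fold errors on AUC ratios:
`AFE` (geometric mean, bias) and `AAFE` (10 to the mean absolute log10
ratio, spread), with the conventional adequacy band `0.5 <= AFE <= 2`,
`AAFE <= 2`. Local sensitivity follows the normalized coefficient
`S = (dAUC/dp) * (p/AUC)` at a 10% perturbation, classified high
(`|S| >= 0.5`), medium (`>= 0.2`), low (`>= 0.1`) or insignificant. The
default difference scheme is one-sided forward, matching the +10% convention
of platform sensitivity analyses; a central option exists and is what the
oracle-equivalence test uses, since a one-sided 10% difference of `1/p`
deviates from the analytic slope by 9% purely by arithmetic.

Parameter estimation (`fit_parameters()`) is bounded nonlinear least squares
(`optim`, L-BFGS-B, log-transformed parameters). The source used an
unspecified Monte Carlo optimizer; only the objective matters to this
artifact, so a deterministic bounded optimizer was chosen deliberately.
Residuals are log-scale for concentration observables, which span decades,
and linear (fraction of baseline) for percent-scale PD observables.

## Synthetic data: what it emulates and what it does not

`generate_observations()` samples simulated observables on a schedule and
applies multiplicative log-normal noise with a chosen CV (default 15%,
typical of tissue PK assays), optionally censoring at an LLOQ (censored
records are dropped, not imputed). It emulates the sampling structure and
study-level variability of digitized mean curves. It does not emulate
between-animal variability structure, assay-specific bias between
laboratories, or digitization error — so a green parameter-recovery test
establishes that the estimation machinery is self-consistent against the
model's own data-generating process, not that the published fitted values
are recoverable from the original studies (whose observed data exist only as
digitized figures and are not redistributed here).

## Known limitations

* With the printed RISC association rate (0.00027 L/nmol/h) and Ago2 pool
  (0.3 nmol/L), simulated RISC occupancy and hence mRNA knockdown at low
  doses is modest; the PD module faithfully reproduces its stated equations
  and parameters, and its closed-form steady states, but absolute knockdown
  depths from the source figures are not an acceptance quantity and were
  not calibrated against.
* The physiology is curated, not fitted; organ-level exposure ratios inherit
  its surface-area and pore-fraction choices.
* Single species (mouse), single global partition coefficient, no
  inter-species translation, no plasma-protein-binding kinetics (binding
  assumed negligible), no Kupffer-cell or mannose-receptor uptake.
* A dose-specific bioavailability override exists for the highest-dose
  antithrombin regimen, but its value is not printed in the source; the
  override table ships empty.
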