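# galnacpbpk

Whole-body physiologically based pharmacokinetic–pharmacodynamic
(WB-PBPK-PD) modelling of GalNAc-conjugated siRNAs in the mouse.

GalNAc-siRNAs are ~16 kDa, ~1 nm-radius polyanionic duplexes whose
tri-antennary N-acetylgalactosamine ligand targets the hepatocyte
asialoglycoprotein receptor (ASGPR). Their pharmacology is defined by a
striking decoupling: plasma exposure is transient (terminal half-life under
4 h in mouse) while the liver biophase persists for hundreds of hours. This
package is an open simulator for that system, aimed at modellers who want a
mechanistic, whole-body description rather than an empirical compartment
fit:

- **Extravasation** by the two-pore formalism — per organ,
  `J_vi = fu · Σ_pore [ J(1−σ)C_v + PS(C_v − C_i/K_iv)·Pe/(e^Pe−1) ]`
  over small (4.4 nm) and large (22.85 nm) pores — plus an additional
  fitted liver permeability `fu·P_liver·SA_liver·(C_pls − C_int/Kp)`.
- **Hepatic TMDD**: reversible GalNAc–ASGPR binding
  (`dDA/dt = k_on·D_free·A_free − k_off·DA − k_int·DA`, with receptor
  turnover `k_syn = R_tot·k_deg` and endosomal recycling), endosomal
  cleavage, and a compound-specific endosomal exit `k_endosome` with 1%
  cytoplasmic escape.
- **RISC pharmacodynamics**: saturable Ago2 loading, an indirect response
  model `dmRNA/dt = k_deg·mRNA0 − (1 + Smax·C_RISC/(SC50+C_RISC))·k_deg·mRNA`,
  and protein turnover `dProt/dt = k_deg,P·(100·(mRNA/100)^γ − Prot)`.
- **Evaluation machinery**: trapezoid AUC, terminal and elimination-phase
  half-lives, AFE/AAFE fold errors, WHO-classified local sensitivity
  coefficients `S = (ΔAUC/Δp)·(p/AUC)`, bounded least-squares fitting, and
  a synthetic-observation generator with log-normal noise and LLOQ
  censoring.

A mouse physiology table, the nine-compound parameter library (with
per-parameter provenance tags) and a stiff compiled Rosenbrock ODE core are
bundled; there are no runtime dependencies beyond Rcpp/RcppArmadillo and
jsonlite.

## Worked example

Simulate 1 mg/kg subcutaneous ALN-AT3 (fitusiran) in a 25 g mouse:

```r
library(galnacpbpk)

model <- model_for_compound("ALN-AT3")
sim <- simulate_model(model, dose_event(0, "SC", 1, 0.025),
                      t_grid = seq(0, 1000, by = 2))
subset(sim$observables, time %in% c(2, 8, 24, 168, 500, 1000))
```

```
 time plasma_ng_ml    liver   RISC     mRNA  protein
    2       9.4910 179.4799 0.0000 100.0000 100.0000
    8       0.0659 207.2441 0.0000  99.9986  99.9998
   24       0.0044 171.6834 0.0002  99.9653  99.9839
  168       0.0042  31.8938 0.0011  99.5939  99.3091
  500       0.0038   2.1079 0.0005  99.7966  99.6184
 1000       0.0033   1.3516 0.0001  99.9478  99.9029
```

Plasma (ng/mL) peaks early and is absorption-rate limited; liver tissue
(nmol/L ≈ pmol/g) peaks near 8 h at ~200 nmol/L — a thousandfold plasma:liver
decoupling — then eliminates at the compound's endosomal rate. Loaded RISC
(nmol/L liver tissue) lags both, and mRNA/protein (% of baseline) respond
indirectly:

```r
obs <- sim$observables
terminal_half_life(obs$time[obs$time <= 72], obs$plasma_ng_ml[obs$time <= 72],
                   tail_fraction = 1/3, lloq = 0.01)   # 0.91 h  (< 4 h)
elimination_half_life(obs$time, obs$liver)             # 87.6 h
fold_error_metrics(c(0.52, 1.22))                      # AFE 0.796, AAFE 1.532
local_sensitivity(model, "F_bio", dose_event(0, "SC", 1, 0.025),
                  output = "liver", window = c(0, 400))$S   # 0.997 -> "high"
```

The half-life pair is the model's headline behaviour: a sub-hour measurable
plasma phase against a ~90 h liver elimination phase for `k_endosome` =
0.012 1/h. Bioavailability sensitivity of ~1 confirms dose-linear hepatic
exposure at 1 mg/kg; the same model saturates ASGPR uptake at 25 mg/kg
(dose-normalized liver AUC drops — one of the acceptance properties).

Fitting and synthetic data:

```r
entry <- compound_library()[["ALN-AT3"]]
obs <- generate_observations(entry, dose_event(0, "SC", 1, 0.025),
                             schedule = c(4, 24, 96, 250, 500, 1000),
                             measurements = "liver",
                             noise = noise_model(CV = 0.15, seed = 1))
fit_parameters(model_for_compound(entry), obs,
               free = c(k_endosome = 0.03))$estimates
```

## Command line

```sh
Rscript -e 'galnacpbpk::run_cli()' simulate --compound ALN-AT3 \
  --dose 1 --route sc --t-end 1000 --out sim.csv
Rscript -e 'galnacpbpk::run_cli()' sensitivity --compound ALN-AT3 \
  --parameter fu --dose 25 --out sens.json
```

Subcommands: `simulate`, `sensitivity`, `fit`, `generate`; exit codes
0/1/2 (success / runtime error / usage).

## Documentation

The methods vignette (`vignettes/galnac-sirna-pbpk.Rmd`) describes the model
equations and assumptions, unit conventions, the reconstructed endosomal
wiring, the bundled physiology's provenance, numerical choices, the
two-half-life measurement convention, and known limitations.
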