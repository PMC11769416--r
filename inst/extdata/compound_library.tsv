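# Compound-specific WB-PBPK-PD parameters for the bundled GalNAc-siRNA library.
# f_bio: subcutaneous bioavailability (fraction); k_endosome: endosomal degradation/escape
# rate (1/h); kon_risc: antisense-RISC association (L/nmol/h); smax / sc50_nmol_l / gamma:
# indirect-response PD parameters; kdeg_* turnover rates (1/h).
# mw_g_mol / radius_nm are class defaults (siRNA duplex ~16 kDa, ~1 nm hydrodynamic radius),
# overridable per run. regimen: published dosing, semicolon-separated route:mg/kg entries.
# Per-parameter provenance lives in compound_provenance.tsv.
compound	target	design	f_bio	k_endosome	kon_risc	smax	sc50_nmol_l	gamma	kdeg_mrna	kdeg_protein	mw_g_mol	radius_nm	regimen
ALN-AT3	antithrombin	ESC	0.401	0.012	0.00027	13.1	3.52	1.77	0.06	0.05	16000	1.0	SC:1;SC:2.5;SC:5
SIAT-2	antithrombin	ESC	0.730	0.012	0.00027	13.1	3.52	1.5	0.06	0.05	16000	1.0	SC:2.5;SC:25
SITTR-1	transthyretin	ESC	0.632	0.042	0.00027	140.2	4.07	0.42	0.06	0.05	16000	1.0	SC:0.5;SC:1.5
SITTR-2	transthyretin	ESC	0.632	0.042	0.00027	140.2	4.07	0.42	0.06	0.05	16000	1.0	SC:10;IV:10
siF7-1	factor_VII	ESC	0.102	0.010	0.00027	85.5	1.71	1.5	0.06	0.05	16000	1.0	SC:2.5
siF7-2	factor_VII	ADV-ESC	0.195	0.0066	0.00027	85.5	1.71	1.5	0.06	0.05	16000	1.0	SC:0.75
siF7-3	factor_VII	ADV-ESC	0.195	0.0066	0.00027	85.5	1.71	1.5	0.06	0.05	16000	1.0	SC:1
siF9-1	factor_IX	ESC	0.050	0.0066	0.0014	40.5	1.71	1.5	0.06	0.05	16000	1.0	SC:2.5
siF9-2	factor_IX	ADV-ESC	0.103	0.0042	0.0014	40.5	1.71	1.5	0.06	0.05	16000	1.0	SC:0.75
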