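# Per-parameter provenance for the bundled compound library.
# source: cell        = compound-specific printed value
#         shared      = shared-group (merged-column) printed value
#         footnote    = footnote-fixed literature value
#         prose       = compound-specific estimate reported in the running text
#         default     = package class default (not printed per compound)
compound	parameter	value	source
ALN-AT3	f_bio	0.401	cell
ALN-AT3	k_endosome	0.012	shared
ALN-AT3	kon_risc	0.00027	shared
ALN-AT3	smax	13.1	cell
ALN-AT3	sc50_nmol_l	3.52	cell
ALN-AT3	gamma	1.77	prose
SIAT-2	f_bio	0.730	cell
SIAT-2	k_endosome	0.012	shared
SIAT-2	kon_risc	0.00027	shared
SIAT-2	smax	13.1	shared
SIAT-2	sc50_nmol_l	3.52	shared
SIAT-2	gamma	1.5	footnote
SITTR-1	f_bio	0.632	shared
SITTR-1	k_endosome	0.042	shared
SITTR-1	kon_risc	0.00027	shared
SITTR-1	smax	140.2	shared
SITTR-1	sc50_nmol_l	4.07	shared
SITTR-1	gamma	0.42	cell
SITTR-2	f_bio	0.632	shared
SITTR-2	k_endosome	0.042	shared
SITTR-2	kon_risc	0.00027	shared
SITTR-2	smax	140.2	shared
SITTR-2	sc50_nmol_l	4.07	shared
SITTR-2	gamma	0.42	cell
siF7-1	f_bio	0.102	cell
siF7-1	k_endosome	0.010	cell
siF7-1	kon_risc	0.00027	shared
siF7-1	smax	85.5	shared
siF7-1	sc50_nmol_l	1.71	shared
siF7-1	gamma	1.5	footnote
siF7-2	f_bio	0.195	shared
siF7-2	k_endosome	0.0066	shared
siF7-2	kon_risc	0.00027	shared
siF7-2	smax	85.5	shared
siF7-2	sc50_nmol_l	1.71	shared
siF7-2	gamma	1.5	footnote
siF7-3	f_bio	0.195	shared
siF7-3	k_endosome	0.0066	shared
siF7-3	kon_risc	0.00027	shared
siF7-3	smax	85.5	shared
siF7-3	sc50_nmol_l	1.71	shared
siF7-3	gamma	1.5	footnote
siF9-1	f_bio	0.050	cell
siF9-1	k_endosome	0.0066	cell
siF9-1	kon_risc	0.0014	shared
siF9-1	smax	40.5	shared
siF9-1	sc50_nmol_l	1.71	shared
siF9-1	gamma	1.5	footnote
siF9-2	f_bio	0.103	cell
siF9-2	k_endosome	0.0042	cell
siF9-2	kon_risc	0.0014	shared
siF9-2	smax	40.5	shared
siF9-2	sc50_nmol_l	1.71	shared
siF9-2	gamma	1.5	footnote
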