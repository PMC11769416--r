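# Mouse (0.025 kg reference) organ-level physiology for large-molecule whole-body PBPK.
# Curated constants assembled from standard rodent physiology compilations
# (Brown et al. 1997 Toxicol Ind Health organ weights/flows; Shah & Betts 2012
# J Pharmacokinet Pharmacodyn large-molecule PBPK conventions: lymph flow = 0.2% of
# organ plasma flow, endosomal space = 0.5% of organ volume; capillary surface-area
# densities from Crone & Levitt 1984 Handbook of Physiology, order-of-magnitude per organ).
# Columns:
#   organ           identifier (15 perfused tissues; venous/arterial plasma pools are in the globals file)
#   v_total_ml      total organ volume, mL (density 1 g/mL assumed)
#   f_vas           vascular (plasma) volume fraction of organ
#   f_int           interstitial volume fraction of organ
#   f_endo          endothelial endosomal volume fraction of organ
#   q_plasma_ml_h   organ plasma flow, mL/h (lung row = cardiac plasma output, in series)
#   lymph_frac      lymph flow as fraction of organ plasma flow
#   sa_per_g_cm2    capillary surface-area density, cm2 per g tissue
#   r_small_nm      small-pore radius, nm
#   r_large_nm      large-pore radius, nm
#   alpha_large     fraction of transcapillary (lymph) fluid flow through large pores
#   a0_frac_large   fraction of total pore cross-sectional area in large pores
#                   (liver/spleen fenestrated/discontinuous endothelium -> large-pore rich)
#   drains_to       venous | portal (portal organs feed the liver vascular space)
organ	v_total_ml	f_vas	f_int	f_endo	q_plasma_ml_h	lymph_frac	sa_per_g_cm2	r_small_nm	r_large_nm	alpha_large	a0_frac_large	drains_to
lung	0.15	0.26	0.19	0.005	500	0.002	300	4.4	22.85	0.042	0.01	venous
heart	0.15	0.06	0.14	0.005	30	0.002	500	4.4	22.85	0.042	0.01	venous
brain	0.45	0.03	0.18	0.005	15	0.002	100	4.4	22.85	0.042	0.01	venous
muscle	9.8	0.02	0.12	0.005	105	0.002	70	4.4	22.85	0.042	0.01	venous
skin	4.0	0.02	0.30	0.005	60	0.002	70	4.4	22.85	0.042	0.01	venous
adipose	1.7	0.01	0.14	0.005	25	0.002	70	4.4	22.85	0.042	0.01	venous
bone	2.6	0.03	0.10	0.005	40	0.002	30	4.4	22.85	0.042	0.01	venous
gonads	0.10	0.03	0.12	0.005	3	0.002	100	4.4	22.85	0.042	0.01	venous
kidney	0.42	0.10	0.20	0.005	85	0.002	350	4.4	22.85	0.042	0.01	venous
liver	1.25	0.115	0.163	0.005	15	0.002	250	4.4	22.85	0.30	0.20	venous
stomach	0.40	0.03	0.10	0.005	10	0.002	100	4.4	22.85	0.042	0.01	portal
small_intestine	0.90	0.02	0.13	0.005	75	0.002	100	4.4	22.85	0.042	0.01	portal
large_intestine	0.55	0.02	0.13	0.005	20	0.002	100	4.4	22.85	0.042	0.01	portal
spleen	0.10	0.22	0.15	0.005	9	0.002	150	4.4	22.85	0.30	0.20	portal
pancreas	0.15	0.03	0.12	0.005	8	0.002	100	4.4	22.85	0.042	0.01	portal
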