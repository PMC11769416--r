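# Whole-body scalars for the reference mouse. Provenance as per the organ table header.
# pore_area_fraction / membrane_thickness_cm set the organ-scale (A0/dx) used by the
# two-pore permeability: A0/dx = SA_cap * pore_area_fraction / membrane_thickness
# (fractional pore area ~0.08% of capillary surface, endothelial path length 0.5 um;
# two-pore literature order of magnitude, Rippe & Haraldsson 1994 Physiol Rev).
key	value	unit
body_weight_kg	0.025	kg
hematocrit	0.45	fraction
cardiac_plasma_output_ml_h	500	mL/h
gfr_ml_h	15	mL/h
v_venous_ml	0.55	mL
v_arterial_ml	0.35	mL
pore_area_fraction	8e-4	fraction
membrane_thickness_cm	5e-5	cm
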