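trait	dataset	best_model	alpha	half_life
scapula_length	extant	OUM_loc3b	0.128	5.40
scapula_height	extant	OUM_loc4	0.074	9.38
humerus_length	extant	OUM_loc4	0.048	14.37
radius_length	extant	OUM_loc4	0.043	16.08
ulna_length	extant	OUM_loc4	0.070	9.96
ulna_olecranon_length	extant	OUM_loc3a	0.084	8.30
metacarpal_length	extant	OUM_loc3c	0.010	69.78
prox_phalanx_length	extant	OUM_loc4	0.022	30.86
intermed_phalanx_length	extant	OUM_loc4	0.032	21.52
humerus_proximal_width	extant	OUM_loc3b	0.096	7.24
humerus_shaft_width	extant	OUM_loc3b	0.097	7.17
humerus_distal_width	extant	OUM_loc3b	0.035	19.60
metacarpal_width	extant	OUM_loc3b	0.034	20.12
scapula_length	extant_extinct	OUM_loc3b	0.134	5.16
scapula_height	extant_extinct	OUM_loc3a	0.064	10.79
humerus_length	extant_extinct	OUM_loc4	0.050	13.86
radius_length	extant_extinct	OUM_loc4	0.075	9.26
ulna_length	extant_extinct	OUM_loc4	0.101	6.84
ulna_olecranon_length	extant_extinct	OUM_loc4	0.102	6.81
metacarpal_length	extant_extinct	OUM_loc3b	0.013	51.70
prox_phalanx_length	extant_extinct	OUM_loc4	0.024	29.40
intermed_phalanx_length	extant_extinct	OUM_loc4	0.036	19.03
humerus_proximal_width	extant_extinct	OUM_loc3a	0.094	7.35
humerus_shaft_width	extant_extinct	OUM_loc3b	0.087	7.94
humerus_distal_width	extant_extinct	OUM_loc3b	0.028	24.80
metacarpal_width	extant_extinct	OUM_loc3b	0.031	22.47
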