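# SYNTHETIC placeholder burst-swimming-speed quantiles -- NOT biological data.
# Published swimming-performance lookup tables are licensed and are not
# redistributed here; replace this file with real quantiles (same columns)
# before using the package for a real assessment.
# Columns: length_m, 10th/50th/90th percentile burst speed (m/s), season,
# water temperature (degrees C).
length_m	q10	q50	q90	season	temperature_C
0.05	0.15	0.38	0.70	spring	21.8
0.06	0.19	0.43	0.78	spring	21.8
0.07	0.24	0.48	0.86	spring	21.8
0.08	0.30	0.54	0.95	spring	21.8
0.09	0.36	0.60	1.04	spring	21.8
0.10	0.42	0.66	1.14	spring	21.8
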