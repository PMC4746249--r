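# Literature compilation of bulk carbon and hydrogen enrichment factors
# (permil, with 95% CI half-widths and regression R2) for anaerobic and
# aerobic benzene biodegradation, one row per culture/condition.
# Columns: culture_label, culture_type {pure, mixed}, condition, initial
# benzene (uM), epsilon_C +/- ci (permil), R2, epsilon_H +/- ci (permil),
# R2, source key (opaque tag grouping rows from a shared literature source).
culture_label	culture_type	condition	initial_benzene_uM	epsilon_C	epsilon_C_ci95	epsilon_C_r2	epsilon_H	epsilon_H_ci95	epsilon_H_r2	source
Ralstonia picketti VKOl(omc)	pure	oxic	885	-1.7	0.2	0.98	-11	4	0.86	lit-A
Cupriavidus necator ATCC 17697 (oxic)	pure	oxic	1180	-4.3	0.4	0.99	-17	11	0.89	lit-A
Burkholderia sp. (oxic)	pure	oxic	700	-3.5	0.3	0.97	-11	2	0.91	lit-B
Acinetobacter sp. (oxic)	pure	oxic	700	-1.5	0.8	0.99	-13	1	0.99	lit-B
Azoarcus denitrificans strain BC (oxic)	pure	oxic	603	-2.6	0.8	0.97	-16	4	0.97	lit-A
A. denitrifans strain BC (Chlorate-reducing)	pure	chlorate-reducing	462	-1.5	0.5	0.86	-28	6	0.98	lit-A
Nitrate-reducing, mixed negative	mixed	nitrate-reducing	250	-2.2	0.4	0.98	-35	6	0.91	lit-C
Sulfate-reducing, mixed negative	mixed	sulfate-reducing	192	-3.6	0.3	0.92	-79	4	0.79	lit-C
Sulfate-reducing, mixed negative	mixed	sulfate-reducing	192	-1.9	0.3	0.97	-59	10	0.99	lit-A
Methanogenic, mixed negative	mixed	methanogenic	750	-1.9	0.1	0.98	-60	3	0.92	lit-C
Methanogenic, mixed negative	mixed	methanogenic	900	-0.8	0.2	0.93	-34	8	0.88	lit-D
Methanogenic, mixed negative	mixed	methanogenic	450	-1.1	0.1	0.88	-38	6	0.80	lit-D
Sulfate-reducing, enriched positive	mixed	sulfate-reducing	450	-2.5	0.2	0.97	-55	4	0.93	lit-E
Iron-reducing, enriched positive	mixed	iron-reducing	200	-3.0	0.5	0.93	-56	8	0.93	lit-E
Sulfate-reducing, enriched positive (deep aquifer consortium)	mixed	sulfate-reducing	400	-2.4	0.3	0.91	-57	0.0	0.98	this-work
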