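trait	chromosome	peak_marker	peak_cm	lod	lod_threshold	additive	dominance	r2_percent
Visual wax_Rep1	Chr07K	Tag_8032	13.4	14.4	4.0	0.239	-0.016	15.6
Visual wax_Rep2	Chr07K	Tag_7893	0	19.1	4.1	0.474	-0.065	23.6
Visual wax_Rep3	Chr07K	Tag_7893	0	15.0	3.9	0.349	-0.040	20.3
Visual wax_Rep1	Chr09K	Tag_12092	18	4.3	4.0	0.093	0.054	4.8
Contact angle_5cm	Chr06N	Tag_7555	40.5	4.2	4.0	7.261	7.389	8.9
Contact angle_5cm	Chr07K	Tag_7893	0	11.2	4.0	21.245	0.407	26.9
Contact angle_6cm	Chr07K	Tag_7893	0	14.9	4.2	24.065	-2.026	34.1
Contact angle_7cm	Chr07K	Tag_7893	0	14.7	4.2	23.464	-4.481	35.2
Contact angle_8cm	Chr07K	Tag_7893	0	13.4	4.1	23.552	-8.244	31.9
Contact angle_9cm	Chr07K	Tag_7893	0	14.1	4.2	23.921	-8.380	34.4
Contact angle_6cm	Chr09K	Tag_11633	90.5	5.8	4.2	-14.769	16.224	10.7
Contact angle_9cm	Chr05K	Tag_6067	0	4.4	4.2	13.703	-8.595	9.2
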