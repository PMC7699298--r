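# pooled serum small-RNA-seq example: average copies per pool replicate, three patient groups sequenced in duplicate
mirna_id	Metastatic_1	Metastatic_2	Tumor_1	Tumor_2	Healthy_1	Healthy_2
hsa-miR-3614-5p	588.15	602.64	0	0	0	0
hsa-miR-1247-5p	923.17	124.99	0	0	0	0
hsa-miR-26b-3p	405.75	0	693.60	0	0	0
hsa-miR-370-3p	930.61	138.38	0	0	0	0
hsa-miR-371b-5p	655.15	196.42	0	0	0	0
hsa-miR-92a-1-5p	201.01	620.50	0	0	0	0
hsa-miR-1343-3p	0	178.56	0	449.91	0	0
hsa-let-7b-3p	450.42	111.60	0	0	0	0
hsa-miR-3130-5p	171.23	0	610.03	0	0	0
hsa-miR-93-5p	23101.53	21016.67	18685.45	26506.86	47283.15	57832.90
hsa-miR-223-3p	355620.64	417538.85	288671.90	294471.36	175026.35	162243.02
hsa-miR-431-5p	0	0	0	0	660.62	748.75
hsa-miR-320a	129310.50	120542.28	57794.55	53603.04	191473.93	241138.63
hsa-miR-486-5p	708832.85	796133.48	937832.71	815698.98	1422293.08	1307148.95
hsa-miR-628-3p	416.91	437.47	434.54	183.78	0	0
hsa-miR-7-1-3p	0	441.94	626.75	1184.98	0	0
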