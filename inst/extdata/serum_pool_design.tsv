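# sample-to-group design for the pooled serum example
sample_id	group
Metastatic_1	metastatic
Metastatic_2	metastatic
Tumor_1	tumor
Tumor_2	tumor
Healthy_1	non_tumor
Healthy_2	non_tumor
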