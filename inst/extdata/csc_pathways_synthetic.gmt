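Wnt	synthetic membership of CSC-relevant genes	FRZB	TCF7L2	WNT10A	FZD8	CDX2
Notch	synthetic membership of CSC-relevant genes	NRCAM	JUN	KDM4C	EP300
Hedgehog	synthetic membership of CSC-relevant genes	PLK1	PPARD	STAT3	KLF4
TGFb	synthetic membership of CSC-relevant genes	SMAD4	NFATC1	NODAL
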