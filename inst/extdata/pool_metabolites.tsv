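id	name
C00080	H+
C00001	H2O
C00009	Orthophosphate
C00002	ATP
C00003	NAD+
C00004	NADH
C00008	ADP
C00011	CO2
C00010	CoA
C00006	NADP+
C00005	NADPH
C00014	NH3
C00013	Diphosphate
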