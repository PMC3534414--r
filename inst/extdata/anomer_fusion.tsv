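anomer	canonical
C00267	C00031
C00221	C00031
C00984	C00124
C00962	C00124
C02336	C00095
C00936	C00159
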