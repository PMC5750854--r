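symbol	aliases
DRD2	DRD2|D2R
CHRNA4	CHRNA4
CHRNB2	CHRNB2|NACHRB2
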