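association,linkage,expression,core
CHRNA4,CHRNA4,CHRNB2,CHRNA4
CHRNB2,CHRNB2,DRD2,CHRNB2
DRD2,GABRA2,SLC6A3,DRD2
DRD4,NTRK2,NTRK2,CHRNA5
CHRNA5,CHRNA5,COMT,
GABRA2,TAS2R38,MAOA,
COMT,,BDNF,
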