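PMID- 1001
TI  - CHRNA4 receptor variants and nicotine dependence
AB  - We examined CHRNA4 polymorphisms in a smoking cohort and found
      an association with nicotine dependence severity.

PMID- 1002
TI  - Dopamine D2R signalling after chronic nicotine
AB  - Chronic nicotine exposure altered D2R availability in striatum.

PMID- 1003
TI  - DRD2 Taq1A and smoking cessation outcomes
AB  - DRD2 genotype predicted response to nicotine replacement therapy.

PMID- 1004
TI  - NACHRB2 knockout mice and nicotinic responses
AB  - Mice lacking NACHRB2 showed blunted nicotinic currents.

PMID- 1005
TI  - A proteomic survey of cortical synapses
AB  - Unrelated control document about synaptic proteins.
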