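species,concentration_uM
TNFa,0.2
TNFR1,0.1
TNFR1A,0.2
TRAFs,0.3
IKKK,0.2
IKK,0.2
NFkB,0.005
IkB,0.02
IkB_NFkB,0.9
IkBn,0.002
IkBn_NFkBn,0.005
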