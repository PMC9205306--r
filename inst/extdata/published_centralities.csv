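trait,forest,betweenness,closeness,degree
SLA,moist,0.00,0.60,0.33
LTh,moist,0.00,0.56,0.33
LWC,moist,0.41,0.82,0.77
MPU,moist,0.00,0.56,0.33
WD,moist,0.13,0.69,0.55
SWC,moist,0.06,0.69,0.55
SRL,moist,0.16,0.69,0.55
RTh,moist,0.00,0.47,0.22
RD,moist,0.08,0.60,0.44
MRD,moist,0.00,0.47,0.11
SLA,dry,0.00,0.50,0.11
LTh,dry,0.00,0.64,0.55
LWC,dry,0.48,0.90,0.88
MPU,dry,0.00,0.64,0.55
WD,dry,0.00,0.64,0.55
SWC,dry,0.09,0.75,0.66
SRL,dry,0.00,0.43,0.22
RTh,dry,0.14,0.64,0.44
RD,dry,0.06,0.60,0.33
MRD,dry,0.00,0.64,0.55
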