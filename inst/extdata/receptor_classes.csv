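receptor_id,gpcr_class
CCR1,A
CCR2,A
CCR6,A
CXCR2,A
CXCR3,A
CRF1R,B
GCGR,B
GLP1R,B
GIPR,B
VPAC2,B
GHRHR,B
SCTR,B
AM,B
AMY,B
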