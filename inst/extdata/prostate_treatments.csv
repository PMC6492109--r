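treatment,class,label
A,control,observational management
B,nonpharmacological,prostatectomy
C,nonpharmacological,conventional radiotherapy
D,nonpharmacological,conventional radiotherapy hypofractionated
E,nonpharmacological,conformal low-dose radiotherapy
F,nonpharmacological,conformal high-dose radiotherapy
G,nonpharmacological,conformal low-dose radiotherapy hypofractionated
H,nonpharmacological,cryotherapy
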