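gene,efficiencyPct,rSquared
GAPDH,88.1,0.999
H2B,92.0,0.999
TIP41,94.1,0.994
18S,90.5,0.998
IDH,87.7,0.999
PXMP2,101.4,0.999
RCA,102.7,0.996
UBC2,84.6,0.998
RPL2,100.9,0.999
DnaJ,95.9,0.999
TUBalpha,87.4,0.994
TUBbeta,106.0,0.998
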