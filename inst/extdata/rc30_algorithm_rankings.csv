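algorithm,gene,position,printed
geNorm,H2B,1,TRUE
geNorm,18S,1,TRUE
geNorm,TIP41,2,TRUE
geNorm,RCA,3,TRUE
geNorm,GAPDH,4,TRUE
geNorm,IDH,5,FALSE
geNorm,PXMP2,6,FALSE
geNorm,UBC2,7,FALSE
geNorm,RPL2,8,FALSE
geNorm,DnaJ,9,FALSE
geNorm,TUBalpha,10,FALSE
geNorm,TUBbeta,11,FALSE
NormFinder,TIP41,1,TRUE
NormFinder,GAPDH,2,TRUE
NormFinder,H2B,3,TRUE
NormFinder,18S,4,TRUE
NormFinder,IDH,5,FALSE
NormFinder,PXMP2,6,FALSE
NormFinder,RCA,7,FALSE
NormFinder,UBC2,8,FALSE
NormFinder,RPL2,9,FALSE
NormFinder,DnaJ,10,FALSE
NormFinder,TUBalpha,11,FALSE
NormFinder,TUBbeta,12,FALSE
BestKeeper,18S,1,TRUE
BestKeeper,H2B,2,TRUE
BestKeeper,IDH,3,TRUE
BestKeeper,GAPDH,4,TRUE
BestKeeper,TIP41,5,FALSE
BestKeeper,PXMP2,6,FALSE
BestKeeper,RCA,7,FALSE
BestKeeper,UBC2,8,FALSE
BestKeeper,RPL2,9,FALSE
BestKeeper,DnaJ,10,FALSE
BestKeeper,TUBalpha,11,FALSE
BestKeeper,TUBbeta,12,FALSE
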