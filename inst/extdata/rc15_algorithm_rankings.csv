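algorithm,gene,position,printed
geNorm,H2B,1,TRUE
geNorm,UBC2,1,TRUE
geNorm,RPL2,2,TRUE
geNorm,IDH,3,TRUE
geNorm,RCA,4,TRUE
geNorm,GAPDH,5,FALSE
geNorm,TIP41,6,FALSE
geNorm,18S,7,FALSE
geNorm,PXMP2,8,FALSE
geNorm,DnaJ,9,FALSE
geNorm,TUBalpha,10,FALSE
geNorm,TUBbeta,11,FALSE
NormFinder,IDH,1,TRUE
NormFinder,GAPDH,2,TRUE
NormFinder,DnaJ,3,TRUE
NormFinder,RCA,4,TRUE
NormFinder,H2B,5,FALSE
NormFinder,TIP41,6,FALSE
NormFinder,18S,7,FALSE
NormFinder,PXMP2,8,FALSE
NormFinder,UBC2,9,FALSE
NormFinder,RPL2,10,FALSE
NormFinder,TUBalpha,11,FALSE
NormFinder,TUBbeta,12,FALSE
BestKeeper,IDH,1,TRUE
BestKeeper,RCA,2,TRUE
BestKeeper,UBC2,3,TRUE
BestKeeper,RPL2,4,TRUE
BestKeeper,GAPDH,5,FALSE
BestKeeper,H2B,6,FALSE
BestKeeper,TIP41,7,FALSE
BestKeeper,18S,8,FALSE
BestKeeper,PXMP2,9,FALSE
BestKeeper,DnaJ,10,FALSE
BestKeeper,TUBalpha,11,FALSE
BestKeeper,TUBbeta,12,FALSE
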