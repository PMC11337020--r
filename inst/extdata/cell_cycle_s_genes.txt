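ATAD2
BRIP1
CCNE2
CDC45
CDC6
CDCA7
CHAF1B
CLSPN
DSCC1
DTL
E2F8
EXO1
FEN1
GINS2
GMNN
HELLS
MCM2
MCM4
MCM5
MCM6
MSH2
NASP
PCNA
POLA1
POLD3
PRIM1
RAD51
RAD51AP1
RFC2
RPA2
RRM1
RRM2
SLBP
TIPIN
TYMS
UBR7
UHRF1
UNG
USP1
WDR76
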