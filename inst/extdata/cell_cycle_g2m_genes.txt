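ANLN
ANP32E
AURKA
AURKB
BIRC5
BUB1
CBX5
CCNB2
CDC20
CDC25C
CDCA2
CDCA3
CDCA8
CDK1
CENPA
CENPE
CENPF
CKAP2
CKAP2L
CKAP5
CKS1B
CKS2
CTCF
DLGAP5
ECT2
G2E3
GAS2L3
GTSE1
HJURP
HMGB2
HMMR
KIF11
KIF20B
KIF23
KIF2C
LBR
MKI67
NCAPD2
NDC80
NEK2
NUF2
NUSAP1
PSRC1
RANGAP1
SMC4
TACC3
TMPO
TOP2A
TPX2
TTK
TUBB4B
UBE2C
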