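gene	direction
KLK3	up
KLK2	up
TMPRSS2	up
NKX3-1	up
FKBP5	up
PMEPA1	up
PART1	up
ALDH1A3	up
NDRG1	up
PLPP1	up
ABCC4	up
ACSL3	up
ADAM7	up
C1orf116	up
EAF2	up
ELL2	up
GNMT	up
HERC3	up
MED28	up
MPHOSPH9	up
PTGER4	up
SLC26A2	up
ZBTB10	up
MAF	down
NNMT	down
SNAI2	down
TNK1	down
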