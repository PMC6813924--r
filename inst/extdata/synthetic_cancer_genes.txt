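SETBP1
C7ORF34
RISKG1
RISKG2
RISKG3
BRCA1
BRCA2
ATM
CHEK2
PALB2
TP53
PTEN
STK11
CDH1
NF1
BARD1
MEN1
GENE0001
GENE0002
GENE0003
GENE0004
GENE0005
GENE0006
GENE0007
GENE0008
GENE0009
GENE0010
GENE0011
GENE0012
GENE0013
GENE0014
GENE0015
GENE0016
GENE0017
GENE0018
GENE0019
GENE0020
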