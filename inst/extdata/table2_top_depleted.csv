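condition,gene
CX5461_IC50,ALKBH1
CX5461_IC50,ATM
CX5461_IC50,ATR
CX5461_IC50,BARD1
CX5461_IC50,BRCA2
CX5461_IC50,H2AFX
CX5461_IC50,LIG4
CX5461_IC50,MMS22L
CX5461_IC50,MUS81
CX5461_IC50,OXR1
CX5461_IC50,PALB2
CX5461_IC50,POLH
CX5461_IC50,POLQ
CX5461_IC50,PSMB4
CX5461_IC50,PSMC4
CX5461_IC50,PSMC5
CX5461_IC50,RAD21
CX5461_IC50,RAD51
CX5461_IC50,RAD51B
CX5461_IC50,RAD54B
CX5461_IC50,RAD54L
CX5461_IC50,RAD9A
CX5461_IC50,REV1
CX5461_IC50,RNF168
CX5461_IC50,STAG2
CX5461_IC50,UBE2N
CX5461_IC50,XPA
CX5461_IC30,ABCF2
CX5461_IC30,ATM
CX5461_IC30,ATR
CX5461_IC30,BARD1
CX5461_IC30,CDC20
CX5461_IC30,CINP
CX5461_IC30,DNA2
CX5461_IC30,ERCC5
CX5461_IC30,H2AFX
CX5461_IC30,LIG4
CX5461_IC30,MCM9
CX5461_IC30,MDC1
CX5461_IC30,POLL
CX5461_IC30,POLQ
CX5461_IC30,RAD21
CX5461_IC30,RAD51
CX5461_IC30,RAD54L
CX5461_IC30,RAD9A
CX5461_IC30,REV1
CX5461_IC30,RNF168
CX5461_IC30,SF3B3
CX5461_IC30,SPO11
CX5461_IC30,UBE2N
CX5461_IC30,XPA
CX5461_IC30,XRCC2
PDS_IC50,APITD1
PDS_IC50,ATM
PDS_IC50,BRCC3
PDS_IC50,CDC20
PDS_IC50,CHTF18
PDS_IC50,EME1
PDS_IC50,EP300
PDS_IC50,GAPDH
PDS_IC50,GTF2H2
PDS_IC50,H2AFX
PDS_IC50,HUS1
PDS_IC50,IGF1
PDS_IC50,LIG4
PDS_IC50,MUS81
PDS_IC50,POLQ
PDS_IC50,PPP4R2
PDS_IC50,PRIM2
PDS_IC50,PSMA5
PDS_IC50,RAD51
PDS_IC50,RAD51B
PDS_IC50,RAD52
PDS_IC50,RAD54L
PDS_IC50,RAD9A
PDS_IC50,RNF168
PDS_IC50,TRRAP
PDS_IC50,UBE2C
PDS_IC30,APITD1
PDS_IC30,ATM
PDS_IC30,BARD1
PDS_IC30,BRCA2
PDS_IC30,CDC20
PDS_IC30,EP300
PDS_IC30,FANCL
PDS_IC30,H2AFX
PDS_IC30,HAUS5
PDS_IC30,INO80
PDS_IC30,INO80E
PDS_IC30,LIG4
PDS_IC30,MMS22L
PDS_IC30,MUS81
PDS_IC30,PALB2
PDS_IC30,PCNA
PDS_IC30,PNKP
PDS_IC30,POLQ
PDS_IC30,PSMB4
PDS_IC30,PSMB5
PDS_IC30,RAD21
PDS_IC30,RAD51
PDS_IC30,RAD51B
PDS_IC30,RAD52
PDS_IC30,RAD54L
PDS_IC30,RAD9A
PDS_IC30,RNF168
PDS_IC30,SMC1A
PDS_IC30,UBE2C
PDS_IC30,WEE1
PDS_IC30,XRCC2
BMH21_IC30,ANAPC15
BMH21_IC30,BCL2
BMH21_IC30,CDC20
BMH21_IC30,CEP192
BMH21_IC30,CHEK1
BMH21_IC30,IGHMBP2
BMH21_IC30,MCM6
BMH21_IC30,PMS2
BMH21_IC30,PNKP
BMH21_IC30,POLD4
BMH21_IC30,POLE2
BMH21_IC30,POLR2B
BMH21_IC30,POLR2L
BMH21_IC30,RAD23B
BMH21_IC30,RAD51
BMH21_IC30,RAD9A
BMH21_IC30,RDM1
BMH21_IC30,RFC4
BMH21_IC30,SUPT3H
BMH21_IC30,TAOK1
BMH21_IC30,TOPBP1
BMH21_IC30,UBB
BMH21_IC30,USP44
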