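gene,pathway,all,e1,e2,a1,a2,na
FGFR4,FGFR4/RAS/AKT,5,0,4,0,0,1
PTPN11,FGFR4/RAS/AKT,2,0,2,0,0,0
GAB1,FGFR4/RAS/AKT,3,0,0,2,0,1
PIK3CA,FGFR4/RAS/AKT,3,0,2,0,0,1
PTEN,FGFR4/RAS/AKT,2,0,1,1,0,0
HRAS,FGFR4/RAS/AKT,1,0,0,0,1,0
KRAS,FGFR4/RAS/AKT,2,2,0,0,0,0
NRAS,FGFR4/RAS/AKT,7,2,2,1,0,2
NF1,FGFR4/RAS/AKT,3,1,2,0,0,0
TP53,NA,9,0,5,2,1,1
FBXW7,NA,1,0,1,0,0,0
BCOR,NA,5,3,1,1,0,1
ARID1A,NA,6,0,3,1,0,2
ROBO1,NA,2,0,0,1,0,1
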