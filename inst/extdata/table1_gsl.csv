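line,group,compound,mean,sd
Chiffu,reference,GRA,ND,
Chiffu,reference,GAL,ND,
Chiffu,reference,SNG,ND,
Chiffu,reference,GNA,0.00,
Chiffu,reference,GBN,0.00,
Chiffu,reference,GNL,0.00,
Chiffu,reference,PRO,0.38,0.00
Chiffu,reference,GBS,4.00,0.26
Chiffu,reference,4-MOGBS,1.09,0.04
Chiffu,reference,NGBS,3.16,0.52
Chiffu,reference,GNT,0.14,0.09
LP08,parent,GRA,0.11,0.05
LP08,parent,GAL,0.55,0.05
LP08,parent,SNG,0.17,0.00
LP08,parent,GNA,43.40,3.63
LP08,parent,GBN,0.66,0.06
LP08,parent,GNL,0.00,
LP08,parent,PRO,0.71,0.06
LP08,parent,GBS,0.40,0.01
LP08,parent,4-MOGBS,0.31,0.04
LP08,parent,NGBS,0.76,0.06
LP08,parent,GNT,0.47,0.14
LP21,parent,GRA,0.00,
LP21,parent,GAL,0.89,0.10
LP21,parent,SNG,0.00,
LP21,parent,GNA,1.82,0.66
LP21,parent,GBN,0.00,
LP21,parent,GNL,0.27,0.03
LP21,parent,PRO,0.88,0.09
LP21,parent,GBS,2.03,0.02
LP21,parent,4-MOGBS,0.63,0.03
LP21,parent,NGBS,3.44,0.24
LP21,parent,GNT,0.81,0.09
F1,f1,GRA,0.10,0.01
F1,f1,GAL,0.85,0.12
F1,f1,SNG,0.00,
F1,f1,GNA,1.97,0.16
F1,f1,GBN,1.68,0.14
F1,f1,GNL,0.34,0.03
F1,f1,PRO,3.86,0.29
F1,f1,GBS,0.59,0.02
F1,f1,4-MOGBS,0.64,0.03
F1,f1,NGBS,4.58,0.16
F1,f1,GNT,0.47,0.05
BrYSP_DH005,high,GRA,1.23,0.18
BrYSP_DH005,high,GAL,3.47,0.18
BrYSP_DH005,high,SNG,0.05,0.01
BrYSP_DH005,high,GNA,35.51,2.84
BrYSP_DH005,high,GBN,0.63,0.04
BrYSP_DH005,high,GNL,0.10,0.04
BrYSP_DH005,high,PRO,0.22,0.03
BrYSP_DH005,high,GBS,0.14,0.00
BrYSP_DH005,high,4-MOGBS,0.06,0.00
BrYSP_DH005,high,NGBS,2.03,0.20
BrYSP_DH005,high,GNT,0.68,0.34
BrYSP_DH014,high,GRA,0.07,0.02
BrYSP_DH014,high,GAL,2.16,0.05
BrYSP_DH014,high,SNG,0.05,0.01
BrYSP_DH014,high,GNA,45.19,2.69
BrYSP_DH014,high,GBN,7.13,0.62
BrYSP_DH014,high,GNL,0.02,0.01
BrYSP_DH014,high,PRO,0.06,0.02
BrYSP_DH014,high,GBS,0.11,0.01
BrYSP_DH014,high,4-MOGBS,0.10,0.01
BrYSP_DH014,high,NGBS,0.77,0.04
BrYSP_DH014,high,GNT,0.39,0.04
BrYSP_DH016,high,GRA,0.12,0.07
BrYSP_DH016,high,GAL,0.43,0.05
BrYSP_DH016,high,SNG,0.11,0.07
BrYSP_DH016,high,GNA,44.42,1.34
BrYSP_DH016,high,GBN,1.68,0.07
BrYSP_DH016,high,GNL,ND,
BrYSP_DH016,high,PRO,0.57,0.37
BrYSP_DH016,high,GBS,0.20,0.01
BrYSP_DH016,high,4-MOGBS,0.16,0.01
BrYSP_DH016,high,NGBS,0.76,0.02
BrYSP_DH016,high,GNT,0.24,0.03
BrYSP_DH017,high,GRA,0.07,0.01
BrYSP_DH017,high,GAL,0.62,0.17
BrYSP_DH017,high,SNG,0.08,0.02
BrYSP_DH017,high,GNA,45.66,1.25
BrYSP_DH017,high,GBN,2.70,0.09
BrYSP_DH017,high,GNL,0.10,0.11
BrYSP_DH017,high,PRO,0.32,0.03
BrYSP_DH017,high,GBS,0.19,0.01
BrYSP_DH017,high,4-MOGBS,0.19,0.02
BrYSP_DH017,high,NGBS,0.50,0.02
BrYSP_DH017,high,GNT,0.20,0.01
BrYSP_DH026,high,GRA,0.09,0.02
BrYSP_DH026,high,GAL,2.05,0.04
BrYSP_DH026,high,SNG,0.07,0.04
BrYSP_DH026,high,GNA,48.23,1.31
BrYSP_DH026,high,GBN,5.39,0.25
BrYSP_DH026,high,GNL,0.03,0.02
BrYSP_DH026,high,PRO,0.05,0.00
BrYSP_DH026,high,GBS,0.08,0.00
BrYSP_DH026,high,4-MOGBS,0.11,0.00
BrYSP_DH026,high,NGBS,0.57,0.05
BrYSP_DH026,high,GNT,0.39,0.03
BrYSP_DH009,low,GRA,0.04,0.03
BrYSP_DH009,low,GAL,1.16,0.10
BrYSP_DH009,low,SNG,0.00,0.00
BrYSP_DH009,low,GNA,0.25,0.05
BrYSP_DH009,low,GBN,0.26,0.07
BrYSP_DH009,low,GNL,0.09,0.03
BrYSP_DH009,low,PRO,0.82,0.26
BrYSP_DH009,low,GBS,0.12,0.02
BrYSP_DH009,low,4-MOGBS,0.10,0.01
BrYSP_DH009,low,NGBS,0.33,0.03
BrYSP_DH009,low,GNT,0.08,0.03
BrYSP_DH059,low,GRA,0.06,0.01
BrYSP_DH059,low,GAL,1.44,0.19
BrYSP_DH059,low,SNG,0.01,0.01
BrYSP_DH059,low,GNA,0.32,0.06
BrYSP_DH059,low,GBN,0.52,0.08
BrYSP_DH059,low,GNL,0.30,0.03
BrYSP_DH059,low,PRO,1.97,0.23
BrYSP_DH059,low,GBS,0.10,0.02
BrYSP_DH059,low,4-MOGBS,0.07,0.01
BrYSP_DH059,low,NGBS,0.38,0.03
BrYSP_DH059,low,GNT,0.15,0.02
BrYSP_DH061,low,GRA,ND,
BrYSP_DH061,low,GAL,1.13,0.26
BrYSP_DH061,low,SNG,0.01,0.01
BrYSP_DH061,low,GNA,2.35,0.81
BrYSP_DH061,low,GBN,1.70,0.64
BrYSP_DH061,low,GNL,0.00,0.00
BrYSP_DH061,low,PRO,0.05,0.01
BrYSP_DH061,low,GBS,0.05,0.01
BrYSP_DH061,low,4-MOGBS,0.01,0.00
BrYSP_DH061,low,NGBS,0.11,0.02
BrYSP_DH061,low,GNT,0.23,0.07
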