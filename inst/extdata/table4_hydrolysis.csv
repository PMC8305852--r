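line,compound,mean,sd
BrYSP_DH005,BITC,601.0,16.8
BrYSP_DH005,4-PEITC,47.7,1.3
BrYSP_DH005,2-PEITC,40.8,0.8
BrYSP_DH005,SFN,20.24,1.33
BrYSP_DH014,BITC,778.8,32.9
BrYSP_DH014,4-PEITC,64.5,3.9
BrYSP_DH014,2-PEITC,25.0,1.2
BrYSP_DH014,SFN,2.03,0.15
BrYSP_DH016,BITC,425.1,10.0
BrYSP_DH016,4-PEITC,100.1,2.5
BrYSP_DH016,2-PEITC,18.5,0.7
BrYSP_DH016,SFN,2.90,0.13
BrYSP_DH017,BITC,281.7,15.3
BrYSP_DH017,4-PEITC,120.7,5.3
BrYSP_DH017,2-PEITC,12.7,0.8
BrYSP_DH017,SFN,2.35,0.21
BrYSP_DH026,BITC,653.0,20.8
BrYSP_DH026,4-PEITC,94.0,2.3
BrYSP_DH026,2-PEITC,34.5,0.5
BrYSP_DH026,SFN,2.39,0.15
pak_choi,BITC,108.9,2.7
pak_choi,4-PEITC,21.6,0.6
pak_choi,2-PEITC,8.1,0.2
pak_choi,SFN,0.57,0.04
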