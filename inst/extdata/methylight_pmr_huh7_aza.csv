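dose_label,aza_um,mec_intensity,alu_pmr,sat2_pmr,sata_pmr
No Drug,0,1.00,1.00,1.00,1.00
0.5 uM,0.5,0.72,0.92,0.86,0.37
1 uM,1,0.34,0.49,0.65,0.20
2.5 uM,2.5,0.26,0.51,0.69,0.42
5 uM,5,0.20,0.31,0.31,0.15
10 uM,10,0.14,0.17,0.45,0.22
20 uM,20,0.13,0.61,0.58,0.88
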