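metal,background,plant_limit,toxicity,screening
Cr,49.30,2.00,2,250.00
Cu,26.70,45.80,5,100.00
Zn,68.80,100.00,1,300.00
Cd,0.12,0.20,30,0.60
Pb,19.40,3.00,5,170.00
Hg,0.02,0.01,40,3.40
As,11.20,5.00,10,25.00
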