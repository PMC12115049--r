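metal,max,min,median,mean,cv_percent,kurtosis,skewness,sd,background,screening
Cr,95.90,16.30,42.40,44.38,35.10,2.43,1.05,15.59,49.30,250.00
Cu,50.30,5.10,21.40,20.89,47.85,0.98,0.70,10.14,26.70,100.00
Zn,90.60,30.10,56.60,55.95,22.53,0.45,0.70,12.65,68.80,300.00
Cd,0.26,0.03,0.13,0.13,45.34,-0.54,0.15,0.056,0.12,0.60
Pb,19.30,10.10,17.50,16.93,11.03,3.35,-1.51,1.87,19.40,170.00
Hg,0.02,0.003,0.009,0.0093,41.64,0.78,0.69,0.00383,0.02,3.40
As,21.40,1.73,6.64,6.95,59.13,5.30,1.93,4.14,11.20,25.00
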