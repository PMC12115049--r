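species,metal,max,min,median,mean,cv_percent,limit
Anabasis aphylla,Cr,480,16.2,326,294.24,60.12,2.00
Anabasis aphylla,Cu,10.5,2.56,7.01,6.51,49.59,45.80
Anabasis aphylla,Zn,18.6,3.82,13,11.63,49.30,100.00
Anabasis aphylla,Cd,0.31,0.06,0.15,0.17,54.94,0.20
Anabasis aphylla,Pb,3.13,0.44,1.77,1.91,61.23,3.00
Anabasis aphylla,Hg,0.02,0.007,0.011,0.01,42.93,0.01
Anabasis aphylla,As,2.65,0.1,1.56,1.53,71.17,5.00
Alhagi camelorum,Cr,135,11.7,59.6,70.10,52.44,2.00
Alhagi camelorum,Cu,5.06,1.98,3.96,3.78,28.14,45.80
Alhagi camelorum,Zn,6.45,2.74,4.72,4.89,24.01,100.00
Alhagi camelorum,Cd,0.1,0.02,0.06,0.06,43.96,0.20
Alhagi camelorum,Pb,1.17,0.18,0.63,0.65,41.52,3.00
Alhagi camelorum,Hg,0.024,0.004,0.01,0.01,56.06,0.01
Alhagi camelorum,As,0.93,0.2,0.41,0.46,43.62,5.00
Reaumuria songonica,Cr,175.00,86.50,90.00,115.46,34.66,2.00
Reaumuria songonica,Cu,9.08,3.89,5.30,5.86,35.85,45.80
Reaumuria songonica,Zn,12.30,4.90,8.18,8.31,34.40,100.00
Reaumuria songonica,Cd,0.31,0.05,0.08,0.12,87.02,0.20
Reaumuria songonica,Pb,14.13,0.81,0.93,3.65,160.72,3.00
Reaumuria songonica,Hg,0.02,0.01,0.01,0.01,13.56,0.01
Reaumuria songonica,As,1.38,0.48,0.83,0.92,39.42,5.00
Haloxylon ammodendron,Cr,366.00,14.70,34.90,63.79,152.14,2.00
Haloxylon ammodendron,Cu,6.23,2.76,3.55,3.85,25.25,45.80
Haloxylon ammodendron,Zn,12.10,2.72,8.11,7.48,42.77,100.00
Haloxylon ammodendron,Cd,0.18,0.04,0.07,0.08,47.90,0.20
Haloxylon ammodendron,Pb,0.94,0.05,0.36,0.39,56.73,3.00
Haloxylon ammodendron,Hg,0.01,0.00,0.01,0.01,52.01,0.01
Haloxylon ammodendron,As,0.87,0.06,0.20,0.26,84.09,5.00
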