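"sample_id","species","x","y","Cr","Cu","Zn","Cd","Pb","Hg","As"
"S01","Anabasis aphylla",14.8879,8.27091,205.179,9.38509,6.57024,0.156922,3.43548,0.0103768,1.31792
"S02","Anabasis aphylla",1.75299,32.5713,376.084,4.47108,12.1539,0.115089,0.741462,0.0101136,1.23197
"S03","Anabasis aphylla",28.3874,0.806688,99.5872,4.31534,9.39643,0.0776327,2.47223,0.011571,1.63049
"S04","Anabasis aphylla",26.3076,36.9922,697.829,8.69238,15.2651,0.177089,1.98723,0.0171683,0.735927
"S05","Anabasis aphylla",9.99423,17.3985,457.457,5.72725,8.81102,0.225419,3.36783,0.0152097,1.66406
"S06","Anabasis aphylla",12.0022,17.6822,552.847,6.90684,18.1488,0.151951,1.91541,0.013896,2.22324
"S07","Anabasis aphylla",23.3947,30.4276,455.913,5.25633,25.2867,0.140182,2.00007,0.0108653,1.08739
"S08","Anabasis aphylla",13.3387,13.3185,335.984,5.86094,13.582,0.241538,2.51015,0.00755899,1.1565
"S09","Anabasis aphylla",24.8805,15.7743,263.227,11.6594,7.79367,0.110163,1.87328,0.0133894,1.31007
"S10","Alhagi camelorum",21.8331,9.33177,109.964,3.39891,1.22047,0.0566112,1.22302,0.00815054,0.339356
"S11","Alhagi camelorum",35.1918,2.86431,66.9944,3.94621,1.34268,0.0367816,0.534218,0.00665278,0.597028
"S12","Alhagi camelorum",28.275,36.5353,72.847,3.06815,5.79266,0.112753,0.887412,0.0133555,0.269767
"S13","Alhagi camelorum",29.2789,30.8677,68.3037,2.82111,7.74962,0.209719,0.792435,0.0222675,0.39305
"S14","Alhagi camelorum",37.2654,4.30147,25.6866,3.94067,2.30244,0.0701946,0.6227,0.010939,0.403477
"S15","Alhagi camelorum",18.2048,3.16849,51.383,5.61335,1.91727,0.0450387,1.35826,0.0148883,0.409373
"S16","Alhagi camelorum",23.6128,17.3556,73.3565,4.57183,5.40097,0.0616297,0.963234,0.00975129,0.514272
"S17","Reaumuria songonica",32.8174,27.191,93.2429,3.92656,9.19871,0.0851853,1.25195,0.0155278,0.57282
"S18","Reaumuria songonica",8.96474,29.3742,167.562,6.41139,8.66952,0.17795,3.22528,0.0108194,0.99469
"S19","Reaumuria songonica",16.4667,18.1004,114.66,5.68628,7.27583,0.165561,4.52704,0.00995822,0.998836
"S20","Reaumuria songonica",1.54442,31.3514,81.8709,6.27828,6.35761,0.0828097,1.71387,0.00613556,1.17223
"S21","Reaumuria songonica",28.0285,27.1934,210.887,5.31089,12.555,0.120729,2.08138,0.0144705,0.850696
"S22","Reaumuria songonica",38.2735,20.7481,94.0057,4.67007,3.6741,0.0424379,2.43305,0.00792966,0.683009
"S23","Haloxylon ammodendron",8.53408,27.6322,83.9577,5.01758,13.7539,0.111195,0.163003,0.0118229,0.330338
"S24","Haloxylon ammodendron",26.4425,23.531,51.6074,2.68955,9.83379,0.0982636,0.39738,0.00965411,0.317938
"S25","Haloxylon ammodendron",36.9328,32.5836,35.3574,1.8542,8.51146,0.066061,0.339109,0.00899404,0.28199
"S26","Haloxylon ammodendron",31.8288,32.4018,63.8106,4.75001,6.6962,0.140119,0.177295,0.00956806,0.106622
"S27","Haloxylon ammodendron",2.8485,24.3974,87.0188,3.85944,10.6274,0.131643,0.190543,0.0060063,0.312097
"S28","Haloxylon ammodendron",15.5763,39.7364,39.0153,4.44665,5.51961,0.181251,0.571516,0.00751009,0.115373
"S29","Haloxylon ammodendron",16.258,33.7296,98.6207,4.83422,17.771,0.117696,0.28501,0.0114957,0.313166
"S30","Haloxylon ammodendron",26.3742,28.6201,201.823,4.5313,8.06691,0.150037,0.341384,0.011991,0.154785
"S31","Haloxylon ammodendron",16.9339,0.763248,43.6925,5.14267,3.52815,0.0673107,0.910403,0.00770654,0.205471
"S32","Haloxylon ammodendron",12.8394,12.2032,69.8895,2.63694,8.24539,0.136916,0.533479,0.00679414,0.220832
"S33","Haloxylon ammodendron",7.90923,35.3179,57.6387,5.07357,6.43192,0.100178,0.207393,0.00751645,0.314454
"S34","Haloxylon ammodendron",6.5268,37.6539,51.2347,4.36899,6.73487,0.0814552,0.176365,0.00549516,0.256314
"S35","Haloxylon ammodendron",20.9324,9.37672,66.777,4.27298,5.30232,0.0762091,0.440471,0.00812792,0.17752
"S36","Haloxylon ammodendron",36.5391,37.4666,105.006,1.33492,5.97826,0.11454,0.287234,0.00809021,0.206755
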