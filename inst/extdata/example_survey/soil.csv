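"sample_id","x","y","Cr","Cu","Zn","Cd","Pb","Hg","As"
"S01",14.8879,8.27091,27.6577,21.907,35.6924,0.0938273,26.7133,0.00474468,8.35899
"S02",1.75299,32.5713,44.9249,15.8196,58.987,0.0839632,8.12108,0.00708866,5.74897
"S03",28.3874,0.806688,18.2432,14.1097,36.0778,0.0651408,18.4948,0.00800449,5.80768
"S04",26.3076,36.9922,65.5911,15.3446,49.6563,0.129671,15.2401,0.0111796,3.8161
"S05",9.99423,17.3985,49.9047,17.3734,58.5544,0.144996,22.6423,0.0114981,8.3299
"S06",12.0022,17.6822,60.7693,22.5116,90.8851,0.105048,14.6136,0.0120244,8.39945
"S07",23.3947,30.4276,53.2606,20.752,126.347,0.127332,22.218,0.0151398,6.56246
"S08",13.3387,13.3185,44.632,20.3672,68.9293,0.142385,20.4677,0.00786727,7.49414
"S09",24.8805,15.7743,32.9576,35.3875,37.509,0.116708,21.7849,0.0100378,6.4962
"S10",21.8331,9.33177,43.0717,23.5194,19.6652,0.0913746,25.2179,0.00614577,6.13659
"S11",35.1918,2.86431,28.763,12.9392,21.5576,0.0471367,12.9183,0.00677065,8.91462
"S12",28.275,36.5353,40.8003,21.758,69.2697,0.119515,16.7508,0.0128249,5.27054
"S13",29.2789,30.8677,44.3806,14.6633,74.0575,0.268653,16.1841,0.0247089,7.16562
"S14",37.2654,4.30147,18.9775,25.0102,27.7696,0.0886214,17.0423,0.0070573,7.37397
"S15",18.2048,3.16849,30.8229,24.0757,31.2634,0.0681216,38.8224,0.0105143,6.09654
"S16",23.6128,17.3556,44.2925,20.8642,61.3106,0.131422,19.779,0.0134059,6.8014
"S17",32.8174,27.191,50.1252,18.3019,72.0193,0.129359,9.71571,0.0129904,5.78264
"S18",8.96474,29.3742,46.2914,23.7625,57.2568,0.277117,15.9322,0.0106522,6.64753
"S19",16.4667,18.1004,62.9365,24.1114,54.6385,0.212266,18.9884,0.00753774,8.50457
"S20",1.54442,31.3514,28.8873,20.5644,56.4175,0.111042,8.09343,0.00574445,7.57249
"S21",28.0285,27.1934,71.1858,21.0127,94.7409,0.197956,11.6453,0.0150655,7.70405
"S22",38.2735,20.7481,38.4708,12.388,31.3988,0.0889131,10.2773,0.01133,6.46968
"S23",8.53408,27.6322,76.9065,31.9711,80.9954,0.147259,9.47621,0.00912858,7.98215
"S24",26.4425,23.531,44.1847,15.145,77.8725,0.125102,17.7981,0.0115887,8.67843
"S25",36.9328,32.5836,26.7175,12.0342,82.3153,0.09492,12.5047,0.010461,8.70492
"S26",31.8288,32.4018,46.5911,30.1688,64.7261,0.114409,9.57783,0.0128386,3.37872
"S27",2.8485,24.3974,60.225,20.9095,82.5214,0.173342,9.91441,0.00364961,8.95794
"S28",15.5763,39.7364,26.5145,17.5486,39.0911,0.172338,16.3547,0.00727286,3.50562
"S29",16.258,33.7296,55.774,18.579,100.848,0.16578,14.2582,0.00983905,6.69518
"S30",26.3742,28.6201,94.9548,21.7961,84.2367,0.211011,16.5878,0.0150917,3.834
"S31",16.9339,0.763248,23.4017,30.3418,45.9715,0.0771035,28.0852,0.00466359,6.26168
"S32",12.8394,12.2032,49.8063,17.473,61.5207,0.176284,20.4069,0.0049097,7.00842
"S33",7.90923,35.3179,50.5288,28.4483,52.2294,0.128242,8.45573,0.0063473,7.38907
"S34",6.5268,37.6539,37.1853,22.0937,52.558,0.0990603,7.67167,0.00529962,5.29038
"S35",20.9324,9.37672,36.9657,26.5681,43.8939,0.0950987,25.9102,0.0064981,5.62373
"S36",36.5391,37.4666,48.3788,7.05239,38.4561,0.10777,8.16118,0.00912086,6.51652
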