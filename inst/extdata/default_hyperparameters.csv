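"state","parameter","shape","rate","sigma_b_bound"
"IA","beta0",60.9702,0.00667599,5000
"IA","beta1",22.5747,0.300809,5000
"IA","beta2",4.0528,19.2188,5000
"IA","sigma_e",44.6393,0.0373866,5000
"IL","beta0",171.999,0.0171805,5000
"IL","beta1",5.79051,0.0752223,5000
"IL","beta2",0.643769,2.01183,5000
"IL","sigma_e",44.8392,0.037019,5000
"IN","beta0",149.713,0.0157725,5000
"IN","beta1",9.99252,0.126499,5000
"IN","beta2",0.81671,1.72542,5000
"IN","sigma_e",36.5545,0.0292702,5000
"MN","beta0",92.3669,0.010261,5000
"MN","beta1",8.61311,0.092508,5000
"MN","beta2",1.39203,2.21783,5000
"MN","sigma_e",35.6969,0.032102,5000
"MO","beta0",108.992,0.0126016,5000
"MO","beta1",5.83108,0.0832448,5000
"MO","beta2",0.82059,1.68047,5000
"MO","sigma_e",43.5609,0.0382436,5000
"ND","beta0",83.9383,0.0103007,5000
"ND","beta1",7.94463,0.100317,5000
"ND","beta2",1.63723,2.16916,5000
"ND","sigma_e",41.8884,0.0369933,5000
"NE","beta0",137.244,0.013393,5000
"NE","beta1",8.51051,0.120933,5000
"NE","beta2",1.74428,9.68992,5000
"NE","sigma_e",27.9322,0.0259609,5000
"WI","beta0",166.358,0.0165996,5000
"WI","beta1",13.5611,0.181474,5000
"WI","beta2",7.35819,45.6146,5000
"WI","sigma_e",32.1996,0.0307789,5000
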