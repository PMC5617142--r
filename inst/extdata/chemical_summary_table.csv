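matrix,chemical,chemical_class,log_kow,reporting_limit,n,median,maximum,detection_frequency
water,Cholesterol,Sterol,7.69,0.20,285,1.80,72.2,100
water,Isophorone,Other,1.7,0.05,291,0.0068,0.0548,72
water,Metformin,Pharmaceutical,-0.88,0.013,288,0.0465,33.6,71
water,Atrazine,Pesticide,2.61,0.019,292,0.0184,0.814,70
water,DEET,Insect repellant,2.18,0.04,291,0.021,5.07,68
water,Metolachlor,Pesticide,3.13,0.04,291,0.0136,1.53,62
water,beta-Sitosterol,Sterol,8.25,4.8,291,0.42,7.77,61
water,Carbamazepine,Pharmaceutical,2.45,0.0041,292,0.00128,0.333,52
water,TBEP,Flame retardant,2.75,0.64,291,0.105,38.7,52
water,Lidocaine,Pharmaceutical,1.44,0.015,292,0.00015,2.06,50
water,BTZA,Industrial,1.44,0.141,292,0.004,8.06,50
water,Desvenlafaxine,Pharmaceutical,,0.00749,292,,1.24,48
water,Methocarbamol,Pharmaceutical,0.61,0.00872,292,,0.592,47
water,Tramadol,Pharmaceutical,2.38,0.0151,292,,0.863,46
water,Cotinine,Other,0.07,0.00637,292,,0.121,45
water,HHCB,Fragrance,5.9,0.04,291,,2.18,44
water,Indole,Fecal indicator,2.14,0.04,289,,0.0284,44
water,Fexofenadine,Pharmaceutical,3.88,0.0199,292,,3.62,43
water,"9,10-Anthraquinone",Industrial,3.39,0.04,291,,0.402,42
water,Venlafaxine,Pharmaceutical,2.51,0.00448,292,,0.319,42
water,Caffeine,Other,-0.07,0.0907,292,,6.61,40
water,TDIP,Flame retardant,3.65,0.32,291,,0.44,37
water,Nicotine,Other,1.17,0.0578,292,,0.492,37
water,Acyclovir,Pharmaceutical,-1.56,0.0222,292,,1.11,36
water,Fluoranthene,PAH,5.16,0.02,291,,0.671,36
water,Sulfamethoxazole,Pharmaceutical,0.89,0.0261,292,,1.39,36
water,Triamterene,Pharmaceutical,0.98,0.00525,292,,0.382,36
water,Pyrene,PAH,4.88,0.02,291,,0.512,35
water,Atenolol,Pharmaceutical,0.16,0.0133,292,,1.70,34
water,3beta-Coprostanol,Sterol,8.22,1.6,291,,14.4,34
water,Meprobamate,Pharmaceutical,0.7,0.086,292,,0.114,32
water,Metoprolol,Pharmaceutical,1.88,0.0275,292,,0.415,30
sediment,Indole,Fecal indicator,2.14,50,76,130,1240,100
sediment,3-Methyl-1H-indole,Fecal indicator,2.6,33,76,10.7,574,91
sediment,Fluoranthene,PAH,5.16,41.5,76,192,20800,87
sediment,Pyrene,PAH,4.88,41.5,76,165,18300,87
sediment,Benzo[a]pyrene,PAH,6.13,41.5,76,65.3,1790,86
sediment,"2,6-Dimethylnaphthalene",PAH,4.31,33,76,25.5,338,84
sediment,Carbazole,Other,3.72,34.5,76,15.4,678,80
sediment,Anthracene,PAH,4.45,40,76,15.5,918,76
sediment,Phenanthrene,PAH,4.46,37.5,76,112.5,2840,74
sediment,"9,10-Anthraquinone",Industrial,3.39,33,71,46.1,899,73
sediment,p-Cresol,Phenolic,1.94,165,76,73.2,9330,72
sediment,Estrone,Hormone,3.13,0.053,76,0.32,10.93,68
sediment,A4,Hormone,2.75,0.053,76,0.171,2.85,67
sediment,Cholesterol,Sterol,7.69,165,76,586,5400,54
sediment,1-Methylnaphthalene,PAH,3.87,33,76,1.045,197,50
sediment,2-Methylnaphthalene,PAH,3.86,33,76,,406,49
sediment,HHCB,Fragrance,5.9,33,76,,660,46
sediment,beta-Sitosterol,Sterol,8.25,330,76,,15200,43
sediment,Naphthalene,PAH,3.3,33,76,,1720,43
sediment,beta-Stigmastanol,Sterol,8.63,330,76,,5250,42
sediment,Isophorone,Other,1.7,33,76,,46.2,41
sediment,4-tert-Octylphenol,Alkylphenol,5.28,33,75,,169,37
sediment,Bisphenol A,Plasticizer,3.32,33,76,,380,37
sediment,17beta-Estradiol,Hormone,4.01,0.053,74,,5.85,36
sediment,cis-Androsterone,Hormone,3.69,0.053,76,,6.91,36
sediment,Diphenhydramine,Pharmaceutical,3.27,2.7,77,,1.75,32
sediment,"1,4-Dichlorobenzene",Other,3.44,33,76,,1160,30
sediment,AHTN,Fragrance,5.7,33,76,,104,30
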