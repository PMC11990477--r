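compound,family,WY,SC,MP,LT,BC,series_ids
Ethyl acetate,Acetates,7.83,5.7,5.0,11.5,9.4,1;2;4
Butyl acetate,Acetates,0.00034,0.0002,0.00035,0.00081,0.0008,2
Isoamyl acetate,Acetates,24,19,9.6,11,18,2
(Z)-3-Hexenyl acetate,Acetates,0.5,0.75,0.0001,0.22,0.28,2;4
Hexyl acetate,Acetates,0.7,1.1,0.0005,0.11,0.15,2;3
Octyl acetate,Acetates,0.115,0.121,0.112,0.113,0.12,5;11
Ethyl phenylacetate,Acetates,0.031,0.009,0.023,0.051,0.041,5;10
2-Phenylethyl acetate,Acetates,15,3.6,2.4,1.3,2.2,5;10
Geranyl acetate,Acetates,0.30,0.21,0.54,0.41,0.45,5
Ethyl lactate,Ethyl esters,0.17,0.166,0.21,0.95,0.80,2
Ethyl isobutyrate,Ethyl esters,1.9,0.60,1.08,3.9,3.5,2
Ethyl butyrate,Ethyl esters,1.9,1.9,2.6,1.8,1.7,2
Ethyl 2-methylbutyrate,Ethyl esters,0.0,0.0,0.0,0.0,0.16,2
Ethyl 3-methylbutyrate,Ethyl esters,1.7,0.0,0.0,0.0,0.0,2;3
Diethyl succinate,Ethyl esters,0.118,0.079,0.08,0.0,0.02,2
Ethyl hexanoate,Ethyl esters,0.0001,0.0001,0.0001,0.0001,0.0001,2;3
Ethyl heptanoate,Ethyl esters,0.087,0.055,0.0,0.058,0.062,2;3
Ethyl octanoate,Ethyl esters,0.0002,0.0002,0.0002,0.0002,0.0002,2;11
Ethyl decanoate,Ethyl esters,0.113,0.12,0.114,0.106,0.15,2;11
Ethyl dodecanoate,Ethyl esters,0.0069,0.0063,0.0069,0.007,0.020,11
Ethyl tetradecanoate,Ethyl esters,0.0042,0.0041,0.0042,0.0034,0.0042,5;6
Ethyl hexadecanoate,Ethyl esters,0.0064,0.0049,0.008,0.0040,0.0052,2;6;11
Cis-3-Hexenyl butyrate,Other esters,9,7,8.6,8,7.1,4
2-Phenylethyl butanoate,Other esters,0.004,0.000005,0.010,0.004,0.009,5
E-Methyldihydrojasmonate,Other esters,0.012,0.02,0.02,0.008,0.011,5
Methanol,Alcohols,0.062,0.09,0.067,0.060,0.118,1
1-Propanol,Alcohols,0.027,0.023,0.029,0.083,0.082,1;4
Isobutanol,Alcohols,1.6,0.79,2.34,1.87,1.93,1
2-Methyl-1-butanol,Alcohols,1.80,1.56,2.56,2.42,2.7,1
3-Methyl-1-butanol,Alcohols,10.5,9.1,10.0,10.6,10.8,1
2-Phenylethanol,Alcohols,6,5.0,6.2,8.2,8.7,5
Hexanol,Alcohols,0.10,0.092,0.094,0.09,0.118,4
2-Ethyl-1-hexanol,Alcohols,0.0017,0.0021,0.0017,0.0024,0.0024,7
Dodecanol,Alcohols,0.006,0.0053,0.0074,0.004,0.0032,11
2-Methoxy-4-vinylphenol,Alcohols,0.7,0.8,0.83,0.000008,0.000008,9
gamma-Butyrolactone,Lactones,0.40,0.48,0.71,0.41,0.39,6
gamma-Crotonolactone,Lactones,0.0,0.0,0.0,0.0,0.0,6
gamma-Nonalactone,Lactones,0.20,0.17,0.39,0.14,0.21,6;2
beta-Damascenone,Lactones,47,62,55,38,43,5;8
Acetaldehyde,Carbonyl compounds,7,9.5,6.4,20,21,1;2
"1,1-Diethoxyethane",Carbonyl compounds,0.0,0.010,0.0,8,1.45,1;4
Acetoin,Carbonyl compounds,1.2,0.99,1.06,4.8,5.7,6
Hexanal,Carbonyl compounds,0.33,0.24,0.48,0.46,0.39,4
Furfural,Carbonyl compounds,0.7,0.6,0.7,0.57,0.9,1;9
Benzaldehyde,Carbonyl compounds,0.0,0.002,0.0,0.003,0.007,2
Octanal,Carbonyl compounds,0.0,0.33,0.4,0.6,0.4,7
Nonanal,Carbonyl compounds,2.9,3.3,3.6,3.7,3.4,7
2-Phenylacetaldehyde,Carbonyl compounds,0.0,0.0,0.0,8,10.3,4;10
Decanal,Carbonyl compounds,4.4,5.2,5.0,6.3,6.1,8;11
Limonene,Terpenes and derivatives,468,348,322,352,320,1;7
E-Geranyl acetone,Terpenes and derivatives,0.024,0.017,0.022,0.011,0.015,5
Z-Geranyl acetone,Terpenes and derivatives,0.0302,0.030,0.031,0.030,0.0299,5
Nerolidol,Terpenes and derivatives,0.0,0.0062,0.002,0.0001,0.0,4;5
Farnesol,Terpenes and derivatives,0.0001,0.0001,0.0001,0.0001,0.0001,5
"2,3-Butanediol levo",Miscellaneous,0.7,0.57,0.69,0.49,0.47,2;6
"2,3-Butanediol meso",Miscellaneous,0.3,0.17,0.25,0.19,0.19,2;6
2-Pentylfuran,Miscellaneous,1.0,0.5,0.66,0.0002,0.0002,3
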