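snp_id,effect_allele,odds_ratio
snp7,T,1.2267
snp8,T,1.0614
snp15,T,1.1675
snp25,A,0.8439
snp38,T,1.1136
snp39,T,0.9817
snp48,T,0.8712
snp53,C,0.9164
snp61,T,0.9619
snp79,T,1.1196
snp89,G,0.9257
snp90,A,1.1057
snp98,T,0.9896
snp101,G,0.9416
snp103,A,0.9305
snp106,C,0.8213
snp116,A,0.9794
snp119,T,0.9732
snp122,T,1.1438
snp128,G,1.1063
snp131,G,0.9114
snp132,C,0.9288
snp134,A,1.0496
snp139,C,0.9542
snp142,C,0.9691
snp143,G,1.1079
snp150,T,0.9326
snp155,T,1.1178
snp157,G,1.1523
snp158,G,0.7779
snp161,T,1.0127
snp168,G,0.769
snp169,G,1.0846
snp173,A,0.8787
snp179,A,0.9017
snp185,T,0.9781
snp198,C,0.9429
snp200,G,0.8506
snp205,T,0.9883
snp216,C,0.8926
snp217,C,1.1341
snp222,C,0.9609
snp226,G,1.3072
snp239,C,0.9944
snp248,T,1.1577
snp267,C,1.0246
snp272,T,1.1253
snp273,G,0.957
snp287,A,1.1478
snp289,A,1.0102
snp291,T,1.3317
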