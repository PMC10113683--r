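patient,median_mm,iqr_low_mm,iqr_high_mm,prediction_rate_pct
1,2.45,2.02,2.89,78.5
2,5.65,5.07,6.36,24.0
3,2.48,1.87,3.29,68.0
4,2.48,2.27,2.84,96.0
5,1.81,1.44,2.15,98.0
6,3.17,2.70,3.81,61.7
7,1.75,1.43,2.13,46.6
8,1.56,1.00,2.65,72.1
9,1.94,1.43,2.54,42.0
10,2.39,1.54,3.54,98.8
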